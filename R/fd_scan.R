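## Per-site divergence scoring at a node partition, empirical null
## calibration by neutral simulation, FDR correction, and branch calls.

.SE_FLOOR <- 1e-6

## Pair-mean/variance of substitution scores between a clade and the
## outgroup, per column.  `code` is the integer-encoded alignment (NA =
## gap); `rows_c`, `rows_o` are row indices.  Gapped members drop out
## pairwise.  Returns n (pair counts), mean and sample variance per column.
pair_column_stats <- function(code, rows_c, rows_o, matrix = blosum62()) {
  pairs <- expand.grid(i = rows_c, k = rows_o)
  ci <- code[pairs$i, , drop = FALSE]
  co <- code[pairs$k, , drop = FALSE]
  ok <- !is.na(ci) & !is.na(co)
  X <- matrix(NA_real_, nrow(ci), ncol(ci))
  X[ok] <- matrix[cbind(ci[ok], co[ok])]
  n <- colSums(ok)
  s <- colSums(X, na.rm = TRUE)
  ss <- colSums(X * X, na.rm = TRUE)
  m <- ifelse(n > 0, s / n, NA_real_)
  v <- ifelse(n > 1, pmax(ss - n * m^2, 0) / pmax(n - 1, 1), 0)
  v[n == 0] <- NA_real_
  list(n = n, mean = m, var = v)
}

## Combine the two clade-vs-outgroup summaries into the Welch-type score.
welch_fd <- function(a, b) {
  scorable <- a$n > 0 & b$n > 0
  diff <- a$mean - b$mean
  se <- sqrt(a$var / a$n + b$var / b$n)
  fd <- ifelse(diff == 0, 0, abs(diff) / pmax(se, .SE_FLOOR))
  fd[!scorable] <- NA_real_
  list(fd = fd, se = se, scorable = scorable)
}

#' Score every alignment column at a node partition
#'
#' For each column, the mean BLOSUM62 substitution score of all non-gap
#' (clade member, outgroup member) pairs is computed for each of the two
#' clades; the divergence score is the absolute difference of the two
#' means divided by the standard error for unequal sample sizes with
#' unequal variances, `SE = sqrt(s1^2/n1 + s2^2/n2)`.  Columns where a
#' clade or the outgroup contributes no non-gap pair are not scorable.
#' When the two means are equal the score is 0; otherwise a vanishing SE
#' is floored at `1e-6` so fully conserved contrasts remain rankable.
#'
#' @param group an [alignment_group()], or an already-encoded integer
#'   matrix as produced internally.
#' @param partition a `node_partition` (see [enumerate_testable_nodes()]).
#' @param matrix scoring matrix, default [blosum62()].
#' @return a data.frame with one row per column: `site`, `n_a`, `n_b`,
#'   `xbar_a`, `xbar_b`, `var_a`, `var_b`, `fd_score`, `scorable`.
#' @export
score_partition <- function(group, partition, matrix = blosum62()) {
  code <- if (inherits(group, "alignment_group")) encode_alignment(group$seq) else group
  stopifnot(inherits(partition, "node_partition"))
  ids <- rownames(code)
  ra <- match(partition$clade_a, ids)
  rb <- match(partition$clade_b, ids)
  ro <- match(partition$outgroup, ids)
  if (anyNA(c(ra, rb, ro))) stop("partition names sequences absent from the alignment")
  a <- pair_column_stats(code, ra, ro, matrix)
  b <- pair_column_stats(code, rb, ro, matrix)
  w <- welch_fd(a, b)
  data.frame(site = seq_len(ncol(code)),
             n_a = a$n, n_b = b$n,
             xbar_a = a$mean, xbar_b = b$mean,
             var_a = a$var, var_b = b$var,
             fd_score = w$fd, scorable = w$scorable)
}

#' Score a single alignment column
#'
#' @param column named character vector of residues (one per sequence,
#'   gap `"-"`).
#' @inheritParams score_partition
#' @return a list (`site_score`) with `xbar_a`, `xbar_b`, `var_a`,
#'   `var_b`, `n_a`, `n_b`, `fd_score`, or `NULL` when the column is not
#'   scorable.
#' @export
score_site <- function(column, partition, matrix = blosum62()) {
  m <- matrix(column, ncol = 1, dimnames = list(names(column), NULL))
  df <- score_partition(encode_alignment(m), partition, matrix)
  if (!df$scorable[1L]) return(NULL)
  structure(as.list(df[1L, c("xbar_a", "xbar_b", "var_a", "var_b",
                             "n_a", "n_b", "fd_score")]),
            class = "site_score")
}

## Precompute the stacked cumulative transition-probability matrix the
## C++ simulator consumes: one 20-column block per (edge, category,
## parent state).
.null_sim_setup <- function(tree, partition, model) {
  tree <- stats::reorder(tree, "cladewise")
  ntip <- length(tree$tip.label)
  nedge <- nrow(tree$edge)
  k <- model$n_categories
  cum <- matrix(0, 20, 20 * k * nedge)
  for (e in seq_len(nedge)) {
    for (cc in seq_len(k)) {
      P <- transition_probs(model, tree$edge.length[e], model$rates[cc])
      block <- ((e - 1L) * k + (cc - 1L)) * 20L
      cum[, block + seq_len(20L)] <- apply(P, 1L, cumsum)  # col s = cum row s
    }
  }
  list(tree = tree, ntip = ntip,
       cum = cum, root_cum = cumsum(model$freq),
       rows_a = match(partition$clade_a, tree$tip.label),
       rows_b = match(partition$clade_b, tree$tip.label),
       rows_o = match(partition$outgroup, tree$tip.label))
}

#' Calibrate the null distribution of the divergence score at one node
#'
#' Neutral alignments are simulated on the group's own tree (topology and
#' branch lengths) under JTT + discrete-gamma evolution, each column is
#' scored at the same node partition, and the scores are pooled.  The
#' simulated length is the alignment length minus the mean per-sequence
#' gap count (rounded half-to-even).  After an initial `n_min` replicates
#' the procedure continues in batches until the running mean and standard
#' deviation of the pooled scores both change by less than `tol` between
#' batches, up to `max_replicates` (a warning of class
#' `fdscan_unconverged` is raised when the cap is hit first).
#'
#' @param group an [alignment_group()].
#' @param tree the group's rooted gene tree.
#' @param partition the `node_partition` under test.
#' @param model a [rate_model()].
#' @param seed integer seed; the whole calibration is deterministic given
#'   the seed.
#' @param n_min minimum number of replicate alignments (default 1000).
#' @param batch_size replicates added per convergence batch (default 100).
#' @param max_replicates hard cap (default 10000).
#' @param tol convergence tolerance on the batch-to-batch change of the
#'   running mean and sd (default 1e-6).
#' @param sim_length override for the simulated alignment length.
#' @return a `null_distribution`: list with `node_id`, `scores` (pooled
#'   numeric vector), `n_replicates`, `mean`, `sd`, `converged`,
#'   `sim_length`, `seed`.
#' @export
calibrate_null <- function(group, tree, partition, model = rate_model(),
                           seed = 1L, n_min = 1000L, batch_size = 100L,
                           max_replicates = 10000L, tol = 1e-6,
                           sim_length = NULL) {
  stopifnot(inherits(partition, "node_partition"))
  if (is.null(sim_length)) sim_length <- gap_profile(group)$simulated_length
  if (sim_length < 1L) {
    stop("degenerate alignment: simulated length < 1 after gap adjustment",
         call. = FALSE)
  }
  setup <- .null_sim_setup(tree, partition, model)
  B <- blosum62()
  set.seed(seed)

  draw <- function(n) {
    null_fd_pool(setup$tree$edge, setup$ntip + setup$tree$Nnode, setup$ntip,
                 setup$cum, setup$root_cum,
                 setup$rows_a, setup$rows_b, setup$rows_o,
                 B, model$n_categories, as.integer(n), as.integer(sim_length),
                 .SE_FLOOR)
  }

  scores <- draw(n_min)
  n_rep <- n_min
  m_old <- mean(scores); s_old <- stats::sd(scores)
  converged <- FALSE
  while (n_rep < max_replicates) {
    nb <- min(batch_size, max_replicates - n_rep)
    scores <- c(scores, draw(nb))
    n_rep <- n_rep + nb
    m_new <- mean(scores); s_new <- stats::sd(scores)
    if (abs(m_new - m_old) < tol && abs(s_new - s_old) < tol) {
      converged <- TRUE
      m_old <- m_new; s_old <- s_new
      break
    }
    m_old <- m_new; s_old <- s_new
  }
  if (!converged && n_rep >= max_replicates) {
    warning(structure(class = c("fdscan_unconverged", "warning", "condition"),
                      list(message = paste0("null distribution for node ",
                                            partition$node_id, " of group '",
                                            group$group_id,
                                            "' not converged after ", n_rep,
                                            " replicates"),
                           call = sys.call())))
  }
  structure(list(node_id = partition$node_id, scores = scores,
                 n_replicates = n_rep, mean = m_old, sd = s_old,
                 converged = converged, sim_length = sim_length, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null distribution, node", x$node_id, ":", x$n_replicates,
      "replicates x", x$sim_length, "columns; mean", signif(x$mean, 4),
      "sd", signif(x$sd, 4),
      if (x$converged) "(converged)" else "(cap reached)", "\n")
  invisible(x)
}

#' Empirical upper-tail p-values against a null distribution
#'
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)` (add-one empirical
#' tail, so p is never zero).  `NA` scores (non-scorable sites) give `NA`.
#'
#' @param observed numeric vector of observed divergence scores, or the
#'   data.frame returned by [score_partition()].
#' @param null a `null_distribution` (or numeric vector of null scores).
#' @return numeric vector of p-values.
#' @export
site_pvalues <- function(observed, null) {
  if (is.data.frame(observed)) observed <- observed$fd_score
  ns <- if (inherits(null, "null_distribution")) null$scores else as.numeric(null)
  if (length(ns) == 0L) stop("empty null distribution", call. = FALSE)
  sv <- sort(ns)
  n <- length(sv)
  ge <- n - findInterval(observed, sv, left.open = TRUE)  # #{null >= obs}
  (1 + ge) / (1 + n)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false-discovery-rate control; sites with `q <= alpha` are
#' declared significant.
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` allowed).
#' @param alpha significance level (default 0.05).
#' @return list with `qvalues` and integer vector `significant` of the
#'   indices with `q <= alpha`.
#' @export
fdr_correct <- function(pvalues, alpha = 0.05) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(qvalues = q, significant = which(!is.na(q) & q <= alpha))
}

#' Branch-level functional-divergence call
#'
#' A branch (tested node) is called functionally divergent when at least
#' one of its sites is significant after FDR correction.
#'
#' @param partition the tested `node_partition`.
#' @param significant_sites integer vector of significant column indices.
#' @param group_id optional group identifier carried into the result.
#' @return a `branch_result`: list with `group_id`, `node_id`,
#'   `significant_sites`, `is_fd`.
#' @export
call_branch <- function(partition, significant_sites, group_id = NA_character_) {
  structure(list(group_id = group_id, node_id = partition$node_id,
                 significant_sites = as.integer(significant_sites),
                 is_fd = length(significant_sites) > 0L),
            class = "branch_result")
}

#' Scan one alignment group for functional divergence
#'
#' Full per-group pipeline: gene tree (JTT + gamma distances, BIONJ,
#' midpoint rooting), enumeration of testable nodes, per-site scoring,
#' null calibration, empirical p-values, per-node BH-FDR, and branch
#' calls.
#'
#' @param group an [alignment_group()] (assumed to have passed
#'   [filter_group()]).
#' @param model a [rate_model()].
#' @param seed integer seed for the null simulations (per-node streams
#'   are derived from it deterministically).
#' @param alpha FDR level (default 0.05).
#' @param min_clade,min_outgroup testability thresholds (defaults 4, 1).
#' @param n_min,batch_size,max_replicates,tol null-calibration controls,
#'   see [calibrate_null()].
#' @param tree optional precomputed rooted tree (skips tree building).
#' @param keep_null keep the pooled null scores in the result (memory!).
#' @return an `fd_scan` object: list with `group_id`, `tree`,
#'   `partitions`, `sites` (per node x column data.frame with `fd_score`,
#'   `p`, `q`, `significant`), `branches` (one row per tested node with
#'   clade sizes, significant-site count, `is_fd`, attributed `species`
#'   and the group `category`), `alpha`, `seed`.
#' @export
scan_group <- function(group, model = rate_model(), seed = 1L, alpha = 0.05,
                       min_clade = 4, min_outgroup = 1,
                       n_min = 1000L, batch_size = 100L,
                       max_replicates = 10000L, tol = 1e-6,
                       tree = NULL, keep_null = FALSE) {
  stopifnot(inherits(group, "alignment_group"))
  if (is.null(tree)) tree <- gene_tree(group, model)
  parts <- enumerate_testable_nodes(tree, min_clade, min_outgroup)
  code <- encode_alignment(group$seq)
  sites <- list(); branches <- list(); nulls <- list()
  for (i in seq_along(parts)) {
    part <- parts[[i]]
    obs <- score_partition(code, part)
    null <- calibrate_null(group, tree, part, model,
                           seed = derive_seed(seed, paste0("node", part$node_id)),
                           n_min = n_min, batch_size = batch_size,
                           max_replicates = max_replicates, tol = tol)
    p <- site_pvalues(obs, null)
    p[!obs$scorable] <- NA_real_
    fdr <- fdr_correct(p, alpha)
    sig <- fdr$significant
    clade_species <- sort(unique(group$species[c(part$clade_a, part$clade_b)]))
    sites[[i]] <- data.frame(group_id = group$group_id,
                             node_id = part$node_id,
                             site = obs$site, fd_score = obs$fd_score,
                             p = p, q = fdr$qvalues,
                             significant = obs$site %in% sig)
    branches[[i]] <- data.frame(group_id = group$group_id,
                                node_id = part$node_id,
                                n_clade_a = length(part$clade_a),
                                n_clade_b = length(part$clade_b),
                                n_outgroup = length(part$outgroup),
                                n_scored = sum(obs$scorable),
                                n_significant = length(sig),
                                is_fd = length(sig) > 0L,
                                category = unname(group$category[[1L]]),
                                species = paste(clade_species, collapse = ","),
                                null_replicates = null$n_replicates,
                                null_converged = null$converged)
    if (keep_null) nulls[[as.character(part$node_id)]] <- null
  }
  structure(list(group_id = group$group_id, tree = tree, partitions = parts,
                 sites = do.call(rbind, sites),
                 branches = do.call(rbind, branches),
                 nulls = if (keep_null) nulls else NULL,
                 alpha = alpha, seed = seed),
            class = "fd_scan")
}

#' @export
print.fd_scan <- function(x, ...) {
  nb <- if (is.null(x$branches)) 0L else nrow(x$branches)
  cat("functional-divergence scan of '", x$group_id, "': ", nb,
      " testable node(s)", sep = "")
  if (nb > 0) {
    cat(", ", sum(x$branches$is_fd), " called divergent (",
        sum(x$branches$n_significant), " significant sites)", sep = "")
  }
  cat("\n")
  invisible(x)
}
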