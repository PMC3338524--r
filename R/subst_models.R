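## Substitution models: BLOSUM62 scoring, JTT + discrete-gamma rate model,
## maximum-likelihood pairwise distances, and a neutral sequence simulator.

#' The BLOSUM62 scoring matrix over the 20 standard amino acids
#'
#' Returns the canonical BLOSUM62 substitution-score matrix restricted to
#' the 20 standard amino acids, in the package's internal residue order.
#' The matrix is symmetric and its diagonal dominates each row.
#'
#' @return a named 20 x 20 integer matrix of substitution scores.
#' @export
#' @examples
#' blosum62()["W", "W"]  # 11
blosum62 <- function() {
  if (is.null(.fdscan_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fdscan_env$blosum62 <- e$BLOSUM62[.AA, .AA]
  }
  .fdscan_env$blosum62
}

#' Score a single amino-acid pair with BLOSUM62
#'
#' @param a,b single amino-acid letters (one of the 20 standard residues).
#' @param matrix scoring matrix, by default [blosum62()].
#' @return the integer substitution score.
#' @export
blosum_score <- function(a, b, matrix = blosum62()) {
  if (!(a %in% .AA) || !(b %in% .AA)) {
    stop("blosum_score() is defined only for the 20 standard amino acids, got '",
         a, "', '", b, "'", call. = FALSE)
  }
  matrix[a, b]
}

#' JTT replacement model with discrete-gamma rate heterogeneity
#'
#' Builds the JTT (Jones-Taylor-Thornton) instantaneous rate matrix from
#' the published exchangeability and equilibrium-frequency tables (as
#' shipped with \pkg{phangorn}), normalised to one expected substitution
#' per site at equilibrium, together with a discrete-gamma model of
#' among-site rate variation (equiprobable categories, mean-of-quartile
#' rates, so that the category rates average exactly 1).
#'
#' @param gamma_shape positive gamma shape parameter alpha (default 1.0).
#' @param n_categories number of discrete rate categories (default 4).
#' @return an object of class `rate_model` with components `Q` (20 x 20
#'   rate matrix, rows sum to zero), `freq` (equilibrium frequencies),
#'   `eig` (spectral decomposition used for matrix exponentials),
#'   `rates` (category rates), `gamma_shape` and `n_categories`.
#' @export
rate_model <- function(gamma_shape = 1.0, n_categories = 4L) {
  stopifnot(gamma_shape > 0, n_categories >= 1)
  jtt <- get(".JTT", envir = asNamespace("phangorn"))
  freq <- as.numeric(jtt$bf)
  names(freq) <- .AA
  S <- matrix(0, 20, 20, dimnames = list(.AA, .AA))
  S[lower.tri(S)] <- jtt$Q
  S <- S + t(S)
  Q <- S %*% diag(freq)
  diag(Q) <- -rowSums(Q)
  Q <- Q / -sum(freq * diag(Q))   # 1 expected substitution/site at rate 1
  dimnames(Q) <- list(.AA, .AA)

  ## reversible Q: symmetrise with sqrt(pi) for a stable eigendecomposition
  d <- sqrt(freq)
  Sym <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((Sym + t(Sym)) / 2, symmetric = TRUE)
  eig <- list(values = eig$values,
              left  = diag(1 / d) %*% eig$vectors,   # P(t) = left exp(Lt) right
              right = t(eig$vectors) %*% diag(d))

  rates <- phangorn::discrete.gamma(gamma_shape, n_categories)
  structure(list(Q = Q, freq = freq, eig = eig, rates = rates,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories)),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("JTT rate model, gamma shape", x$gamma_shape, "with", x$n_categories,
      "rate categories\n")
  cat("category rates:", signif(x$rates, 4), "\n")
  invisible(x)
}

#' Transition probabilities exp(Q r t)
#'
#' @param model a [rate_model()].
#' @param t branch length in expected substitutions per site.
#' @param rate rate multiplier (e.g. a discrete-gamma category rate).
#' @return a 20 x 20 row-stochastic matrix.
#' @export
transition_probs <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "rate_model"), is.finite(t), t >= 0)
  P <- model$eig$left %*% (exp(model$eig$values * t * rate) * model$eig$right)
  P[P < 0] <- 0           # clip eigen-roundoff
  P <- P / rowSums(P)
  dimnames(P) <- list(.AA, .AA)
  P
}

#' Maximum-likelihood pairwise distances under JTT + gamma
#'
#' Distances are estimated by numerical likelihood optimisation under the
#' JTT model with discrete-gamma rates (via [phangorn::dist.ml()]);
#' alignment columns containing a gap in either sequence of a pair are
#' excluded pairwise.  Estimates above `d_max` are treated as saturated
#' and clamped, so that tree building can proceed.
#'
#' @param x an [alignment_group()] or a character matrix of aligned
#'   residues (rows = sequences, gap `"-"`).
#' @param model a [rate_model()].
#' @param d_max saturation cap in substitutions/site (default 10).
#' @return a `dist` object; the logical attribute `saturated` marks
#'   clamped pairs.
#' @export
pairwise_distances <- function(x, model = rate_model(), d_max = 10) {
  m <- if (inherits(x, "alignment_group")) x$seq else x
  stopifnot(is.matrix(m), nrow(m) >= 2)
  pd <- phangorn::phyDat(m, type = "AA")
  d <- phangorn::dist.ml(pd, model = "JTT", exclude = "pairwise",
                         k = model$n_categories, shape = model$gamma_shape)
  sat <- !is.na(d) & d > d_max
  if (any(is.na(d) | !is.finite(d))) {
    stop("undefined distance: a sequence pair shares no comparable columns",
         call. = FALSE)
  }
  d[sat] <- d_max
  attr(d, "saturated") <- sat
  d
}

#' Maximum-likelihood distance between two aligned sequences
#'
#' @param s1,s2 aligned amino-acid strings (or character vectors) of equal
#'   length; gap is `"-"`.
#' @inheritParams pairwise_distances
#' @return a single distance (substitutions/site); attribute `saturated`
#'   is `TRUE` when the estimate hit `d_max`.
#' @export
pairwise_distance <- function(s1, s2, model = rate_model(), d_max = 10) {
  to_vec <- function(s) if (length(s) == 1L) strsplit(s, "")[[1]] else s
  v1 <- to_vec(s1); v2 <- to_vec(s2)
  if (length(v1) != length(v2)) stop("sequences must be aligned (equal length)")
  if (!any(v1 != .GAP & v2 != .GAP)) {
    stop("undefined distance: no columns where both sequences are ungapped",
         call. = FALSE)
  }
  m <- rbind(a = v1, b = v2)
  d <- pairwise_distances(m, model, d_max)
  structure(as.numeric(d), saturated = as.logical(attr(d, "saturated")))
}

#' Simulate neutral protein evolution along a tree
#'
#' Draws a root sequence from the model's equilibrium frequencies, assigns
#' each site one of the discrete-gamma rate categories with equal
#' probability, and evolves the sequence along every branch with the
#' transition matrix `exp(Q r t)`.  Deterministic given `seed`.
#'
#' @param tree a rooted or unrooted `phylo` tree with finite, non-negative
#'   branch lengths.
#' @param length number of alignment columns to simulate.
#' @param model a [rate_model()].
#' @param seed optional integer seed; when `NULL` the current RNG stream
#'   is used.
#' @return a character matrix (tips x columns, rownames = tip labels) of
#'   simulated residues, with the rate-category assignment in attribute
#'   `rate_category`.
#' @export
evolve_alignment <- function(tree, length, model = rate_model(), seed = NULL) {
  stopifnot(inherits(tree, "phylo"), length >= 1)
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0)) {
    stop("tree must have finite, non-negative branch lengths", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(length)
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  k <- model$n_categories

  ## inverse-CDF category draw (keeps the stream identical to the
  ## compiled null simulator, which consumes one uniform per site)
  cats <- pmin(as.integer(floor(runif(L) * k)) + 1L, k)
  states <- matrix(NA_integer_, nnode, L)
  cum_root <- cumsum(model$freq)
  states[root, ] <- findInterval(runif(L), cum_root, left.open = TRUE) + 1L

  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    t_e <- tree$edge.length[e]
    ## stacked cumulative transition rows: (category, parent state) x child
    Pc <- matrix(0, 20L * k, 20L)
    for (cc in seq_len(k)) {
      P <- transition_probs(model, t_e, model$rates[cc])
      Pc[(cc - 1L) * 20L + seq_len(20L), ] <- t(apply(P, 1L, cumsum))
    }
    idx <- (cats - 1L) * 20L + states[par, ]
    u <- runif(L)
    states[child, ] <- rowSums(Pc[idx, , drop = FALSE] < u) + 1L
  }

  out <- matrix(.AA[states[seq_len(ntip), , drop = FALSE]], ntip, L,
                dimnames = list(tree$tip.label, NULL))
  attr(out, "rate_category") <- cats
  out
}
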