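## Fully synthetic datasets with known ground truth: neutral groups,
## groups with planted clade-specific radical substitutions, and complete
## multi-group pipeline inputs.

#' Random gene tree (Yule shape, exponential branch lengths)
#'
#' @param n_taxa number of tips.
#' @param branch_scale mean branch length (substitutions/site); lengths
#'   are drawn i.i.d. exponential.
#' @param labels optional tip labels (default `s01`, `s02`, ...).
#' @return an unrooted-style `phylo` with the random topology of a pure
#'   birth process.
#' @export
random_gene_tree <- function(n_taxa, branch_scale = 0.1, labels = NULL) {
  stopifnot(n_taxa >= 3)
  tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_scale)
  tr$tip.label <- if (is.null(labels)) sprintf("s%02d", seq_len(n_taxa)) else labels
  tr
}

## Fixed signature topology used for planted-divergence groups: clade A
## and clade B (balanced) attached below the root, with the outgroup on a
## long stem so that midpoint rooting of a reconstructed tree separates
## it from the two clades.  The two clade stems are fixed (not random):
## long enough that distance-based reconstruction recovers the clades
## from a few hundred columns, short enough that neutral clade-wide
## substitutions - the background the planted signal competes with -
## stay rare.  Clades are balanced and within-clade branch lengths are
## bounded uniform draws (0.5-1.2 x `branch_scale`), keeping clade depth
## well below the outgroup stem so the midpoint always falls on the stem.
.signature_tree <- function(n_a = 4, n_b = 4, n_out = 2, branch_scale = 0.1,
                            clade_stem = 0.12, outgroup_stem = 0.45,
                            labels = NULL) {
  bl <- function() stats::runif(1, 0.5 * branch_scale, 1.2 * branch_scale)
  obl <- function() stats::runif(1, branch_scale, 1.8 * branch_scale)
  clade <- function(tips) {
    while (length(tips) > 1L) {
      h <- ceiling(length(tips) / 2)
      pairs <- character(0)
      for (i in seq_len(h)) {
        j <- h + i
        pairs <- c(pairs, if (j <= length(tips)) {
          sprintf("(%s:%.6f,%s:%.6f)", tips[i], bl(), tips[j], bl())
        } else tips[i])
      }
      tips <- pairs
    }
    tips
  }
  if (is.null(labels)) {
    labels <- c(sprintf("a%02d", seq_len(n_a)), sprintf("b%02d", seq_len(n_b)),
                sprintf("o%02d", seq_len(n_out)))
  }
  la <- labels[seq_len(n_a)]
  lb <- labels[n_a + seq_len(n_b)]
  lo <- labels[n_a + n_b + seq_len(n_out)]
  lo_txt <- if (n_out > 1) {
    while (length(lo) > 1L) {
      lo <- c(sprintf("(%s:%.6f,%s:%.6f)", lo[1L], obl(), lo[2L], obl()),
              lo[-(1:2)])
    }
    lo
  } else lo
  txt <- sprintf("((%s:%.6f,%s:%.6f):%.6f,%s:%.6f);",
                 clade(la), clade_stem, clade(lb), clade_stem, bl(),
                 lo_txt, outgroup_stem)
  ape::read.tree(text = txt)
}

#' Generate a neutral alignment group with its true tree
#'
#' A random gene tree is drawn and a gap-free protein alignment evolved
#' along it under JTT + discrete-gamma; no divergence signal is planted.
#'
#' @param n_taxa,n_columns alignment dimensions (defaults 16 x 300).
#' @param branch_scale mean branch length (default 0.1
#'   substitutions/site).
#' @param model a [rate_model()].
#' @param seed integer seed; the group is reproducible given the seed.
#' @param group_id group identifier.
#' @param category functional tag applied to all sequences (default "J").
#' @param species named character vector mapping sequence id to species;
#'   by default each sequence gets its own species (`sp01`, ...).
#' @return list with `group` (an [alignment_group()]) and `tree` (the
#'   true generating tree).
#' @export
make_neutral_group <- function(n_taxa = 16, n_columns = 300,
                               branch_scale = 0.1, model = rate_model(),
                               seed = 1L, group_id = "neutral",
                               category = "J", species = NULL) {
  set.seed(seed)
  tree <- random_gene_tree(n_taxa, branch_scale)
  aln <- evolve_alignment(tree, n_columns, model)
  ids <- rownames(aln)
  if (is.null(species)) {
    species <- stats::setNames(sprintf("sp%02d", seq_len(n_taxa)), ids)
  }
  group <- alignment_group(aln, species = species,
                           category = stats::setNames(rep(category, n_taxa), ids),
                           group_id = group_id)
  list(group = group, tree = tree)
}

#' Generate a group with planted clade-specific radical substitutions
#'
#' A neutral alignment is evolved on a signature topology with two clades
#' of `n_a` and `n_b` sequences and an `n_out`-sequence outgroup (the
#' configuration the divergence statistic tests).  At each of `k_sites`
#' planted columns every sequence of the target clade has its residue
#' replaced by the residue with the lowest BLOSUM62 score against the
#' consensus of the remaining sequences - the radical, clade-wide,
#' conserved replacement the statistic is designed to detect.  Planted
#' columns are chosen among the most conserved columns outside the target
#' clade (ties towards lower index), mimicking divergence at functionally
#' constrained positions.
#'
#' @param k_sites number of planted columns (default 5).
#' @param n_a,n_b,n_out clade and outgroup sizes (defaults 4, 4, 2).
#' @param n_columns alignment length (default 300).
#' @param branch_scale mean within-clade branch length (default 0.1).
#' @param target_clade `"A"` or `"B"`: which clade receives the radical
#'   replacement.
#' @param model a [rate_model()].
#' @param seed integer seed.
#' @param group_id,category,species as in [make_neutral_group()].
#' @return list with `group`, `tree` (true tree) and `truth`: a list with
#'   the planted `clade_a`, `clade_b`, `outgroup` label sets, `sites`
#'   (planted column indices) and `residues` (replacement residue per
#'   planted column).
#' @export
make_divergent_group <- function(k_sites = 5, n_a = 4, n_b = 4, n_out = 2,
                                 n_columns = 300, branch_scale = 0.1,
                                 target_clade = "A", model = rate_model(),
                                 seed = 1L, group_id = "divergent",
                                 category = "U", species = NULL) {
  n_taxa <- n_a + n_b + n_out
  if (k_sites > n_columns) stop("more planted sites than columns")
  set.seed(seed)
  tree <- .signature_tree(n_a, n_b, n_out, branch_scale)
  aln <- evolve_alignment(tree, n_columns, model)
  ids <- rownames(aln)
  clade_a <- grep("^a", ids, value = TRUE)
  clade_b <- grep("^b", ids, value = TRUE)
  outgrp <- grep("^o", ids, value = TRUE)
  target <- if (target_clade == "A") clade_a else clade_b
  rest <- setdiff(ids, target)

  sites <- integer(0)
  residues <- character(0)
  if (k_sites > 0) {
    B <- blosum62()
    ## Planted columns carry the signature the statistic targets: a
    ## position conserved outside the target clade, at which the clade
    ## fixed a radical replacement.  Rank columns by conservation of the
    ## non-target sequences, then by how radical a replacement the
    ## consensus residue admits (its diagonal score minus the most
    ## negative score against it), ties towards lower index.
    cons_of <- function(col) {
      names(sort(table(factor(col, levels = .AA)), decreasing = TRUE))[1L]
    }
    rest_cols <- aln[rest, , drop = FALSE]
    cons_frac <- apply(rest_cols, 2L, function(col) max(table(col)) / length(col))
    cons_res <- apply(rest_cols, 2L, cons_of)
    radicality <- B[cbind(cons_res, cons_res)] - apply(B[, cons_res, drop = FALSE], 2L, min)
    sites <- order(-cons_frac, -radicality, seq_len(n_columns))[seq_len(k_sites)]
    sites <- sort(sites)
    for (j in sites) {
      repl <- .AA[which.min(B[, cons_res[j]])]
      aln[target, j] <- repl
      residues <- c(residues, repl)
    }
  }
  if (is.null(species)) {
    species <- stats::setNames(sprintf("sp%02d", seq_len(n_taxa)), ids)
  }
  group <- alignment_group(aln, species = species,
                           category = stats::setNames(rep(category, n_taxa), ids),
                           group_id = group_id)
  list(group = group, tree = tree,
       truth = list(clade_a = clade_a, clade_b = clade_b, outgroup = outgrp,
                    target_clade = target_clade, sites = sites,
                    residues = residues))
}

#' Generate a complete multi-group dataset on disk
#'
#' Writes a directory of aligned FASTA files, a combined annotation TSV,
#' a species lifestyle TSV, and a machine-readable truth file, forming a
#' full pipeline input with known ground truth.  Every group uses the
#' signature topology (two testable clades plus outgroup).  In groups of
#' the divergent categories, clade A consists of `n_a` sequences of the
#' focal species and carries `k_sites` planted radical substitutions;
#' clade B and the outgroup rotate through the background roster so that
#' no background species is attributed to more than one planted branch.
#' All other groups are neutral, with all slots rotating through the
#' background roster.
#'
#' @param dir output directory (created if needed).
#' @param groups_per_category named integer vector: number of groups per
#'   category tag (default `c(U = 4, J = 4, E = 4)`).
#' @param divergent_categories tags whose groups receive planted
#'   divergence (default `"U"`).
#' @param focal_species species carrying the planted signal (default
#'   `"sp_focal"`).
#' @param n_background number of background species (default 16).
#' @param k_sites planted columns per divergent group (default 5).
#' @param n_a,n_b,n_out,n_columns,branch_scale group geometry, see
#'   [make_divergent_group()].
#' @param model a [rate_model()].
#' @param seed master seed; per-group seeds are derived with
#'   [derive_seed()].
#' @return (invisibly) a manifest list with the file paths, the group
#'   list and the truth records.
#' @export
make_dataset <- function(dir, groups_per_category = c(U = 4, J = 4, E = 4),
                         divergent_categories = "U",
                         focal_species = "sp_focal", n_background = 16,
                         k_sites = 5, n_a = 4, n_b = 4, n_out = 2,
                         n_columns = 300, branch_scale = 0.1,
                         model = rate_model(), seed = 1L) {
  dir.create(file.path(dir, "groups"), recursive = TRUE, showWarnings = FALSE)
  n_taxa <- n_a + n_b + n_out
  roster <- sprintf("bg%02d", seq_len(n_background))
  rot <- 0L          # neutral-slot and outgroup rotation pointer
  div_rot <- 0L      # planted clade-B pointer: each background species is
                     # attributed to at most one planted branch
  take <- function(pointer, k) {
    idx <- ((pointer + seq_len(k) - 1L) %% n_background) + 1L
    roster[idx]
  }
  groups <- list(); truths <- list()
  gi <- 0L
  for (cat in names(groups_per_category)) {
    for (r in seq_len(groups_per_category[[cat]])) {
      gi <- gi + 1L
      gid <- sprintf("g%02d_%s", gi, cat)
      gseed <- derive_seed(seed, gid)
      if (cat %in% divergent_categories) {
        clade_b_sp <- take(div_rot, n_b)
        div_rot <- (div_rot + n_b) %% n_background
        out_sp <- take(rot, n_out)
        rot <- (rot + n_out) %% n_background
        sp <- c(rep(focal_species, n_a), clade_b_sp, out_sp)
        gen <- make_divergent_group(k_sites, n_a, n_b, n_out, n_columns,
                                    branch_scale, target_clade = "A",
                                    model = model, seed = gseed,
                                    group_id = gid, category = cat)
        ids <- rownames(gen$group$seq)
        gen$group$species <- stats::setNames(sp[match(ids, c(
          grep("^a", ids, value = TRUE), grep("^b", ids, value = TRUE),
          grep("^o", ids, value = TRUE)))], ids)
        truths[[gid]] <- c(list(group_id = gid), gen$truth)
      } else {
        sp <- take(rot, n_taxa)
        rot <- (rot + n_taxa) %% n_background
        gen <- make_divergent_group(0L, n_a, n_b, n_out, n_columns,
                                    branch_scale, model = model, seed = gseed,
                                    group_id = gid, category = cat)
        ids <- rownames(gen$group$seq)
        gen$group$species <- stats::setNames(sp[match(ids, c(
          grep("^a", ids, value = TRUE), grep("^b", ids, value = TRUE),
          grep("^o", ids, value = TRUE)))], ids)
      }
      ## sequence ids must be unique across the dataset
      new_ids <- paste0(gid, ".", rownames(gen$group$seq))
      rownames(gen$group$seq) <- new_ids
      names(gen$group$species) <- new_ids
      names(gen$group$category) <- new_ids
      write_alignment(gen$group, file.path(dir, "groups", paste0(gid, ".fasta")))
      groups[[gid]] <- gen$group
    }
  }
  ann_path <- file.path(dir, "annotations.tsv")
  write_annotations(groups, ann_path)
  all_species <- sort(unique(unlist(lapply(groups, function(g) g$species))))
  life <- data.frame(species = all_species,
                     lifestyle = ifelse(all_species == focal_species,
                                        "host-associated", "free-living"))
  life_path <- file.path(dir, "lifestyle.tsv")
  utils::write.table(life, life_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(truths, truth_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = dir, annotations = ann_path, lifestyle = life_path,
                 truth = truth_path, groups = groups, truths = truths))
}
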