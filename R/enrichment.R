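## Aggregation of branch-level calls into enrichment tests per functional
## category, per species, and per category-within-species, plus lifestyle
## contingency tests.

#' Goodness-of-fit chi-squared test
#'
#' `X^2 = sum (O - E)^2 / E`, with the p-value from the upper tail of the
#' chi-squared distribution.
#'
#' @param observed,expected equal-length numeric vectors; all expected
#'   counts must be positive.
#' @param df degrees of freedom (default `length(observed) - 1`).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_squared(c(12, 8), c(10, 10), df = 1)$statistic  # 0.8
chi_squared <- function(observed, expected, df = length(observed) - 1) {
  stopifnot(length(observed) == length(expected))
  if (any(expected <= 0)) {
    stop("degenerate test: zero expected count (use a Fisher test instead)",
         call. = FALSE)
  }
  stat <- sum((observed - expected)^2 / expected)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

## One unit (category, species, or cell) against the rest: a 2x2 test of
## FD-positive vs negative branches, in-unit vs all others.  Yates
## correction by default, Fisher's exact test when any expected count
## falls below 5.  Status follows the sign of O - E at p < alpha.
unit_enrichment <- function(o_unit, t_unit, o_all, t_all,
                            alpha = 0.05, yates = TRUE) {
  if (t_unit == 0L) {
    return(list(observed = 0L, total = 0L, expected = NA_real_,
                p_value = NA_real_, test = "none", status = "no-data"))
  }
  expected <- t_unit * o_all / t_all
  tab <- matrix(c(o_unit, t_unit - o_unit,
                  o_all - o_unit, (t_all - t_unit) - (o_all - o_unit)),
                nrow = 2, byrow = TRUE)
  if (any(tab < 0)) stop("inconsistent counts")
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (t_unit == t_all || o_all == 0L || o_all == t_all) {
    ## degenerate margin: no contrast to test
    p <- 1; test <- "none"
  } else if (any(exp_tab < 5)) {
    p <- stats::fisher.test(tab)$p.value
    test <- "fisher"
  } else {
    p <- suppressWarnings(stats::chisq.test(tab, correct = yates)$p.value)
    test <- if (yates) "chi-squared-yates" else "chi-squared"
  }
  status <- if (p < alpha && o_unit - expected > 0) "enriched"
            else if (p < alpha && o_unit - expected < 0) "impoverished"
            else "neither"
  list(observed = o_unit, total = t_unit, expected = expected,
       p_value = p, test = test, status = status)
}

#' Combine per-group scans into one branch table
#'
#' @param scans a list of `fd_scan` objects (or a single one).
#' @return data.frame with one row per tested branch (columns include
#'   `group_id`, `node_id`, `is_fd`, `category`, comma-separated clade
#'   `species`).
#' @export
branch_table <- function(scans) {
  if (inherits(scans, "fd_scan")) scans <- list(scans)
  tabs <- Filter(Negate(is.null), lapply(scans, function(s) s$branches))
  if (!length(tabs)) {
    stop("no tested branches in the supplied scans", call. = FALSE)
  }
  do.call(rbind, tabs)
}

.enrich_over <- function(units, unit_of_branch, is_fd, alpha, yates) {
  o_all <- sum(is_fd)
  t_all <- length(is_fd)
  rows <- lapply(units, function(u) {
    sel <- unit_of_branch == u
    r <- unit_enrichment(sum(is_fd[sel]), sum(sel), o_all, t_all,
                         alpha = alpha, yates = yates)
    data.frame(unit = u, observed_fd = r$observed, total_tests = r$total,
               expected_fd = r$expected, p_value = r$p_value,
               test = r$test, status = r$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Enrichment of functional divergence by functional category
#'
#' Compares, for each category, the proportion of FD-positive tested
#' branches to the background proportion over all categories, with a 2x2
#' Yates-corrected chi-squared test (Fisher fallback for small expected
#' counts).
#'
#' @param branches a branch table ([branch_table()]) or list of scans.
#' @param alpha significance level (default 0.05).
#' @param yates apply the Yates continuity correction (default TRUE).
#' @return data.frame with one row per category: `category`,
#'   `observed_fd`, `total_tests`, `expected_fd`, `p_value`, `test`,
#'   `status` (enriched / impoverished / neither / no-data).
#' @export
enrich_by_category <- function(branches, alpha = 0.05, yates = TRUE) {
  if (!is.data.frame(branches)) branches <- branch_table(branches)
  out <- .enrich_over(sort(unique(branches$category)), branches$category,
                      branches$is_fd, alpha, yates)
  names(out)[1L] <- "category"
  out
}

## explode the comma-joined species column into (branch index, species)
.species_long <- function(branches) {
  sp <- strsplit(branches$species, ",", fixed = TRUE)
  data.frame(branch = rep(seq_len(nrow(branches)), lengths(sp)),
             species = unlist(sp), stringsAsFactors = FALSE)
}

#' Enrichment of functional divergence by species
#'
#' Each tested branch is attributed to every species with at least one
#' sequence in either of the node's two clades (outgroup members are not
#' attributed).  Per species, the proportion of FD-positive attributed
#' branches is compared to the background over all attributions.
#'
#' @inheritParams enrich_by_category
#' @return data.frame as in [enrich_by_category()], keyed by `species`.
#' @export
enrich_by_species <- function(branches, alpha = 0.05, yates = TRUE) {
  if (!is.data.frame(branches)) branches <- branch_table(branches)
  long <- .species_long(branches)
  is_fd <- branches$is_fd[long$branch]
  out <- .enrich_over(sort(unique(long$species)), long$species, is_fd,
                      alpha, yates)
  names(out)[1L] <- "species"
  out
}

#' Enrichment status of each functional category within each species
#'
#' The cross of the category and species attributions: for every
#' (species, category) pair with at least one attributed test, a 2x2 test
#' against the overall background.  The resulting status grid is the
#' input to [status_matrix()] and [cluster_matrix()].
#'
#' @inheritParams enrich_by_category
#' @return data.frame with `species`, `category`, `observed_fd`,
#'   `total_tests`, `expected_fd`, `p_value`, `test`, `status`.
#' @export
enrich_species_by_category <- function(branches, alpha = 0.05, yates = TRUE) {
  if (!is.data.frame(branches)) branches <- branch_table(branches)
  long <- .species_long(branches)
  long$category <- branches$category[long$branch]
  long$is_fd <- branches$is_fd[long$branch]
  key <- paste(long$species, long$category, sep = "\r")
  out <- .enrich_over(sort(unique(key)), key, long$is_fd, alpha, yates)
  parts <- strsplit(out$unit, "\r", fixed = TRUE)
  out$unit <- NULL
  cbind(data.frame(species = vapply(parts, `[`, "", 1L),
                   category = vapply(parts, `[`, "", 2L),
                   stringsAsFactors = FALSE),
        out)
}

#' Association between lifestyle and enrichment status
#'
#' Builds the 2 x 3 contingency table of species counts over the status
#' levels (enriched, neither, impoverished) for a focal lifestyle against
#' a comparison lifestyle, and tests it with a Yates-corrected
#' chi-squared test, switching to Fisher's exact test when any expected
#' cell is below 5 (exact enumeration up to a table total of 1000,
#' Monte-Carlo beyond).  When the association is
#' significant the direction reports whether the focal lifestyle is
#' shifted towards enrichment (`"+"`) or impoverishment (`"-"`).
#'
#' @param status named character vector of per-species enrichment status
#'   (`"enriched"`, `"neither"`, `"impoverished"`; typically the `status`
#'   column of [enrich_by_species()] named by species).  Species with
#'   status `"no-data"` are dropped.
#' @param lifestyle_of named character vector mapping species to a
#'   lifestyle label.
#' @param lifestyle focal lifestyle label(s).
#' @param comparison comparison lifestyle label(s).
#' @param alpha significance level (default 0.05).
#' @return a `lifestyle_table`: list with the 2 x 3 `table`, `expected`
#'   counts, `test` used, `statistic` (chi-squared only), `p_value`,
#'   `significant`, `direction`.
#' @export
lifestyle_association <- function(status, lifestyle_of, lifestyle, comparison,
                                  alpha = 0.05) {
  status <- status[!is.na(status) & status != "no-data"]
  common <- intersect(names(status), names(lifestyle_of))
  status <- status[common]
  ls <- lifestyle_of[common]
  levels <- c("enriched", "neither", "impoverished")
  stopifnot(all(status %in% levels))
  in_focal <- ls %in% lifestyle
  in_comp <- ls %in% comparison
  if (!any(in_focal) || !any(in_comp)) {
    stop("a lifestyle with zero annotated species cannot be tested",
         call. = FALSE)
  }
  tab <- rbind(focal = table(factor(status[in_focal], levels = levels)),
               comparison = table(factor(status[in_comp], levels = levels)))
  keep <- colSums(tab) > 0
  if (sum(keep) < 2L) stop("contingency table has fewer than 2 informative columns")
  tab2 <- tab[, keep, drop = FALSE]
  expected <- outer(rowSums(tab2), colSums(tab2)) / sum(tab2)
  statistic <- NA_real_
  if (any(expected < 5)) {
    if (sum(tab2) <= 1000) {
      p <- stats::fisher.test(tab2)$p.value
      test <- "fisher"
    } else {
      p <- stats::fisher.test(tab2, simulate.p.value = TRUE, B = 1e5)$p.value
      test <- "fisher-mc"
    }
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab2, correct = TRUE))
    p <- ct$p.value
    statistic <- unname(ct$statistic)
    test <- "chi-squared"
  }
  direction <- NA_character_
  if (p < alpha) {
    expected_full <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    d <- (tab["focal", "enriched"] - expected_full["focal", "enriched"]) -
      (tab["focal", "impoverished"] - expected_full["focal", "impoverished"])
    direction <- if (d > 0) "+" else "-"
  }
  structure(list(table = tab, expected = expected, test = test,
                 statistic = statistic, p_value = p,
                 significant = p < alpha, direction = direction),
            class = "lifestyle_table")
}

#' @export
print.lifestyle_table <- function(x, ...) {
  print(x$table)
  cat(x$test, "p =", signif(x$p_value, 4),
      if (x$significant) paste0("(significant, ", x$direction, ")")
      else "(N.S.)", "\n")
  invisible(x)
}
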