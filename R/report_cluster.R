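## Status-matrix construction, two-dimensional hierarchical clustering,
## and heatmap / TSV rendering.

#' Build the species x category status matrix
#'
#' Encodes enrichment statuses numerically: enriched = +1, neither = 0,
#' impoverished = -1, no-data = `NA`.
#'
#' @param cells the data.frame returned by [enrich_species_by_category()]
#'   (columns `species`, `category`, `status`).
#' @return a numeric matrix, rows = species, columns = categories.
#' @export
status_matrix <- function(cells) {
  stopifnot(all(c("species", "category", "status") %in% names(cells)))
  code <- c(enriched = 1, neither = 0, impoverished = -1, "no-data" = NA)
  sp <- sort(unique(cells$species))
  cat <- sort(unique(cells$category))
  m <- matrix(NA_real_, length(sp), length(cat), dimnames = list(sp, cat))
  m[cbind(match(cells$species, sp), match(cells$category, cat))] <-
    code[cells$status]
  m
}

#' Two-dimensional hierarchical clustering of a status matrix
#'
#' Rows (species) and columns (categories) are clustered independently by
#' Euclidean distance with agglomerative linkage (complete by default).
#' Missing cells are imputed as 0 (neither) for distance computation only
#' and reported back.  Rows/columns with no data at all are dropped with
#' a warning.  Labels are sorted before clustering so the result does not
#' depend on input order (ties break by label).
#'
#' @param m a numeric status matrix ([status_matrix()]).
#' @param linkage agglomeration method for [hclust()] (default
#'   `"complete"`).
#' @return list with `row_order` and `col_order` (label vectors),
#'   `row_hclust`, `col_hclust`, the clustered `matrix`, and `imputed`
#'   (logical matrix marking imputed cells).
#' @export
cluster_matrix <- function(m, linkage = "complete") {
  stopifnot(is.matrix(m))
  drop_r <- rowSums(!is.na(m)) == 0
  drop_c <- colSums(!is.na(m)) == 0
  if (any(drop_r)) {
    warning("dropping all-missing rows: ",
            paste(rownames(m)[drop_r], collapse = ", "))
  }
  if (any(drop_c)) {
    warning("dropping all-missing columns: ",
            paste(colnames(m)[drop_c], collapse = ", "))
  }
  m <- m[!drop_r, !drop_c, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("clustering needs at least 2 rows and 2 columns with data",
         call. = FALSE)
  }
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  imputed <- is.na(m)
  mi <- m
  mi[imputed] <- 0
  hr <- stats::hclust(stats::dist(mi, method = "euclidean"), method = linkage)
  hc <- stats::hclust(stats::dist(t(mi), method = "euclidean"), method = linkage)
  list(row_order = rownames(m)[hr$order], col_order = colnames(m)[hc$order],
       row_hclust = hr, col_hclust = hc, matrix = m, imputed = imputed)
}

#' Export a clustering dendrogram as a Newick string
#'
#' @param h an `hclust` object (e.g. `row_hclust` from
#'   [cluster_matrix()]).
#' @param file optional path; when given the tree is written there.
#' @return the Newick string, invisibly when written to file.
#' @export
cluster_newick <- function(h, file = NULL) {
  tr <- ape::as.phylo(h)
  s <- ape::write.tree(tr)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Render the clustered status heatmap
#'
#' Writes a three-colour heatmap (enriched / neither / impoverished, plus
#' a fourth colour for missing cells) with row and column dendrograms,
#' and a TSV of the reordered matrix so the result is inspectable without
#' the image.
#'
#' @param m a status matrix ([status_matrix()]).
#' @param clustering result of [cluster_matrix()]; computed when `NULL`.
#' @param file output image path (`.png` or `.svg`).
#' @param tsv optional path for the reordered-matrix TSV.
#' @param colors length-4 colour vector for (impoverished, neither,
#'   enriched, no-data).
#' @return the clustering, invisibly.
#' @export
render_heatmap <- function(m, clustering = NULL, file, tsv = NULL,
                           colors = c("#4575b4", "#ffffbf", "#d73027",
                                      "#bbbbbb")) {
  if (is.null(clustering)) clustering <- cluster_matrix(m)
  mm <- clustering$matrix[clustering$row_order, clustering$col_order,
                          drop = FALSE]
  if (!is.null(tsv)) {
    utils::write.table(cbind(species = rownames(mm), as.data.frame(mm)),
                       tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") {
    grDevices::svg(file, width = 8, height = 8)
  } else {
    grDevices::png(file, width = 1200, height = 1200, res = 150)
  }
  on.exit(grDevices::dev.off(), add = TRUE)

  graphics::layout(matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE),
                   widths = c(1, 4), heights = c(1, 4))
  op <- graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  on.exit(graphics::par(op), add = TRUE)
  plot(stats::as.dendrogram(clustering$col_hclust), axes = FALSE,
       leaflab = "none", xaxs = "i")
  graphics::par(mar = c(4, 0.5, 0.5, 0.5))
  plot(stats::as.dendrogram(clustering$row_hclust), horiz = TRUE,
       axes = FALSE, leaflab = "none", yaxs = "i")
  graphics::par(mar = c(4, 0.5, 0.5, 4))
  z <- t(mm)   # row 1 at the bottom, matching the dendrogram leaf order
  graphics::image(x = seq_len(ncol(mm)), y = seq_len(nrow(mm)), z = z,
                  zlim = c(-1, 1), col = colors[1:3], axes = FALSE,
                  xlab = "", ylab = "", useRaster = FALSE)
  if (anyNA(z)) {
    na_idx <- which(is.na(z), arr.ind = TRUE)
    graphics::rect(na_idx[, 1] - 0.5, na_idx[, 2] - 0.5,
                   na_idx[, 1] + 0.5, na_idx[, 2] + 0.5,
                   col = colors[4], border = NA)
  }
  graphics::axis(1, at = seq_len(ncol(mm)), labels = colnames(mm), las = 2,
                 cex.axis = 0.7, tick = FALSE)
  graphics::axis(4, at = seq_len(nrow(mm)), labels = rownames(mm),
                 las = 2, cex.axis = 0.5, tick = FALSE)
  invisible(clustering)
}
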