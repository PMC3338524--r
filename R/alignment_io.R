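## Reading, validating and filtering aligned protein homolog groups.

#' Construct an alignment group in memory
#'
#' An alignment group is an aligned set of homologous protein sequences
#' together with a species and a functional-category annotation for every
#' sequence.  All downstream stages (filtering, tree building, the
#' divergence scan) operate on this container.
#'
#' @param sequences named character vector of aligned sequences (equal
#'   length, residues from the 20-letter alphabet plus gap `"-"`), or a
#'   character matrix of single letters with rownames.
#' @param species named character vector mapping sequence id to species.
#' @param category named character vector mapping sequence id to a
#'   functional-category tag (single COG-style letter; multi-letter tags
#'   are kept verbatim and counted as multi-tag by [filter_group()]).
#' @param group_id identifier for the group.
#' @param mode `"strict"` rejects ambiguity letters (B, Z, X, U, O, J);
#'   `"permissive"` converts them to gaps.  BLOSUM62 scoring of ambiguity
#'   codes is ill-defined for the divergence statistic, so they are never
#'   scored.
#' @return an object of class `alignment_group` with components
#'   `group_id`, `seq` (character matrix, rows = sequences), `species`,
#'   `category`.
#' @export
alignment_group <- function(sequences, species, category,
                            group_id = "group",
                            mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  if (is.matrix(sequences)) {
    m <- sequences
  } else {
    if (is.null(names(sequences))) stop("sequences must be named")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "),
           call. = FALSE)
    }
    m <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(m) <- names(sequences)
  }
  if (is.null(rownames(m))) stop("sequences must be named")
  if (anyDuplicated(rownames(m))) stop("duplicated sequence ids")
  if (ncol(m) < 1L) stop("alignment must have at least one column")

  bad <- !(m %in% c(.AA, .GAP))
  if (any(bad)) {
    letters_bad <- unique(m[bad])
    if (mode == "permissive" && all(letters_bad %in% .AA_AMBIGUOUS)) {
      m[bad] <- .GAP
    } else {
      stop("alphabet error: illegal letter(s) ",
           paste(letters_bad, collapse = ", "),
           " (strict mode accepts the 20 standard amino acids and '-')",
           call. = FALSE)
    }
  }

  ids <- rownames(m)
  miss <- setdiff(ids, names(species))
  if (length(miss)) {
    stop("annotation error: no species for ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  miss <- setdiff(ids, names(category))
  if (length(miss)) {
    stop("annotation error: no category for ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(list(group_id = group_id, seq = m,
                 species = species[ids], category = toupper(category[ids])),
            class = "alignment_group")
}

#' @export
print.alignment_group <- function(x, ...) {
  cat("alignment group '", x$group_id, "': ", nrow(x$seq), " sequences x ",
      ncol(x$seq), " columns, ", length(unique(x$species)), " species\n",
      sep = "")
  invisible(x)
}

#' Read an aligned FASTA file with its annotation table
#'
#' @param path path to an aligned FASTA file (gap character `"-"`).
#' @param annotations path to a tab-separated table with header columns
#'   `seq_id`, `species`, `category`, covering every sequence in the
#'   alignment (extra rows are ignored).
#' @param group_id group identifier; defaults to the FASTA file name
#'   without extension.
#' @inheritParams alignment_group
#' @return an [alignment_group()]; sequence order is preserved from the
#'   file.
#' @export
read_alignment <- function(path, annotations, group_id = NULL,
                           mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  ss <- Biostrings::readBStringSet(path)   # BStringSet: validate ourselves
  if (length(ss) < 1L) stop("empty FASTA file: ", path)
  w <- Biostrings::width(ss)
  if (length(unique(w)) != 1L) {
    stop("ragged alignment in ", path, ": lengths ",
         paste(sort(unique(w)), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  ann <- read_annotations(annotations)
  if (is.null(group_id)) {
    group_id <- tools::file_path_sans_ext(basename(path))
  }
  alignment_group(seqs,
                  species = ann$species, category = ann$category,
                  group_id = group_id, mode = mode)
}

#' Read a sequence annotation table
#'
#' @param path tab-separated file with header `seq_id`, `species`,
#'   `category`.
#' @return a list with named character vectors `species` and `category`.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character")
  need <- c("seq_id", "species", "category")
  if (!all(need %in% names(tab))) {
    stop("annotation table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$seq_id)) stop("duplicated seq_id in annotations")
  list(species = stats::setNames(tab$species, tab$seq_id),
       category = stats::setNames(tab$category, tab$seq_id))
}

#' Write an alignment group as canonical FASTA (one line per sequence)
#'
#' @param group an [alignment_group()].
#' @param path output file.
#' @export
write_alignment <- function(group, path) {
  stopifnot(inherits(group, "alignment_group"))
  lines <- rbind(paste0(">", rownames(group$seq)),
                 apply(group$seq, 1L, paste, collapse = ""))
  writeLines(as.vector(lines), path)
  invisible(path)
}

#' Write an annotation table for one or more groups
#'
#' @param groups a list of [alignment_group()] objects (or a single one).
#' @param path output TSV file.
#' @export
write_annotations <- function(groups, path) {
  if (inherits(groups, "alignment_group")) groups <- list(groups)
  tab <- do.call(rbind, lapply(groups, function(g) {
    data.frame(seq_id = rownames(g$seq), species = unname(g$species),
               category = unname(g$category), stringsAsFactors = FALSE)
  }))
  tab <- tab[!duplicated(tab$seq_id), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a homolog group for the divergence scan
#'
#' A group enters the scan only when it is large enough to contain a
#' testable node (two clades of four plus an outgroup, i.e. at least nine
#' sequences), all its sequences carry one and the same functional tag,
#' and that tag is not one of the poorly characterised catch-all
#' categories (R, S by default).
#'
#' @param group an [alignment_group()].
#' @param min_sequences minimum number of sequences (default 9).
#' @param excluded_categories tags excluded as ambiguous (default R, S).
#' @return a `group_filter_report`: list with `group_id`, `n_sequences`,
#'   `n_distinct_tags`, `modal_tag`, `modal_tag_frequency`, `passed`,
#'   `failure_reasons`.
#' @export
filter_group <- function(group, min_sequences = 9,
                         excluded_categories = c("R", "S")) {
  stopifnot(inherits(group, "alignment_group"))
  n <- nrow(group$seq)
  tags <- group$category
  letters <- strsplit(tags, "")
  all_letters <- unlist(letters)
  tag_counts <- sort(table(all_letters), decreasing = TRUE)
  modal <- names(tag_counts)[order(-tag_counts, names(tag_counts))][1L]
  modal_freq <- sum(tags == modal) / n   # sequences tagged exactly the modal letter
  single_tag <- all(lengths(letters) == 1L) && length(tag_counts) == 1L

  reasons <- character(0)
  if (n < min_sequences) reasons <- c(reasons, "too-few-sequences")
  if (!single_tag) reasons <- c(reasons, "multi-tag")
  if (single_tag && modal %in% excluded_categories) {
    reasons <- c(reasons, "excluded-category")
  }
  structure(list(group_id = group$group_id,
                 n_sequences = n,
                 n_distinct_tags = length(tag_counts),
                 modal_tag = modal,
                 modal_tag_frequency = modal_freq,
                 passed = length(reasons) == 0L,
                 failure_reasons = reasons),
            class = "group_filter_report")
}

#' @export
print.group_filter_report <- function(x, ...) {
  cat("group '", x$group_id, "': ", x$n_sequences, " sequences, modal tag ",
      x$modal_tag, " (", round(100 * x$modal_tag_frequency, 1), "%) -> ",
      if (x$passed) "PASS" else paste("FAIL:", paste(x$failure_reasons, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

#' Gap profile of an alignment group
#'
#' The neutral alignments used for significance calibration are simulated
#' gap-free, with the number of columns equal to the alignment length
#' minus the mean per-sequence gap count (rounded half-to-even).
#'
#' @param group an [alignment_group()].
#' @return list with `per_sequence` gap counts, `mean` gap count, and the
#'   integer `simulated_length`.
#' @export
gap_profile <- function(group) {
  stopifnot(inherits(group, "alignment_group"))
  per_seq <- rowSums(group$seq == .GAP)
  m <- mean(per_seq)
  list(per_sequence = per_seq, mean = m,
       simulated_length = as.integer(ncol(group$seq) - round(m)))
}
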