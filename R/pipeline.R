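## End-to-end orchestration: configuration, the directory-level scan,
## result tables, and the run manifest.

#' Configuration for a full functional-divergence run
#'
#' @param input_dir directory containing aligned FASTA files (`.fasta`,
#'   `.fa`, one homolog group per file).
#' @param annotations TSV with columns `seq_id`, `species`, `category`
#'   covering all sequences.
#' @param output_dir where result tables and figures are written.
#' @param alpha FDR / significance level (default 0.05).
#' @param gamma_shape,n_categories discrete-gamma model (defaults 1.0, 4).
#' @param min_sequences minimum group size (default 9).
#' @param min_clade,min_outgroup node-testability thresholds (4, 1).
#' @param excluded_categories tags excluded from analysis (R, S).
#' @param null_min,null_batch,null_cap,null_tol null-calibration controls
#'   (defaults 1000, 100, 10000, 1e-6), see [calibrate_null()].
#' @param seed master seed; per-group streams are derived with
#'   [derive_seed()], so results do not depend on processing order.
#' @param lifestyle optional TSV with columns `species`, `lifestyle`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input_dir, annotations, output_dir,
                       alpha = 0.05, gamma_shape = 1.0, n_categories = 4L,
                       min_sequences = 9L, min_clade = 4L, min_outgroup = 1L,
                       excluded_categories = c("R", "S"),
                       null_min = 1000L, null_batch = 100L,
                       null_cap = 10000L, null_tol = 1e-6,
                       seed = 1L, lifestyle = NULL) {
  stopifnot(alpha > 0, alpha < 1, gamma_shape > 0, n_categories >= 1,
            min_sequences >= 1, min_clade >= 1, min_outgroup >= 1,
            null_min >= 1, null_batch >= 1, null_cap >= null_min,
            null_tol > 0)
  structure(list(input_dir = input_dir, annotations = annotations,
                 output_dir = output_dir, alpha = alpha,
                 gamma_shape = gamma_shape,
                 n_categories = as.integer(n_categories),
                 min_sequences = as.integer(min_sequences),
                 min_clade = as.integer(min_clade),
                 min_outgroup = as.integer(min_outgroup),
                 excluded_categories = excluded_categories,
                 null_min = as.integer(null_min),
                 null_batch = as.integer(null_batch),
                 null_cap = as.integer(null_cap), null_tol = null_tol,
                 seed = as.integer(seed), lifestyle = lifestyle),
            class = "run_config")
}

#' Run the full functional-divergence pipeline over a group directory
#'
#' Reads and filters every group, builds its gene tree, scans all
#' testable nodes with null calibration and per-node FDR, aggregates
#' branch calls into category / species / category-within-species
#' enrichment tables, clusters the status matrix, and writes all result
#' TSVs, the heatmap and a run manifest into the output directory.
#' Groups that fail filters are reported, not fatal; a group-level error
#' is logged and quarantined without aborting the run.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a result bundle: list with `scans`, `filter_report`,
#'   `branches`, `sites`, `enrichment` (category / species / cells),
#'   `status`, `clustering`, `lifestyle`, `quarantined`, `manifest`.
#' @export
run_scan <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  files <- sort(list.files(config$input_dir, pattern = "\\.(fasta|fa)$",
                           full.names = TRUE))
  if (!length(files)) stop("no FASTA files in ", config$input_dir, call. = FALSE)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  model <- rate_model(config$gamma_shape, config$n_categories)

  reports <- list(); scans <- list(); quarantined <- list()
  for (f in files) {
    gid <- tools::file_path_sans_ext(basename(f))
    res <- tryCatch({
      group <- read_alignment(f, config$annotations, group_id = gid)
      rep <- filter_group(group, config$min_sequences,
                          config$excluded_categories)
      reports[[gid]] <- rep
      if (rep$passed) {
        say("scanning ", gid)
        scans[[gid]] <- suppressWarnings(
          scan_group(group, model,
                     seed = derive_seed(config$seed, gid),
                     alpha = config$alpha,
                     min_clade = config$min_clade,
                     min_outgroup = config$min_outgroup,
                     n_min = config$null_min,
                     batch_size = config$null_batch,
                     max_replicates = config$null_cap,
                     tol = config$null_tol))
      }
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) {
      quarantined[[gid]] <- res
      say("quarantined ", gid, ": ", res)
    }
  }
  if (!length(scans)) stop("no group passed the filters", call. = FALSE)

  filter_report <- do.call(rbind, lapply(reports, function(r) {
    data.frame(group_id = r$group_id, n_sequences = r$n_sequences,
               n_distinct_tags = r$n_distinct_tags, modal_tag = r$modal_tag,
               modal_tag_frequency = r$modal_tag_frequency, passed = r$passed,
               failure_reasons = paste(r$failure_reasons, collapse = ";"))
  }))
  branches <- branch_table(scans)
  sites <- do.call(rbind, Filter(Negate(is.null),
                                 lapply(scans, function(s) s$sites)))
  enr_cat <- enrich_by_category(branches, config$alpha)
  enr_sp <- enrich_by_species(branches, config$alpha)
  cells <- enrich_species_by_category(branches, config$alpha)
  status <- status_matrix(cells)

  clustering <- NULL
  if (nrow(status) >= 2 && ncol(status) >= 2) {
    clustering <- tryCatch(cluster_matrix(status), error = function(e) NULL)
    if (!is.null(clustering)) {
      render_heatmap(status, clustering,
                     file = file.path(config$output_dir, "status_heatmap.png"),
                     tsv = file.path(config$output_dir, "status_matrix_ordered.tsv"))
    }
  }

  life <- NULL
  if (!is.null(config$lifestyle) && file.exists(config$lifestyle)) {
    lt <- utils::read.delim(config$lifestyle, colClasses = "character")
    if (all(c("species", "lifestyle") %in% names(lt)) &&
        length(unique(lt$lifestyle)) >= 2) {
      status_by_sp <- stats::setNames(enr_sp$status, enr_sp$species)
      lf <- stats::setNames(lt$lifestyle, lt$species)
      lv <- sort(unique(lf))
      life <- tryCatch(
        lifestyle_association(status_by_sp, lf, lv[1L], lv[-1L],
                              alpha = config$alpha),
        error = function(e) NULL)
    }
  }

  wt <- function(x, name) {
    utils::write.table(x, file.path(config$output_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(filter_report, "filter_report.tsv")
  wt(branches, "branches.tsv")
  wt(sites, "sites.tsv")
  wt(enr_cat, "enrichment_category.tsv")
  wt(enr_sp, "enrichment_species.tsv")
  wt(cells, "enrichment_cells.tsv")
  wt(cbind(species = rownames(status), as.data.frame(status)),
     "status_matrix.tsv")
  manifest <- list(package = "fdscan",
                   version = as.character(utils::packageVersion("fdscan")),
                   r_version = R.version.string,
                   config = unclass(config)[setdiff(names(config), "lifestyle")],
                   n_groups = length(files), n_scanned = length(scans),
                   n_quarantined = length(quarantined))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(scans = scans, filter_report = filter_report,
                 branches = branches, sites = sites,
                 enrichment = list(category = enr_cat, species = enr_sp,
                                   cells = cells),
                 status = status, clustering = clustering, lifestyle = life,
                 quarantined = quarantined, manifest = manifest))
}
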