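#' Pipeline configuration
#'
#' Collects the file paths and options of a full annotation/comparison
#' run.  A configuration can also be loaded from JSON with
#' [read_pipeline_config()]; keys mirror the argument names.
#'
#' @param fasta_a path to the reference-species protein FASTA (required).
#' @param fasta_b optional path to the target-species FASTA; enables the
#'   comparative stages.
#' @param ortholog_map optional path to a two-column TSV pairing reference
#'   and target IDs.  Required when `compare = TRUE`.
#' @param classes_file optional JSON residue-class table overriding the
#'   default.
#' @param out_dir output directory (created if missing).
#' @param species length-2 character vector of species labels.
#' @param compare build the comparative report (default: `TRUE` when
#'   `fasta_b` is given).
#' @param pts2_mode `"relaxed"` or `"strict"` PTS2 matching.
#' @param pts2_window,allow_internal_pts2,internal_min_offset,internal_max_offset,offset_convention
#'   annotation options; see [annotation_options()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta_a, fasta_b = NULL, ortholog_map = NULL,
                            classes_file = NULL, out_dir = ".",
                            species = c("speciesA", "speciesB"),
                            compare = !is.null(fasta_b),
                            pts2_mode = "relaxed", pts2_window = 40L,
                            allow_internal_pts2 = FALSE,
                            internal_min_offset = 1L,
                            internal_max_offset = 50L,
                            offset_convention = "after") {
  if (missing(fasta_a) || is.null(fasta_a))
    stop("configuration error: fasta_a is required", call. = FALSE)
  if (!file.exists(fasta_a))
    stop("configuration error: FASTA not found: ", fasta_a, call. = FALSE)
  if (!is.null(fasta_b) && !file.exists(fasta_b))
    stop("configuration error: FASTA not found: ", fasta_b, call. = FALSE)
  if (isTRUE(compare) && is.null(fasta_b))
    stop("configuration error: compare requested but fasta_b missing",
         call. = FALSE)
  if (isTRUE(compare) && is.null(ortholog_map))
    stop("configuration error: compare requested but ortholog map missing",
         call. = FALSE)
  if (!is.null(ortholog_map) && !file.exists(ortholog_map))
    stop("configuration error: ortholog map not found: ", ortholog_map,
         call. = FALSE)
  if (!is.null(classes_file) && !file.exists(classes_file))
    stop("configuration error: residue-class file not found: ",
         classes_file, call. = FALSE)
  structure(list(fasta_a = fasta_a, fasta_b = fasta_b,
                 ortholog_map = ortholog_map, classes_file = classes_file,
                 out_dir = out_dir, species = species,
                 compare = isTRUE(compare), pts2_mode = pts2_mode,
                 options = annotation_options(
                   pts2_window, allow_internal_pts2, internal_min_offset,
                   internal_max_offset, offset_convention)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from JSON
#'
#' @param path JSON file whose keys mirror [pipeline_config()] arguments.
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("configuration error: unknown key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, cfg)
}

pipeline_log <- function(...) message("[peroscan] ", sprintf(...))

pts2_sites_of <- function(annotations) {
  det <- attr(annotations, "details")
  sites <- vapply(det, function(d) {
    m <- d$pts2_matches[!d$pts2_matches$internal, , drop = FALSE]
    if (nrow(m) == 0) NA_character_
    else m$nonapeptide[which.min(m$n_deviations)]
  }, character(1))
  sites[!is.na(sites)]
}

#' Run the full annotation pipeline
#'
#' Reads the configured FASTA file(s), annotates each proteome, writes
#' per-species annotation TSVs and PTS2 propensity TSVs, and -- when
#' comparison is enabled -- the comparative report (JSON + TSV).  Progress
#' counts are logged via [message()].
#'
#' @param config a [pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @return Invisible named list of the written file paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  classes <- if (is.null(config$classes_file)) pts1_residue_classes()
             else read_pts1_classes(config$classes_file)
  consensus <- pts2_consensus(mode = config$pts2_mode)
  paths <- list()

  annotate_one <- function(fasta_path, label) {
    fa <- read_fasta(fasta_path)
    pipeline_log("%s: %d record(s) read from %s", label, nrow(fa),
                 fasta_path)
    ann <- annotate_proteome(fa, classes, consensus, config$options)
    p <- file.path(config$out_dir, paste0("annotation_", label, ".tsv"))
    write_annotations(ann, p)
    paths[[paste0("annotation_", label)]] <<- p
    sites <- pts2_sites_of(ann)
    if (length(sites) > 0) {
      pt <- compute_propensity(sites)
      pp <- file.path(config$out_dir, paste0("propensity_", label, ".tsv"))
      utils::write.table(pt$table, pp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths[[paste0("propensity_", label)]] <<- pp
    }
    pipeline_log("%s: %d PTS2, %d canonical PTS1, %d non-canonical PTS1",
                 label, sum(ann$summary_category == "PTS2"),
                 sum(ann$summary_category == "PTS1_canonical"),
                 sum(ann$summary_category == "PTS1_noncanonical"))
    ann
  }

  ann_a <- annotate_one(config$fasta_a, config$species[1])
  if (!is.null(config$fasta_b)) {
    ann_b <- annotate_one(config$fasta_b, config$species[2])
    if (config$compare) {
      map <- read_ortholog_map(config$ortholog_map)
      summ <- compare_proteomes(ann_a, ann_b, config$species, map)
      jp <- file.path(config$out_dir, "comparative_report.json")
      tp <- file.path(config$out_dir, "comparative_report.tsv")
      build_report(summ, jp, tp)
      paths$report_json <- jp
      paths$report_tsv <- tp
      pipeline_log("comparison: %d shared non-canonical tripeptide(s), %d orphan(s)",
                   length(summ$shared_noncanonical), length(summ$orphans))
    }
  }
  invisible(paths)
}
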