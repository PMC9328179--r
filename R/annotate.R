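#' Annotation options
#'
#' Bundles the tunable scan parameters used by [annotate_protein()] and
#' [annotate_proteome()].
#'
#' @param pts2_window number of N-terminal start positions scanned for PTS2
#'   sites (default 40).
#' @param allow_internal_pts2 also scan the rest of the sequence for PTS2,
#'   flagging internal matches (default `FALSE`).
#' @param internal_min_offset,internal_max_offset end-offset range for the
#'   internal PTS1 scan (default 1..50).
#' @param offset_convention internal-PTS1 offset convention; see
#'   [scan_internal_pts1()].
#' @return A list of class `annotation_options`.
#' @export
annotation_options <- function(pts2_window = 40L, allow_internal_pts2 = FALSE,
                               internal_min_offset = 1L,
                               internal_max_offset = 50L,
                               offset_convention = c("after", "between")) {
  offset_convention <- match.arg(offset_convention)
  stopifnot(pts2_window >= 1, internal_min_offset >= 1,
            internal_max_offset >= internal_min_offset)
  structure(list(pts2_window = as.integer(pts2_window),
                 allow_internal_pts2 = isTRUE(allow_internal_pts2),
                 internal_min_offset = as.integer(internal_min_offset),
                 internal_max_offset = as.integer(internal_max_offset),
                 offset_convention = offset_convention),
            class = "annotation_options")
}

summary_category_from <- function(pts1_label, has_nterm_pts2, has_internal) {
  if (has_nterm_pts2) return("PTS2")
  if (pts1_label == "canonical") return("PTS1_canonical")
  if (pts1_label == "non_canonical") return("PTS1_noncanonical")
  if (has_internal) return("internal_PTS")
  "none"
}

#' Annotate a single protein
#'
#' Runs the three scans on one sequence -- terminal PTS1 classification,
#' internal PTS1 motif scan, PTS2 nonapeptide scan -- and assigns a summary
#' category by precedence: `PTS2` if any non-internal PTS2 site matches;
#' else `PTS1_canonical` / `PTS1_noncanonical` from the terminal tripeptide;
#' else `internal_PTS` if any internal PTS1 hit; else `none`.  A protein
#' with both an N-terminal PTS2 and a canonical or non-canonical terminal
#' PTS1 keeps all evidence and is flagged `dual_signal`, with PTS2 taking
#' precedence in the summary.
#'
#' @param sequence amino-acid string (>= 3 residues after stop stripping).
#' @param id optional protein identifier carried into the result.
#' @param classes a [pts1_classes] table.
#' @param consensus a [pts2_consensus].
#' @param options an [annotation_options] list.
#' @return A list of class `protein_annotation` with elements `id`,
#'   `length`, `terminal` (one-row [classify_pts1()] result),
#'   `internal_hits`, `pts2_matches`, `summary_category`, `dual_signal`.
#' @export
annotate_protein <- function(sequence, id = NA_character_,
                             classes = pts1_residue_classes(),
                             consensus = pts2_consensus(),
                             options = annotation_options()) {
  s <- sub("\\*$", "", toupper(sequence))
  terminal <- classify_pts1(extract_tripeptide(s), classes)
  internal <- scan_internal_pts1(
    s, classes, options$internal_min_offset, options$internal_max_offset,
    options$offset_convention)
  pts2 <- scan_pts2(s, consensus, options$pts2_window,
                    options$allow_internal_pts2)
  has_nterm_pts2 <- any(!pts2$internal)
  category <- summary_category_from(terminal$label, has_nterm_pts2,
                                    nrow(internal) > 0)
  dual <- has_nterm_pts2 &&
    terminal$label %in% c("canonical", "non_canonical")
  structure(list(id = id, length = nchar(s), terminal = terminal,
                 internal_hits = internal, pts2_matches = pts2,
                 summary_category = category, dual_signal = dual),
            class = "protein_annotation")
}

#' @export
print.protein_annotation <- function(x, ...) {
  cat(sprintf("Protein %s (%d aa): %s\n",
              ifelse(is.na(x$id), "<unnamed>", x$id), x$length,
              x$summary_category))
  cat(sprintf("  terminal tripeptide %s> [%s]\n", x$terminal$tripeptide,
              x$terminal$label))
  if (nrow(x$pts2_matches) > 0)
    cat(sprintf("  PTS2 site(s): %s\n",
                paste(sprintf("%s@%d%s", x$pts2_matches$nonapeptide,
                              x$pts2_matches$start,
                              ifelse(x$pts2_matches$internal,
                                     " (internal)", "")),
                      collapse = ", ")))
  if (nrow(x$internal_hits) > 0)
    cat(sprintf("  internal PTS1: %s\n",
                paste(sprintf("%s-%d", x$internal_hits$tripeptide,
                              x$internal_hits$end_offset), collapse = ", ")))
  if (x$dual_signal) cat("  dual signal (PTS2 + terminal PTS1)\n")
  invisible(x)
}

format_internal_hits <- function(hits) {
  if (nrow(hits) == 0) return(".")
  paste(sprintf("%s-%d", hits$tripeptide, hits$end_offset), collapse = ";")
}

annotation_row <- function(ann) {
  nterm <- ann$pts2_matches[!ann$pts2_matches$internal, , drop = FALSE]
  best <- if (nrow(nterm) > 0) nterm[which.min(nterm$n_deviations), ]
          else if (nrow(ann$pts2_matches) > 0)
            ann$pts2_matches[which.min(ann$pts2_matches$n_deviations), ]
          else NULL
  data.frame(
    id = ann$id,
    length = ann$length,
    terminal_tripeptide = ann$terminal$tripeptide,
    pts1_label = ann$terminal$label,
    low_position = ann$terminal$low_position,
    pts2_best_start = if (is.null(best)) NA_integer_ else best$start,
    pts2_deviations = if (is.null(best)) "." else best$deviations,
    internal_hits = format_internal_hits(ann$internal_hits),
    summary_category = ann$summary_category,
    dual_signal = ann$dual_signal,
    stringsAsFactors = FALSE)
}

#' Annotate a whole proteome
#'
#' Applies [annotate_protein()] to every record, preserving input order.
#'
#' @param fasta either a data frame with columns `id` and `sequence` (as
#'   returned by [read_fasta()]) or a named character vector of sequences.
#' @inheritParams annotate_protein
#' @return A data frame of class `pts_annotation`, one row per protein,
#'   with columns `id`, `length`, `terminal_tripeptide`, `pts1_label`,
#'   `low_position`, `pts2_best_start`, `pts2_deviations`, `internal_hits`
#'   (semicolon-joined `motif-offset` tokens), `summary_category`,
#'   `dual_signal`.  The full per-protein annotations are attached as the
#'   `"details"` attribute.
#' @export
annotate_proteome <- function(fasta, classes = pts1_residue_classes(),
                              consensus = pts2_consensus(),
                              options = annotation_options()) {
  if (is.character(fasta))
    fasta <- data.frame(id = names(fasta), sequence = unname(fasta),
                        stringsAsFactors = FALSE)
  stopifnot(is.data.frame(fasta), all(c("id", "sequence") %in% names(fasta)))
  dup <- unique(fasta$id[duplicated(fasta$id)])
  if (length(dup) > 0)
    stop("duplicate record ID(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  details <- lapply(seq_len(nrow(fasta)), function(i)
    annotate_protein(fasta$sequence[i], fasta$id[i], classes, consensus,
                     options))
  rows <- do.call(rbind, lapply(details, annotation_row))
  if (is.null(rows))
    rows <- annotation_row(annotate_protein("AAASKL", "template",
                                            classes, consensus,
                                            options))[0, ]
  rownames(rows) <- NULL
  structure(rows, details = details,
            class = c("pts_annotation", "data.frame"))
}

#' @export
print.pts_annotation <- function(x, ...) {
  cat(sprintf("PTS annotation of %d protein(s)\n", nrow(x)))
  if (nrow(x) > 0) {
    tab <- table(factor(x$summary_category,
                        levels = c("PTS2", "PTS1_canonical",
                                   "PTS1_noncanonical", "internal_PTS",
                                   "none")))
    for (k in names(tab)) cat(sprintf("  %-18s %d\n", k, tab[[k]]))
  }
  NextMethod()
}

#' Write / read an annotation table as TSV
#'
#' Tab-separated, UTF-8, header row, no quoting; `.` encodes missing
#' values.  Reading back restores column types, so a write/read round trip
#' preserves all fields.
#'
#' @param x a `pts_annotation` data frame.
#' @param path file path.
#' @return `write_annotations` returns `path` invisibly; `read_annotations`
#'   returns a `pts_annotation` data frame.
#' @export
write_annotations <- function(x, path) {
  out <- as.data.frame(x)
  out$low_position[is.na(out$low_position)] <- "."
  out$pts2_best_start[is.na(out$pts2_best_start)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  x$length <- as.integer(x$length)
  x$low_position <- suppressWarnings(
    as.integer(ifelse(x$low_position == ".", NA, x$low_position)))
  x$pts2_best_start <- suppressWarnings(
    as.integer(ifelse(x$pts2_best_start == ".", NA, x$pts2_best_start)))
  x$dual_signal <- as.logical(x$dual_signal)
  structure(x, class = c("pts_annotation", "data.frame"))
}
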