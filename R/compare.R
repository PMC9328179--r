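#' Integer percentage by truncation
#'
#' `floor(100 * canonical / total)` -- truncation, not rounding, which is
#' the convention of the catalogues this package reproduces (74/108 -> 68;
#' 55/97 = 56.7 -> 56, not 57).
#'
#' @param canonical count of canonical-signal proteins.
#' @param total total count (> 0).
#' @return Integer percentage.
#' @export
percent_canonical <- function(canonical, total) {
  if (any(total <= 0))
    stop("total must be > 0", call. = FALSE)
  as.integer(floor(100 * canonical / total))
}

#' Category tallies for one annotated proteome
#'
#' Counts proteins per summary category.  PTS2 proteins (including
#' dual-signal ones, by precedence) are counted apart; the remaining
#' proteins form the PTS1 catalogue, split into canonical, non-canonical
#' and no-obvious (the three no-obvious sub-categories combined).
#' Proteins whose only signal is an internal PTS1 motif -- the catalase
#' pattern -- sit inside the no-obvious count and are additionally broken
#' out as `n_catalase_internal`, with `n_no_pts_strict` the no-obvious
#' count after removing them.
#'
#' @param annotations a [annotate_proteome()] result.
#' @return A list of class `category_tally` with counts `n_total`,
#'   `n_pts2`, `n_pts1_canonical`, `n_pts1_noncanonical`, `n_no_obvious`,
#'   `n_catalase_internal`, `n_no_pts_strict`, `n_pts1_total` and
#'   `pct_canonical` (integer truncation of 100 * canonical / PTS1 total;
#'   `NA` when the PTS1 catalogue is empty).
#' @export
tally_categories <- function(annotations) {
  stopifnot(is.data.frame(annotations))
  a <- annotations
  is_pts2 <- a$summary_category == "PTS2"
  p <- a[!is_pts2, , drop = FALSE]
  n_can <- sum(p$pts1_label == "canonical")
  n_nc <- sum(p$pts1_label == "non_canonical")
  n_no <- sum(grepl("^no_obvious", p$pts1_label))
  n_cat <- sum(p$summary_category == "internal_PTS")
  n_pts1 <- n_can + n_nc + n_no
  structure(list(
    n_total = nrow(a),
    n_pts2 = sum(is_pts2),
    n_pts1_canonical = n_can,
    n_pts1_noncanonical = n_nc,
    n_no_obvious = n_no,
    n_catalase_internal = n_cat,
    n_no_pts_strict = n_no - n_cat,
    n_pts1_total = n_pts1,
    pct_canonical = if (n_pts1 > 0) percent_canonical(n_can, n_pts1)
                    else NA_integer_),
    class = "category_tally")
}

#' @export
print.category_tally <- function(x, ...) {
  cat(sprintf("%d protein(s): %d PTS2; PTS1 catalogue %d = %d canonical + %d non-canonical + %d no-obvious (%d catalase-internal)\n",
              x$n_total, x$n_pts2, x$n_pts1_total, x$n_pts1_canonical,
              x$n_pts1_noncanonical, x$n_no_obvious, x$n_catalase_internal))
  if (!is.na(x$pct_canonical))
    cat(sprintf("  %d%% of PTS1 catalogue canonical\n", x$pct_canonical))
  invisible(x)
}

noncanonical_tripeptides <- function(annotations) {
  a <- annotations[annotations$summary_category != "PTS2" &
                     annotations$pts1_label == "non_canonical", ,
                   drop = FALSE]
  sort(unique(a$terminal_tripeptide))
}

#' Shared and unique non-canonical tripeptide sets of two proteomes
#'
#' @param annotations_a,annotations_b [annotate_proteome()] results for the
#'   two species.
#' @return A list with sorted character vectors `shared`, `unique_a`,
#'   `unique_b` of distinct non-canonical terminal tripeptides.
#' @export
noncanonical_sets <- function(annotations_a, annotations_b) {
  a <- noncanonical_tripeptides(annotations_a)
  b <- noncanonical_tripeptides(annotations_b)
  list(shared = intersect(a, b),
       unique_a = setdiff(a, b),
       unique_b = setdiff(b, a))
}

#' Read a two-column ortholog map
#'
#' Tab-separated file with columns `reference_id` and `target_id`; lines
#' starting with `#` are comments.  A header row is optional and detected
#' by name.
#'
#' @param path file path.
#' @return Data frame with columns `reference_id`, `target_id`; duplicate
#'   pairs are dropped.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path))
    stop("ortholog map not found: ", path, call. = FALSE)
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (ncol(x) < 2)
    stop("ortholog map must have two tab-separated columns", call. = FALSE)
  x <- x[, 1:2]
  names(x) <- c("reference_id", "target_id")
  if (nrow(x) > 0 && x$reference_id[1] == "reference_id")
    x <- x[-1, , drop = FALSE]
  if (any(x$reference_id == "" | x$target_id == ""))
    stop("ortholog map contains empty IDs", call. = FALSE)
  x <- unique(x)
  rownames(x) <- NULL
  x
}

#' Listing of no-obvious tripeptides by sub-category
#'
#' Distinct no-obvious terminal tripeptides ordered by sub-category
#' (i, ii, iii) then alphabetically.
#'
#' @param annotations a [annotate_proteome()] result.
#' @return Data frame with columns `label`, `tripeptide`.
#' @export
no_obvious_listing <- function(annotations) {
  a <- annotations[annotations$summary_category != "PTS2" &
                     grepl("^no_obvious", annotations$pts1_label), ,
                   drop = FALSE]
  d <- unique(data.frame(label = a$pts1_label,
                         tripeptide = a$terminal_tripeptide,
                         stringsAsFactors = FALSE))
  lev <- c("no_obvious_i", "no_obvious_ii", "no_obvious_iii")
  d <- d[order(match(d$label, lev), d$tripeptide), ]
  rownames(d) <- NULL
  d
}

#' Two-species comparative catalogue
#'
#' Combines per-species category tallies, shared/unique non-canonical
#' tripeptide sets, no-obvious sub-category listings, and orphan reference
#' proteins (reference-species entries with no ortholog pair in the map).
#'
#' @param annotations_a,annotations_b annotated proteomes of the reference
#'   and target species.
#' @param species length-2 character vector of species labels.
#' @param ortholog_map optional data frame from [read_ortholog_map()].
#' @return An object of class `comparative_summary`.
#' @export
compare_proteomes <- function(annotations_a, annotations_b,
                              species = c("reference", "target"),
                              ortholog_map = NULL) {
  sets <- noncanonical_sets(annotations_a, annotations_b)
  orphans <- character(0)
  if (!is.null(ortholog_map))
    orphans <- sort(setdiff(annotations_a$id, ortholog_map$reference_id))
  structure(list(
    species = species,
    tally_a = tally_categories(annotations_a),
    tally_b = tally_categories(annotations_b),
    shared_noncanonical = sets$shared,
    unique_noncanonical_a = sets$unique_a,
    unique_noncanonical_b = sets$unique_b,
    no_obvious_a = no_obvious_listing(annotations_a),
    no_obvious_b = no_obvious_listing(annotations_b),
    orphans = orphans),
    class = "comparative_summary")
}

#' @export
print.comparative_summary <- function(x, ...) {
  cat(sprintf("Comparative catalogue: %s vs %s\n", x$species[1],
              x$species[2]))
  cat(sprintf("[%s] ", x$species[1])); print(x$tally_a)
  cat(sprintf("[%s] ", x$species[2])); print(x$tally_b)
  cat(sprintf("shared non-canonical tripeptides (%d): %s\n",
              length(x$shared_noncanonical),
              paste(x$shared_noncanonical, collapse = ", ")))
  cat(sprintf("unique to %s (%d): %s\n", x$species[1],
              length(x$unique_noncanonical_a),
              paste(x$unique_noncanonical_a, collapse = ", ")))
  cat(sprintf("unique to %s (%d): %s\n", x$species[2],
              length(x$unique_noncanonical_b),
              paste(x$unique_noncanonical_b, collapse = ", ")))
  if (length(x$orphans) > 0)
    cat(sprintf("orphan reference proteins (%d): %s\n", length(x$orphans),
                paste(x$orphans, collapse = ", ")))
  invisible(x)
}

tally_row <- function(t, label) {
  data.frame(species = label, n_total = t$n_total, n_pts2 = t$n_pts2,
             n_pts1_canonical = t$n_pts1_canonical,
             n_pts1_noncanonical = t$n_pts1_noncanonical,
             n_no_obvious = t$n_no_obvious,
             n_catalase_internal = t$n_catalase_internal,
             n_no_pts_strict = t$n_no_pts_strict,
             n_pts1_total = t$n_pts1_total,
             pct_canonical = t$pct_canonical, stringsAsFactors = FALSE)
}

#' Serialize a comparative catalogue
#'
#' Writes the catalogue as machine-readable JSON plus a human-readable
#' tally TSV.
#'
#' @param summary a [compare_proteomes()] result.
#' @param json_path,tsv_path output paths.
#' @return Invisible list of the two paths.
#' @export
build_report <- function(summary, json_path, tsv_path) {
  stopifnot(inherits(summary, "comparative_summary"))
  obj <- list(
    species = summary$species,
    tallies = list(unclass(summary$tally_a), unclass(summary$tally_b)),
    shared_noncanonical = summary$shared_noncanonical,
    unique_noncanonical = list(summary$unique_noncanonical_a,
                               summary$unique_noncanonical_b),
    no_obvious = list(summary$no_obvious_a, summary$no_obvious_b),
    orphans = summary$orphans)
  names(obj$tallies) <- summary$species
  names(obj$unique_noncanonical) <- summary$species
  names(obj$no_obvious) <- summary$species
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  tsv <- rbind(tally_row(summary$tally_a, summary$species[1]),
               tally_row(summary$tally_b, summary$species[2]))
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(json = json_path, tsv = tsv_path))
}
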