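#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids (one-letter codes)
#' @keywords internal
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PTS1_POSITIONS <- c("-3", "-2", "-1")

#' Construct a PTS1 residue-class table
#'
#' A PTS1 residue-class table partitions the 20 standard amino acids, at each
#' of the three C-terminal positions (-3, -2, -1), into three classes:
#' \emph{high}-abundance (canonical) residues, \emph{low}-abundance
#' (non-canonical) residues that have been demonstrated in functional PTS1
#' tripeptides but are rare, and \emph{unproven} residues never demonstrated
#' at that position.  The unproven class is implied: it is whatever remains
#' after the high and low sets are removed.
#'
#' @param high named list with elements `"-3"`, `"-2"`, `"-1"`, each a
#'   character vector of one-letter residue codes forming the high-abundance
#'   set at that position.
#' @param low same shape as `high`, giving the low-abundance sets.
#' @return An object of class `pts1_classes`: a list with one element per
#'   position, each holding `high`, `low` and the derived `unproven` set.
#' @seealso [pts1_residue_classes()] for the default table,
#'   [read_pts1_classes()] to load one from JSON.
#' @export
pts1_classes <- function(high, low) {
  for (p in PTS1_POSITIONS) {
    if (is.null(high[[p]]) || is.null(low[[p]]))
      stop("residue-class table must define positions -3, -2 and -1",
           call. = FALSE)
  }
  out <- lapply(PTS1_POSITIONS, function(p) {
    h <- toupper(as.character(high[[p]]))
    l <- toupper(as.character(low[[p]]))
    bad <- setdiff(c(h, l), AA20)
    if (length(bad) > 0)
      stop(sprintf("non-standard residue(s) at position %s: %s",
                   p, paste(bad, collapse = ", ")), call. = FALSE)
    overlap <- intersect(h, l)
    if (length(overlap) > 0)
      stop(sprintf(
        "residue %s listed as both high- and low-abundance at position %s",
        paste(overlap, collapse = ", "), p), call. = FALSE)
    if (length(h) == 0)
      stop(sprintf("high-abundance set at position %s is empty", p),
           call. = FALSE)
    list(high = sort(h), low = sort(l),
         unproven = sort(setdiff(AA20, c(h, l))))
  })
  names(out) <- PTS1_POSITIONS
  structure(out, class = "pts1_classes")
}

#' Default PTS1 residue-class table
#'
#' The default classes reproduce the classification of every tripeptide in
#' the Arabidopsis/tomato peroxisome catalogues this package models:
#' canonical residues follow the plant PTS1 consensus (S/A at -3, K/R at -2,
#' L/M/I at -1); low-abundance residues are those demonstrated, rarely, in
#' functional PTS1s at each position (e.g. N at -2 as in SNL, P at -3 as in
#' PKL, F at -1 as in SRF).  Everything else is unproven.
#'
#' @return A `pts1_classes` object.
#' @examples
#' tab <- pts1_residue_classes()
#' tab[["-3"]]$high   # "A" "S"
#' @export
pts1_residue_classes <- function() {
  pts1_classes(
    high = list("-3" = c("S", "A"),
                "-2" = c("K", "R"),
                "-1" = c("L", "M", "I")),
    low  = list("-3" = c("P", "T", "Q", "I", "V"),
                "-2" = c("N", "S", "T", "Y", "H", "M", "L", "Q", "F", "A"),
                "-1" = c("F", "V", "Y"))
  )
}

#' @export
print.pts1_classes <- function(x, ...) {
  cat("PTS1 residue-class table\n")
  for (p in PTS1_POSITIONS) {
    cat(sprintf("  %2s  high: %-10s low: %s\n", p,
                paste(x[[p]]$high, collapse = ""),
                paste(x[[p]]$low, collapse = "")))
  }
  invisible(x)
}

#' Look up the abundance class of a residue at a PTS1 position
#'
#' Non-standard letters (X, B, Z, U, '*', gaps) are treated as unproven,
#' with a warning.
#'
#' @param residue character vector of single letters.
#' @param position one of -3, -2, -1 (numeric or character).
#' @param classes a `pts1_classes` table.
#' @return character vector of "high", "low" or "unproven".
#' @export
residue_class <- function(residue, position, classes = pts1_residue_classes()) {
  p <- as.character(as.integer(position))
  if (!p %in% PTS1_POSITIONS)
    stop("position must be -3, -2 or -1", call. = FALSE)
  r <- toupper(residue)
  nonstd <- setdiff(unique(r), AA20)
  if (length(nonstd) > 0)
    warning(sprintf("non-standard residue(s) %s treated as unproven",
                    paste(nonstd, collapse = ", ")), call. = FALSE)
  out <- rep("unproven", length(r))
  out[r %in% classes[[p]]$high] <- "high"
  out[r %in% classes[[p]]$low] <- "low"
  out
}

#' Read a PTS1 residue-class table from a JSON file
#'
#' Expected schema: an object with keys `"-3"`, `"-2"`, `"-1"`, each mapping
#' to `{"high": [...], "low": [...]}`.  A residue listed in both classes at
#' one position is rejected.
#'
#' @param path path to a JSON file.
#' @return A validated `pts1_classes` object.
#' @export
read_pts1_classes <- function(path) {
  if (!file.exists(path))
    stop("residue-class file not found: ", path, call. = FALSE)
  parsed <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) stop("cannot parse residue-class file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  if (!is.list(parsed) || is.null(names(parsed)))
    stop("residue-class file '", path,
         "' does not contain a position -> class object", call. = FALSE)
  pts1_classes(high = lapply(parsed, function(x) x$high),
               low  = lapply(parsed, function(x) x$low))
}

#' Write a PTS1 residue-class table to JSON
#'
#' @param classes a `pts1_classes` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pts1_classes <- function(classes, path) {
  stopifnot(inherits(classes, "pts1_classes"))
  obj <- lapply(classes, function(x) list(high = x$high, low = x$low))
  jsonlite::write_json(obj, path, pretty = TRUE)
  invisible(path)
}

# Strict PTS2 consensus: [RK][LVIQ]xx[LVIHQ][LSGAK]x[HQ][LAF]
PTS2_STRICT_SETS <- list(
  c("R", "K"),
  c("L", "V", "I", "Q"),
  NULL,
  NULL,
  c("L", "V", "I", "H", "Q"),
  c("L", "S", "G", "A", "K"),
  NULL,
  c("H", "Q"),
  c("L", "A", "F")
)

#' PTS2 nonapeptide consensus specification
#'
#' The PTS2 signal is a degenerate nonapeptide whose published consensus is
#' \code{[RK][LVIQ]x2[LVIHQ][LSGAK]x[HQ][LAF]} (positions 1..9; x =
#' wildcard).  In `strict` mode a site matches only if every constrained
#' position conforms.  In `relaxed` mode only the anchor positions (default
#' 1, 8 and 9 -- the invariant R/K ... H/Q + terminal L/A/F core) must
#' conform; other non-conforming constrained positions are reported as
#' deviations.  Relaxed mode is the default because observed functional PTS2
#' domains (e.g. RTx5HL, with threonine at position 2) fall outside the
#' strict consensus at non-anchor positions.
#'
#' @param mode `"relaxed"` (default) or `"strict"`.
#' @param anchors integer vector of positions that must conform in relaxed
#'   mode; subset of 1..9.
#' @return An object of class `pts2_consensus`.
#' @export
pts2_consensus <- function(mode = c("relaxed", "strict"), anchors = c(1, 8, 9)) {
  mode <- match.arg(mode)
  anchors <- sort(unique(as.integer(anchors)))
  if (length(anchors) == 0 || any(anchors < 1 | anchors > 9))
    stop("anchors must be a non-empty subset of positions 1..9",
         call. = FALSE)
  structure(list(allowed = PTS2_STRICT_SETS, mode = mode, anchors = anchors),
            class = "pts2_consensus")
}

#' @export
print.pts2_consensus <- function(x, ...) {
  pat <- vapply(x$allowed, function(s)
    if (is.null(s)) "x" else paste0("[", paste(s, collapse = ""), "]"),
    character(1))
  cat("PTS2 consensus ", paste(pat, collapse = ""),
      sprintf("  (mode: %s; anchors: %s)\n", x$mode,
              paste(x$anchors, collapse = ",")), sep = "")
  invisible(x)
}
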