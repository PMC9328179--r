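#' Extract the C-terminal tripeptide of a protein
#'
#' Uppercases the sequence and strips a single trailing stop symbol (`*`)
#' before taking the last three residues.
#'
#' @param sequence amino-acid string (or vector of strings).
#' @return character vector of 3-letter tripeptides, N-to-C order.
#' @examples
#' extract_tripeptide("MDDSAPSKL")  # "SKL"
#' @export
extract_tripeptide <- function(sequence) {
  s <- sub("\\*$", "", toupper(sequence))
  if (any(nchar(s) < 3))
    stop("sequence shorter than 3 residues: cannot extract a C-terminal ",
         "tripeptide", call. = FALSE)
  substring(s, nchar(s) - 2L, nchar(s))
}

PTS1_LABELS <- c("canonical", "non_canonical",
                 "no_obvious_i", "no_obvious_ii", "no_obvious_iii")

# Label from the three per-position classes ("high"/"low"/"unproven"),
# applied in order; the five rules partition all inputs.
pts1_label_from_classes <- function(c3, c2, c1) {
  n_high <- (c3 == "high") + (c2 == "high") + (c1 == "high")
  n_low <- (c3 == "low") + (c2 == "low") + (c1 == "low")
  n_unp <- 3L - n_high - n_low
  ifelse(n_high == 3L, "canonical",
  ifelse(n_low == 1L & n_high == 2L, "non_canonical",
  ifelse(n_unp == 0L & n_low >= 2L, "no_obvious_i",
  ifelse(n_unp == 1L, "no_obvious_ii", "no_obvious_iii"))))
}

#' Classify C-terminal PTS1 tripeptides
#'
#' Assigns each tripeptide one of five labels from the abundance classes of
#' its residues at positions -3, -2 and -1:
#' \describe{
#'   \item{canonical}{all three residues high-abundance (e.g. SKL).}
#'   \item{non_canonical}{exactly one low-abundance residue, the other two
#'     high (e.g. SNL, with N low at -2).}
#'   \item{no_obvious_i}{two or more low-abundance residues, none unproven
#'     (e.g. PML).}
#'   \item{no_obvious_ii}{exactly one unproven residue (e.g. SAK, with K
#'     unproven at -1).}
#'   \item{no_obvious_iii}{two or more unproven residues (e.g. VVA).}
#' }
#' The rules are applied in that order and partition all inputs.
#'
#' @param tripeptide character vector of 3-letter tripeptides (N-to-C).
#' @param classes a [pts1_classes] table; defaults to
#'   [pts1_residue_classes()].
#' @return A data frame of class `pts1_call` with columns `tripeptide`,
#'   `class_m3`, `class_m2`, `class_m1` (per-position abundance class),
#'   `label`, and `low_position` (the position, -3/-2/-1, of the single
#'   low-abundance residue; `NA` except for non-canonical calls).
#' @examples
#' classify_pts1(c("SKL", "SNL", "PML", "SAK", "VVA"))$label
#' @export
classify_pts1 <- function(tripeptide, classes = pts1_residue_classes()) {
  tp <- toupper(as.character(tripeptide))
  if (any(nchar(tp) != 3))
    stop("tripeptides must have exactly 3 residues", call. = FALSE)
  c3 <- residue_class(substring(tp, 1, 1), -3, classes)
  c2 <- residue_class(substring(tp, 2, 2), -2, classes)
  c1 <- residue_class(substring(tp, 3, 3), -1, classes)
  label <- pts1_label_from_classes(c3, c2, c1)
  low_position <- rep(NA_integer_, length(tp))
  nc <- label == "non_canonical"
  low_position[nc & c3 == "low"] <- -3L
  low_position[nc & c2 == "low"] <- -2L
  low_position[nc & c1 == "low"] <- -1L
  structure(
    data.frame(tripeptide = tp, class_m3 = c3, class_m2 = c2, class_m1 = c1,
               label = label, low_position = low_position,
               stringsAsFactors = FALSE),
    class = c("pts1_call", "data.frame"))
}

#' Scan for internal PTS1-like tripeptides
#'
#' Finds every 3-mer upstream of the C-terminus that would itself be a
#' canonical or non-canonical PTS1, reporting its end offset.  Catalase is
#' the motivating case: its import signal is an internal QKL ten residues
#' before the terminus, written "QKL-10>".
#'
#' The offset convention is configurable because the "-N>" notation is used
#' loosely in the literature.  With `offset_convention = "after"` (default)
#' the end offset is the number of residues C-terminal to the motif's last
#' residue, so QKL followed by 10 residues is QKL-10.  With `"between"` it
#' is the count of residues strictly between the motif's last residue and
#' the final residue (one less).
#'
#' @param sequence amino-acid string.
#' @param classes a [pts1_classes] table.
#' @param min_offset,max_offset inclusive end-offset range to report;
#'   defaults 1..50 (observed plant internal PTS offsets are 3, 10 and 13).
#' @param offset_convention `"after"` or `"between"`.
#' @return A data frame with columns `tripeptide`, `end_offset`, `label`
#'   (the motif's PTS1 label) ordered by increasing `end_offset`.  Empty
#'   (zero rows) when the sequence is too short or nothing qualifies.
#' @export
scan_internal_pts1 <- function(sequence, classes = pts1_residue_classes(),
                               min_offset = 1L, max_offset = 50L,
                               offset_convention = c("after", "between")) {
  offset_convention <- match.arg(offset_convention)
  stopifnot(length(sequence) == 1)
  if (min_offset < 1L || max_offset < min_offset)
    stop("need 1 <= min_offset <= max_offset", call. = FALSE)
  s <- sub("\\*$", "", toupper(sequence))
  L <- nchar(s)
  empty <- data.frame(tripeptide = character(0), end_offset = integer(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (L < 3L + min_offset) return(empty)
  shift <- if (offset_convention == "after") 0L else 1L
  # motif ends at position e; end_offset = L - e - shift
  offs <- min_offset:min(max_offset, L - 3L - shift)
  if (length(offs) == 0 || offs[1] > offs[length(offs)]) return(empty)
  ends <- L - offs - shift
  tp <- substring(s, ends - 2L, ends)
  call <- classify_pts1(tp, classes)
  keep <- call$label %in% c("canonical", "non_canonical")
  data.frame(tripeptide = tp[keep], end_offset = as.integer(offs[keep]),
             label = call$label[keep], stringsAsFactors = FALSE)
}
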