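#' Match a single nonapeptide against the PTS2 consensus
#'
#' @param nonapeptide a 9-residue string.
#' @param consensus a [pts2_consensus] specification.
#' @return A list of class `pts2_site` with elements `nonapeptide`,
#'   `conforms` (logical, length 9; wildcards always conform), `deviations`
#'   (data frame of `position`, `residue` for every constrained position
#'   whose residue is outside its allowed set), `strict_match` (all
#'   positions conform), `relaxed_match` (all anchor positions conform) and
#'   `match` (the one selected by the consensus `mode`).
#' @examples
#' match_pts2_site("RLAAALSHL")$strict_match   # TRUE
#' match_pts2_site("RTAAALSHL")$deviations     # position 2, residue T
#' @export
match_pts2_site <- function(nonapeptide, consensus = pts2_consensus()) {
  np <- toupper(nonapeptide)
  if (length(np) != 1 || nchar(np) != 9)
    stop("a PTS2 site is exactly 9 residues", call. = FALSE)
  res <- substring(np, 1:9, 1:9)
  conforms <- vapply(1:9, function(i) {
    allowed <- consensus$allowed[[i]]
    is.null(allowed) || res[i] %in% allowed
  }, logical(1))
  dev <- data.frame(position = which(!conforms),
                    residue = res[!conforms], stringsAsFactors = FALSE)
  strict <- all(conforms)
  relaxed <- all(conforms[consensus$anchors])
  structure(list(nonapeptide = np, conforms = conforms, deviations = dev,
                 strict_match = strict, relaxed_match = relaxed,
                 match = if (consensus$mode == "strict") strict else relaxed),
            class = "pts2_site")
}

#' @export
print.pts2_site <- function(x, ...) {
  cat(x$nonapeptide,
      if (x$strict_match) " strict match"
      else if (x$relaxed_match) " relaxed match" else " no match", "\n",
      sep = "")
  if (nrow(x$deviations) > 0)
    cat("  deviations:",
        paste(sprintf("%d:%s", x$deviations$position, x$deviations$residue),
              collapse = " "), "\n")
  invisible(x)
}

format_deviations <- function(dev) {
  if (nrow(dev) == 0) return(".")
  paste(sprintf("%d:%s", dev$position, dev$residue), collapse = ";")
}

#' Scan a protein for PTS2 nonapeptide sites
#'
#' Slides the 9-mer consensus matcher over start positions 1..`window`
#' (the N-terminal region where PTS2 signals reside).  With
#' `allow_internal = TRUE` the whole sequence is scanned and matches whose
#' start exceeds `window` are flagged internal, covering the rare proteins
#' carrying an internal PTS2.
#'
#' @param sequence amino-acid string.
#' @param consensus a [pts2_consensus]; its `mode` decides whether strict or
#'   relaxed matches are reported.
#' @param window number of N-terminal start positions scanned by default
#'   (default 40).
#' @param allow_internal scan beyond the window, flagging such matches.
#' @return A data frame with columns `start` (1-based position of
#'   nonapeptide position 1), `nonapeptide`, `internal`, `n_deviations`,
#'   `deviations` (semicolon-joined `position:residue` tokens, `"."` if
#'   none), in start order.
#' @export
scan_pts2 <- function(sequence, consensus = pts2_consensus(), window = 40L,
                      allow_internal = FALSE) {
  stopifnot(length(sequence) == 1)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  s <- sub("\\*$", "", toupper(sequence))
  L <- nchar(s)
  empty <- data.frame(start = integer(0), nonapeptide = character(0),
                      internal = logical(0), n_deviations = integer(0),
                      deviations = character(0), stringsAsFactors = FALSE)
  if (L < 9L) return(empty)
  last <- if (allow_internal) L - 8L else min(window, L - 8L)
  if (last < 1L) return(empty)
  starts <- seq_len(last)
  hits <- lapply(starts, function(i) {
    m <- match_pts2_site(substring(s, i, i + 8L), consensus)
    if (!m$match) return(NULL)
    data.frame(start = i, nonapeptide = m$nonapeptide,
               internal = i > window, n_deviations = nrow(m$deviations),
               deviations = format_deviations(m$deviations),
               stringsAsFactors = FALSE)
  })
  hits <- hits[!vapply(hits, is.null, logical(1))]
  if (length(hits) == 0) return(empty)
  do.call(rbind, hits)
}
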