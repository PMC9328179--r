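#' Read a protein FASTA file
#'
#' Wrapped lines are joined, sequences are uppercased, and a single
#' trailing stop symbol (`*`) is stripped with a warning.  The record ID is
#' the header token before the first whitespace; the remainder is kept as
#' the description.
#'
#' @param path FASTA file path.
#' @return Data frame with columns `id`, `description`, `sequence`, in
#'   file order (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    return(data.frame(id = character(0), description = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot parse FASTA '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  if (any(seqs == ""))
    stop("empty sequence for record(s): ",
         paste(ids[seqs == ""], collapse = ", "), call. = FALSE)
  stops <- grepl("\\*$", seqs)
  if (any(stops)) {
    warning(sprintf("stripped trailing stop symbol from %d record(s)",
                    sum(stops)), call. = FALSE)
    seqs <- sub("\\*$", "", seqs)
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector of amino-acid strings.
#' @param path output path.
#' @param width line width for wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(!is.null(names(sequences)))
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
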