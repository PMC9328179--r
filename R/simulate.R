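# Tripeptides demonstrated as non-canonical (single low-abundance residue)
# PTS1s in the Arabidopsis/tomato catalogues; the non-canonical motif
# sampler draws from this inventory.
NONCANONICAL_PTS1_INVENTORY <- c(
  "SNL", "SSL", "ASL", "PKL", "PRL", "SRF", "AHL", "SNI", "SML", "SRY",
  "SYM", "SSM", "TKL", "AKV", "ANL", "SSI", "SLM")

SIGNAL_KINDS <- c("canonical", "non_canonical", "pts2", "internal", "none")

#' Configuration for the synthetic proteome generator
#'
#' Default settings emulate the composition of the Arabidopsis reference
#' catalogue this package models: 127 proteins of which 74 carry a
#' canonical terminal PTS1, 24 a non-canonical terminal PTS1, 19 an
#' N-terminal PTS2 nonapeptide, 3 a catalase-type internal PTS1
#' (QKL ten residues before the terminus), and 7 no signal at all.
#'
#' @param n_proteins number of proteins to generate.
#' @param length_range min/max protein length in residues (min >= 20).
#' @param fractions named numeric vector over `canonical`,
#'   `non_canonical`, `pts2`, `internal`, `none`; must sum to 1.
#' @param pts2_start_range range of 1-based start positions for embedded
#'   PTS2 nonapeptides (default 1..32, inside the 40-residue scan window).
#' @param internal_offset_range range of end offsets for embedded internal
#'   PTS1 motifs (default 10..10, the catalase convention).
#' @param background_freqs optional named numeric vector of residue
#'   frequencies over the 20 standard amino acids (summing to 1); uniform
#'   when `NULL`.
#' @param seed integer random seed; a fixed seed makes the generated FASTA
#'   byte-identical across runs.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 127L,
                              length_range = c(100L, 600L),
                              fractions = c(canonical = 74, non_canonical = 24,
                                            pts2 = 19, internal = 3,
                                            none = 7) / 127,
                              pts2_start_range = c(1L, 32L),
                              internal_offset_range = c(10L, 10L),
                              background_freqs = NULL,
                              seed = 1L) {
  if (!all(SIGNAL_KINDS %in% names(fractions)))
    stop("fractions must be named over: ",
         paste(SIGNAL_KINDS, collapse = ", "), call. = FALSE)
  fractions <- fractions[SIGNAL_KINDS]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must be in [0,1] and sum to 1", call. = FALSE)
  if (length_range[1] < 20L)
    stop("minimum protein length must be >= 20", call. = FALSE)
  if (!is.null(background_freqs)) validate_freqs(background_freqs)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 fractions = fractions,
                 pts2_start_range = as.integer(pts2_start_range),
                 internal_offset_range = as.integer(internal_offset_range),
                 background_freqs = background_freqs,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

validate_freqs <- function(freqs) {
  if (is.null(names(freqs)) || !setequal(names(freqs), AA20) ||
      any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop("background frequencies must be named over the 20 standard ",
         "residues and sum to 1", call. = FALSE)
  invisible(freqs)
}

#' Sample an i.i.d. background protein sequence
#'
#' Draws from the current RNG stream (seed it with [set.seed()] or via
#' [gen_proteome()]'s config).
#'
#' @param length sequence length.
#' @param freqs named residue frequency vector over the 20 standard amino
#'   acids summing to 1; uniform when `NULL`.
#' @return A single amino-acid string.
#' @export
sample_background <- function(length, freqs = NULL) {
  if (is.null(freqs)) {
    res <- sample(AA20, length, replace = TRUE)
  } else {
    validate_freqs(freqs)
    res <- sample(names(freqs), length, replace = TRUE, prob = freqs)
  }
  paste(res, collapse = "")
}

sample_canonical_pts1 <- function() {
  paste0(sample(c("S", "A"), 1), sample(c("K", "R"), 1),
         sample(c("L", "M", "I"), 1))
}

sample_noncanonical_pts1 <- function() {
  sample(NONCANONICAL_PTS1_INVENTORY, 1)
}

sample_strict_pts2 <- function() {
  paste(vapply(PTS2_STRICT_SETS, function(s)
    if (is.null(s)) sample(AA20, 1) else sample(s, 1), character(1)),
    collapse = "")
}

overwrite_at <- function(sequence, motif, start) {
  end <- start + nchar(motif) - 1L
  stopifnot(start >= 1, end <= nchar(sequence))
  paste0(substring(sequence, 1, start - 1L), motif,
         substring(sequence, end + 1L, nchar(sequence)))
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
}

#' Embed one targeting signal into a background sequence
#'
#' The motif overwrites residues in place (the sequence length is
#' unchanged).  Motif samplers: canonical PTS1 from {S,A} x {K,R} x
#' {L,M,I}; non-canonical PTS1 from the catalogue inventory; PTS2 as a
#' random instantiation of the strict consensus; internal PTS1 as QKL at
#' the configured end offset.
#'
#' @param sequence background amino-acid string.
#' @param kind one of `"canonical"`, `"non_canonical"`, `"pts2"`,
#'   `"internal"`, `"none"`.
#' @param pts2_start_range,internal_offset_range placement ranges (see
#'   [simulation_config()]).
#' @return A list with `sequence` (modified), `motif` (`NA` for kind
#'   `"none"`) and `position` (PTS2 start, or internal end offset; `NA`
#'   otherwise).
#' @export
embed_signal <- function(sequence, kind,
                         pts2_start_range = c(1L, 32L),
                         internal_offset_range = c(10L, 10L)) {
  kind <- match.arg(kind, SIGNAL_KINDS)
  L <- nchar(sequence)
  if (kind == "none")
    return(list(sequence = sequence, motif = NA_character_,
                position = NA_integer_))
  if (kind %in% c("canonical", "non_canonical")) {
    motif <- if (kind == "canonical") sample_canonical_pts1()
             else sample_noncanonical_pts1()
    return(list(sequence = overwrite_at(sequence, motif, L - 2L),
                motif = motif, position = NA_integer_))
  }
  if (kind == "pts2") {
    start <- sample_range(pts2_start_range)
    if (start + 8L > L)
      stop("sequence too short for PTS2 placement", call. = FALSE)
    motif <- sample_strict_pts2()
    return(list(sequence = overwrite_at(sequence, motif, start),
                motif = motif, position = as.integer(start)))
  }
  # internal catalase-type PTS1
  offset <- sample_range(internal_offset_range)
  start <- L - offset - 2L
  if (start < 1L)
    stop("sequence too short for internal PTS1 placement", call. = FALSE)
  list(sequence = overwrite_at(sequence, "QKL", start), motif = "QKL",
       position = as.integer(offset))
}

audit_signals <- function(sequence, kind, motif, position, classes,
                          consensus, options) {
  term <- classify_pts1(extract_tripeptide(sequence), classes)
  pts2 <- scan_pts2(sequence, consensus, options$pts2_window,
                    options$allow_internal_pts2)
  pts2 <- pts2[!pts2$internal, , drop = FALSE]
  internal <- scan_internal_pts1(sequence, classes,
                                 options$internal_min_offset,
                                 options$internal_max_offset,
                                 options$offset_convention)
  tok <- character(0)
  if (term$label %in% c("canonical", "non_canonical") &&
      !(kind %in% c("canonical", "non_canonical")))
    tok <- c(tok, sprintf("terminal:%s", term$tripeptide))
  inc_pts2 <- pts2$start[!(kind == "pts2" & pts2$start == position)]
  if (length(inc_pts2) > 0)
    tok <- c(tok, sprintf("pts2@%d", inc_pts2))
  inc_int <- internal[!(kind == "internal" &
                          internal$end_offset == position &
                          internal$tripeptide == motif), , drop = FALSE]
  if (nrow(inc_int) > 0)
    tok <- c(tok, sprintf("internal:%s-%d", inc_int$tripeptide,
                          inc_int$end_offset))
  list(terminal_label = term$label,
       n_pts2_window = nrow(pts2),
       n_internal = nrow(internal),
       incidental = if (length(tok) == 0) "." else
         paste(tok, collapse = ";"))
}

#' Generate a labelled synthetic proteome
#'
#' Produces `n_proteins` i.i.d. background sequences, assigns each a
#' signal kind multinomially according to the configured fractions, embeds
#' the signals by overwriting in place, and records a per-protein truth
#' table.  An audit pass then scans every finished sequence with the
#' package's own scanners and records the signals that arose by chance in
#' the background ("incidental" signals), so that recovery tests can
#' separate embedded from incidental evidence instead of biasing the
#' generator with rejection sampling.
#'
#' @param config a [simulation_config()].
#' @param classes,consensus,options scan settings used for the audit pass;
#'   defaults match [annotate_proteome()]'s defaults.
#' @return A list of class `synthetic_proteome` with `fasta` (named
#'   character vector of sequences), `truth` (data frame: `id`, `kind`,
#'   `motif`, `position`, `terminal_label`, `n_pts2_window`, `n_internal`,
#'   `incidental`) and `config`.
#' @export
gen_proteome <- function(config = simulation_config(),
                         classes = pts1_residue_classes(),
                         consensus = pts2_consensus(),
                         options = annotation_options()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  kinds <- sample(SIGNAL_KINDS, n, replace = TRUE, prob = config$fractions)
  lens <- if (config$length_range[1] == config$length_range[2])
    rep(config$length_range[1], n)
  else sample(config$length_range[1]:config$length_range[2], n,
              replace = TRUE)
  ids <- sprintf("synth%04d", seq_len(n))
  seqs <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    bg <- sample_background(lens[i], config$background_freqs)
    emb <- embed_signal(bg, kinds[i], config$pts2_start_range,
                        config$internal_offset_range)
    seqs[i] <- emb$sequence
    aud <- audit_signals(emb$sequence, kinds[i], emb$motif, emb$position,
                         classes, consensus, options)
    truth[[i]] <- data.frame(
      id = ids[i], kind = kinds[i], motif = emb$motif,
      position = emb$position, terminal_label = aud$terminal_label,
      n_pts2_window = aud$n_pts2_window, n_internal = aud$n_internal,
      incidental = aud$incidental, stringsAsFactors = FALSE)
  }
  names(seqs) <- ids
  structure(list(fasta = seqs, truth = do.call(rbind, truth),
                 config = config),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf("Synthetic proteome: %d protein(s), seed %d\n",
              length(x$fasta), x$config$seed))
  print(table(x$truth$kind))
  invisible(x)
}

#' Expected summary category of a synthetic protein
#'
#' Applies the annotation precedence rule to the union of embedded and
#' incidental evidence in a truth table, giving the category the annotator
#' must report for each generated protein.
#'
#' @param truth the `truth` data frame of a [gen_proteome()] result.
#' @return Character vector of summary categories.
#' @export
expected_category <- function(truth) {
  mapply(function(label, n_pts2, n_int)
    summary_category_from(label, n_pts2 > 0, n_int > 0),
    truth$terminal_label, truth$n_pts2_window, truth$n_internal,
    USE.NAMES = FALSE)
}

#' Write a synthetic proteome to FASTA + truth TSV
#'
#' @param proteome a [gen_proteome()] result.
#' @param fasta_path,truth_path output paths.
#' @return Invisible list of the two paths.
#' @export
write_proteome <- function(proteome, fasta_path, truth_path) {
  stopifnot(inherits(proteome, "synthetic_proteome"))
  write_fasta(proteome$fasta, fasta_path)
  tr <- proteome$truth
  tr$motif[is.na(tr$motif)] <- "."
  tr$position[is.na(tr$position)] <- "."
  utils::write.table(tr, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(fasta = fasta_path, truth = truth_path))
}
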