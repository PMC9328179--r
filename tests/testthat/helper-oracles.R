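# Independent brute-force oracles, written as literal rule ladders over
# single residues; deliberately kept separate from the vectorized package
# implementation they cross-check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_residue_class <- function(res, pos, classes) {
  cl <- classes[[as.character(pos)]]
  if (res %in% cl$high) return("high")
  if (res %in% cl$low) return("low")
  "unproven"
}

oracle_classify <- function(tripeptide, classes = pts1_residue_classes()) {
  r <- strsplit(tripeptide, "")[[1]]
  cls <- c(oracle_residue_class(r[1], -3, classes),
           oracle_residue_class(r[2], -2, classes),
           oracle_residue_class(r[3], -1, classes))
  n_high <- sum(cls == "high")
  n_low <- sum(cls == "low")
  n_unp <- sum(cls == "unproven")
  if (n_high == 3) return("canonical")
  if (n_low == 1 && n_high == 2) return("non_canonical")
  if (n_unp == 0 && n_low >= 2) return("no_obvious_i")
  if (n_unp == 1) return("no_obvious_ii")
  "no_obvious_iii"
}

# every 3-mer window, checked one by one
oracle_scan_internal <- function(sequence, classes = pts1_residue_classes(),
                                 min_offset = 1, max_offset = 50) {
  L <- nchar(sequence)
  hits <- list()
  for (start in seq_len(max(L - 2, 0))) {
    end <- start + 2
    off <- L - end
    if (off < min_offset || off > max_offset) next
    tp <- substr(sequence, start, end)
    lab <- oracle_classify(tp, classes)
    if (lab %in% c("canonical", "non_canonical"))
      hits[[length(hits) + 1]] <- list(tp = tp, off = off, lab = lab)
  }
  hits <- hits[order(vapply(hits, function(h) h$off, numeric(1)))]
  data.frame(tripeptide = vapply(hits, function(h) h$tp, character(1)),
             end_offset = vapply(hits, function(h) as.integer(h$off),
                                 integer(1)),
             label = vapply(hits, function(h) h$lab, character(1)),
             stringsAsFactors = FALSE)
}

ORACLE_PTS2 <- list(`1` = c("R", "K"), `2` = c("L", "V", "I", "Q"),
                    `5` = c("L", "V", "I", "H", "Q"),
                    `6` = c("L", "S", "G", "A", "K"),
                    `8` = c("H", "Q"), `9` = c("L", "A", "F"))

oracle_pts2_ok <- function(nine, positions) {
  r <- strsplit(nine, "")[[1]]
  for (p in positions) {
    allowed <- ORACLE_PTS2[[as.character(p)]]
    if (!is.null(allowed) && !(r[p] %in% allowed)) return(FALSE)
  }
  TRUE
}

oracle_scan_pts2_starts <- function(sequence, mode = "relaxed",
                                    window = 40, allow_internal = FALSE) {
  L <- nchar(sequence)
  last <- if (allow_internal) L - 8 else min(window, L - 8)
  positions <- if (mode == "strict") c(1, 2, 5, 6, 8, 9) else c(1, 8, 9)
  out <- integer(0)
  for (i in seq_len(max(last, 0)))
    if (oracle_pts2_ok(substr(sequence, i, i + 8), positions))
      out <- c(out, i)
  out
}

random_protein <- function(n) paste(sample(AA, n, replace = TRUE),
                                    collapse = "")

# signal-free filler: G at every position fails all residue classes and
# every PTS2 anchor set
polyG <- function(n) strrep("G", n)
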