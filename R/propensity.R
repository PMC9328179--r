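#' Printed form of a propensity percentage
#'
#' Reproduces the printing convention of published PTS2 propensity tables:
#' a percentage that is exact to two decimal places (as every count out of
#' 16 is, e.g. 68.75, 43.75, 6.25) is printed in full; any other value is
#' truncated toward zero to three significant figures (counts out of 14:
#' 78.571... prints as 78.5, 7.1428... as 7.14).  Truncation, not rounding:
#' 42.857 prints as 42.8.
#'
#' @param value numeric vector of percentages in [0, 100].
#' @return numeric vector of printed values.
#' @export
propensity_printed <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return(NA_real_)
    if (v == 0) return(0)
    if (abs(v * 100 - round(v * 100)) < 1e-9) return(round(v * 100) / 100)
    k <- 2L - floor(log10(abs(v)))
    trunc(v * 10^k) / 10^k
  }, numeric(1))
}

#' Positional residue propensity over a set of nonapeptides
#'
#' For every position 1..9 and residue, counts in how many of the `n`
#' nonapeptides the residue occurs at that position and assigns the
#' propensity 100 * count / n.  A residue present at a position in all
#' sequences therefore has propensity 100.  The input is a flat list of
#' fixed-length 9-mers; no alignment is needed.
#'
#' @param nonapeptides character vector of 9-residue strings.
#' @return An object of class `propensity_table`: a list with `n` and
#'   `table`, a data frame of `position`, `residue`, `count`, `propensity`
#'   (full precision) and `printed` (see [propensity_printed()]), holding
#'   one row per (position, residue) with count > 0, ordered by position
#'   then decreasing count then residue.
#' @examples
#' pt <- compute_propensity(c("RLAAALSHL", "RLAAALSHL", "RQAAALSHF"))
#' subset(pt$table, position == 9)
#' @export
compute_propensity <- function(nonapeptides) {
  np <- toupper(as.character(nonapeptides))
  if (length(np) == 0)
    stop("need at least one nonapeptide", call. = FALSE)
  if (any(nchar(np) != 9))
    stop("all nonapeptides must have exactly 9 residues", call. = FALSE)
  n <- length(np)
  rows <- lapply(1:9, function(p) {
    counts <- table(substring(np, p, p))
    d <- data.frame(position = p, residue = names(counts),
                    count = as.integer(counts), stringsAsFactors = FALSE)
    d[order(-d$count, d$residue), ]
  })
  tab <- do.call(rbind, rows)
  tab$propensity <- 100 * tab$count / n
  tab$printed <- propensity_printed(tab$propensity)
  rownames(tab) <- NULL
  structure(list(n = n, table = tab), class = "propensity_table")
}

#' @export
print.propensity_table <- function(x, ...) {
  cat(sprintf("Residue propensity over %d nonapeptide(s)\n", x$n))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Residues at a position, most prevalent first
#'
#' @param table a [compute_propensity()] result.
#' @param position nonapeptide position, 1..9.
#' @return Character vector of residues with count > 0, sorted by
#'   decreasing count, ties broken alphabetically.
#' @export
most_prevalent <- function(table, position) {
  stopifnot(inherits(table, "propensity_table"))
  if (length(position) != 1 || position < 1 || position > 9)
    stop("position must be a single value in 1..9", call. = FALSE)
  d <- table$table[table$table$position == position, ]
  d$residue[order(-d$count, d$residue)]
}

#' Tabular propensity report, optionally two species side by side
#'
#' Rows are ordered by position then decreasing count.  When a comparison
#' table is supplied, rows of the two species are paired rank-by-rank
#' within each position (the layout of published comparative propensity
#' tables); positions where one species has fewer distinct residues get
#' `NA` cells on that side.
#'
#' @param table a [compute_propensity()] result.
#' @param comparison optional second `propensity_table`.
#' @param labels column-suffix labels for the two species.
#' @return A data frame ready for printing or TSV export.
#' @export
format_propensity <- function(table, comparison = NULL,
                              labels = c("A", "B")) {
  stopifnot(inherits(table, "propensity_table"))
  one <- function(tab, lab) {
    d <- tab$table[order(tab$table$position, -tab$table$count,
                         tab$table$residue), ]
    d <- d[, c("position", "residue", "count", "printed")]
    names(d) <- c("position", paste(c("residue", "count", "propensity"),
                                    lab, sep = "_"))
    d$rank <- stats::ave(d$position, d$position, FUN = seq_along)
    d
  }
  a <- one(table, labels[1])
  if (is.null(comparison)) {
    a$rank <- NULL
    rownames(a) <- NULL
    return(a)
  }
  stopifnot(inherits(comparison, "propensity_table"))
  b <- one(comparison, labels[2])
  out <- merge(a, b, by = c("position", "rank"), all = TRUE)
  out <- out[order(out$position, out$rank), ]
  out$rank <- NULL
  rownames(out) <- NULL
  out
}

#' Plot a propensity table as a grid of squares
#'
#' One column per nonapeptide position, squares sized by propensity --
#' a compact visual of positional residue preference.
#'
#' @param x a `propensity_table`.
#' @param main plot title.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.propensity_table <- function(x, main = "Residue propensity", ...) {
  tab <- x$table
  graphics::plot(NULL, xlim = c(0.5, 9.5),
                 ylim = c(0.5, max(table(tab$position)) + 0.5),
                 xlab = "nonapeptide position", ylab = "prevalence rank",
                 main = main, xaxt = "n", yaxt = "n")
  graphics::axis(1, at = 1:9)
  for (p in unique(tab$position)) {
    d <- tab[tab$position == p, ]
    d <- d[order(-d$count, d$residue), ]
    for (i in seq_len(nrow(d))) {
      half <- 0.45 * sqrt(d$propensity[i] / 100)
      graphics::rect(p - half, i - half, p + half, i + half,
                     col = "grey80")
      graphics::text(p, i, d$residue[i], cex = 0.7)
    }
  }
  invisible(x)
}
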