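# Kozak context representation, TIE tables and the synthetic context model.
#
# A "context" is the 11-nt window around an AUG start codon: positions
# -6..-1 (upstream), +1..+3 (the AUG itself; +1 is the A) and +4..+5
# (downstream).  Contexts are stored in RNA alphabet; DNA input (T) is
# normalized to U transparently.

CONTEXT_WIDTH <- 11L
RNA_LETTERS <- c("A", "C", "G", "U")
# flank positions scored by the synthetic model, in window order
FLANK_POSITIONS <- c("-6", "-5", "-4", "-3", "-2", "-1", "+4", "+5")
# 1-based offsets of the flank positions within the 11-mer
FLANK_OFFSETS <- c(1L, 2L, 3L, 4L, 5L, 6L, 10L, 11L)

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and maps T to U. Used for both full transcript sequences and
#' 11-nt Kozak contexts.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector in `A/C/G/U` alphabet.
#' @export
normalize_nt <- function(x) {
  chartr("acgtuT", "ACGUUU", x)
}

#' Validate an 11-nt Kozak context string
#'
#' A valid context is exactly 11 characters of `A/C/G/U` (after
#' normalization) whose central three characters (positions 7-9, the +1..+3
#' window) are `AUG`.
#'
#' @param x character vector.
#' @param require_aug if `TRUE` (default) the central codon must be AUG.
#' @return logical vector.
#' @export
is_valid_context <- function(x, require_aug = TRUE) {
  x <- normalize_nt(x)
  ok <- !is.na(x) & nchar(x) == CONTEXT_WIDTH & !grepl("[^ACGU]", x)
  if (require_aug) ok <- ok & substr(x, 7L, 9L) == "AUG"
  ok
}

#' Read a TIE lookup table from a two-column TSV
#'
#' The file format is `context<TAB>tie` with optional `#` comment lines and
#' no required header. Contexts are normalized to RNA alphabet on read.
#' Duplicate contexts, malformed 11-mers and non-positive TIE values are
#' hard errors reported with the offending line.
#'
#' @param path path to a TSV file.
#' @return a `tie_table` object with `provenance = "measured"`.
#' @seealso [write_tie_table()], [tie_lookup()]
#' @export
load_tie_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("TIE table '", path, "' has no data rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    stop("TIE table '", path, "': line ", line_no[bad[1L]],
         " does not have two tab-separated fields")
  }
  ctx <- normalize_nt(vapply(parts, `[[`, "", 1L))
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  bad <- which(!is_valid_context(ctx, require_aug = FALSE))
  if (length(bad) > 0L) {
    stop("TIE table '", path, "': line ", line_no[bad[1L]],
         " has a malformed 11-mer: '", ctx[bad[1L]], "'")
  }
  bad <- which(is.na(val) | val <= 0)
  if (length(bad) > 0L) {
    stop("TIE table '", path, "': line ", line_no[bad[1L]],
         " has a non-positive or non-numeric TIE value")
  }
  dup <- ctx[duplicated(ctx)]
  if (length(dup) > 0L) {
    stop("TIE table '", path, "': duplicate context '", dup[1L], "'")
  }
  tie_table(stats::setNames(val, ctx), provenance = "measured")
}

#' Construct a TIE table from a named numeric vector
#'
#' @param entries numeric vector of positive TIE values named by 11-mer
#'   contexts (RNA alphabet).
#' @param provenance `"measured"` or `"synthetic"`.
#' @return a `tie_table` object.
#' @export
tie_table <- function(entries, provenance = c("measured", "synthetic")) {
  provenance <- match.arg(provenance)
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (anyDuplicated(names(entries))) stop("duplicate context keys in TIE table")
  if (any(entries <= 0) || anyNA(entries)) stop("TIE values must be positive")
  structure(list(entries = entries, provenance = provenance),
            class = "tie_table")
}

#' @export
print.tie_table <- function(x, ...) {
  cat("TIE table (", x$provenance, "), ", length(x$entries), " contexts\n",
      sep = "")
  invisible(x)
}

#' @export
length.tie_table <- function(x) length(x$entries)

#' Look up TIE values for contexts
#'
#' A context absent from the table is an explicit miss returned as `NA`,
#' never silently 0; filtering stages count misses rather than crash.
#'
#' @param table a `tie_table`.
#' @param contexts character vector of 11-mer contexts (DNA accepted).
#' @return numeric vector; `NA` for misses.
#' @export
tie_lookup <- function(table, contexts) {
  stopifnot(inherits(table, "tie_table"))
  out <- rep(NA_real_, length(contexts))
  ok <- !is.na(contexts)
  out[ok] <- unname(table$entries[normalize_nt(contexts[ok])])
  out
}

#' Write a TIE table as TSV
#'
#' Emits a `#context<TAB>tie` header comment followed by one row per entry.
#'
#' @param table a `tie_table`.
#' @param path output path.
#' @export
write_tie_table <- function(table, path) {
  stopifnot(inherits(table, "tie_table"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("#context\ttie", con)
  writeLines(paste0(names(table$entries), "\t",
                    format(table$entries, trim = TRUE, scientific = FALSE)),
             con)
  invisible(path)
}

#' Extract the 11-nt Kozak context around an AUG
#'
#' Returns the window spanning 6 nt upstream through 2 nt downstream of the
#' AUG. When fewer than 6 nt precede or fewer than 2 nt follow the codon the
#' result is a miss (`NA`), not an error: flank-deficient starts are dropped
#' by the caller, mirroring how catalog filtering discards them.
#'
#' @param seq transcript sequence (single string, DNA or RNA).
#' @param aug_pos 0-based index of the A of the AUG. An AUG must actually be
#'   present there; anything else is a caller bug and raises an error.
#' @return 11-character context string, or `NA` on insufficient flank.
#' @export
extract_context <- function(seq, aug_pos) {
  seq <- normalize_nt(seq)
  n <- nchar(seq)
  stopifnot(length(aug_pos) == 1L, aug_pos >= 0, aug_pos + 3 <= n)
  if (substr(seq, aug_pos + 1L, aug_pos + 3L) != "AUG") {
    stop("no AUG at position ", aug_pos, " (0-based)")
  }
  if (aug_pos < 6L || aug_pos + 5L > n) return(NA_character_)
  substr(seq, aug_pos - 5L, aug_pos + 5L)
}

#' Default position-weight scheme of the synthetic TIE model
#'
#' The synthetic model scores a context as `base` times the product of eight
#' per-position nucleotide multipliers (positions -6..-1, +4, +5). The
#' default weights are chosen so that (i) the set of maximal contexts is
#' exactly the degenerate optimum `RYMRMVAUGGC` reported for human start
#' codons, and (ii) the -3 and +4 positions carry the largest dynamic range,
#' the dominant positions of the Kozak context. The absolute values are a
#' modeling choice and can be overridden.
#'
#' @param base positive scale constant (the score of an optimal context).
#' @param weights 8 x 4 numeric matrix (rows `-6,-5,-4,-3,-2,-1,+4,+5`,
#'   columns `A,C,G,U`) of multipliers in (0, 1]; each row must contain at
#'   least one multiplier equal to 1.
#' @return a `weight_scheme` object.
#' @export
default_weight_scheme <- function(base = 150, weights = NULL) {
  if (is.null(weights)) {
    weights <- rbind(
      "-6" = c(A = 1,   C = 0.8,  G = 1,    U = 0.8),
      "-5" = c(A = 0.8, C = 1,    G = 0.8,  U = 1),
      "-4" = c(A = 1,   C = 1,    G = 0.8,  U = 0.8),
      "-3" = c(A = 1,   C = 0.5,  G = 1,    U = 0.45),
      "-2" = c(A = 1,   C = 1,    G = 0.85, U = 0.8),
      "-1" = c(A = 1,   C = 1,    G = 1,    U = 0.75),
      "+4" = c(A = 0.7, C = 0.65, G = 1,    U = 0.6),
      "+5" = c(A = 0.9, C = 1,    G = 0.9,  U = 0.85)
    )
  }
  stopifnot(is.matrix(weights), nrow(weights) == 8L, ncol(weights) == 4L,
            base > 0)
  dimnames(weights) <- list(FLANK_POSITIONS, RNA_LETTERS)
  if (any(weights <= 0) || any(weights > 1)) {
    stop("weights must lie in (0, 1]")
  }
  if (any(apply(weights, 1L, max) < 1)) {
    stop("each position needs at least one multiplier equal to 1")
  }
  structure(list(base = base, weights = weights), class = "weight_scheme")
}

#' Synthetic TIE of a context under a position-weight scheme
#'
#' Deterministic parametric stand-in for measured translation initiation
#' efficiencies: `TIE = base * prod(weights[position, nucleotide])` over the
#' eight flank positions. Strictly positive, maximal exactly on contexts
#' matching `RYMRMVAUGGC` under the default scheme.
#'
#' @param contexts character vector of valid 11-mer contexts.
#' @param scheme a `weight_scheme`, default [default_weight_scheme()].
#' @return numeric vector of TIE values.
#' @export
synthetic_tie <- function(contexts, scheme = default_weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  contexts <- normalize_nt(contexts)
  if (!all(is_valid_context(contexts))) {
    stop("invalid context(s) passed to synthetic_tie")
  }
  out <- rep(scheme$base, length(contexts))
  for (k in seq_along(FLANK_OFFSETS)) {
    nt <- substr(contexts, FLANK_OFFSETS[k], FLANK_OFFSETS[k])
    out <- out * scheme$weights[k, nt]
  }
  unname(out)
}

#' Enumerate the full synthetic TIE table
#'
#' Scores all 4^8 = 65,536 possible flank combinations around an AUG core
#' under `scheme`. Used by the simulator to define strong/weak context
#' strata and by diagnostics needing the complete score distribution.
#'
#' @param scheme a `weight_scheme`.
#' @return a `tie_table` with `provenance = "synthetic"`.
#' @export
synthetic_tie_table <- function(scheme = default_weight_scheme()) {
  stopifnot(inherits(scheme, "weight_scheme"))
  idx <- as.matrix(expand.grid(rep(list(1:4), 8L), KEEP.OUT.ATTRS = FALSE))
  tie <- rep(scheme$base, nrow(idx))
  for (k in 1:8) tie <- tie * scheme$weights[k, idx[, k]]
  flank <- matrix(RNA_LETTERS[idx], nrow = nrow(idx))
  ctx <- paste0(flank[, 1], flank[, 2], flank[, 3], flank[, 4], flank[, 5],
                flank[, 6], "AUG", flank[, 7], flank[, 8])
  tie_table(stats::setNames(tie, ctx), provenance = "synthetic")
}

#' Percentile rank of a context's TIE within a table
#'
#' Fraction of table entries with TIE strictly below the queried context's
#' value, times 100; tied values share the lower rank. A context absent from
#' the table propagates as a miss (`NA`).
#'
#' @param table a `tie_table`.
#' @param contexts character vector of contexts.
#' @return numeric vector of percentiles in \[0, 100\] (`NA` on miss).
#' @export
rank_percentile <- function(table, contexts) {
  v <- tie_lookup(table, contexts)
  n <- length(table$entries)
  vals <- sort(table$entries)
  # strict count via binary search: entries < v
  below <- findInterval(v, vals, left.open = TRUE)
  ifelse(is.na(v), NA_real_, 100 * below / n)
}
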