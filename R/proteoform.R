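# In-silico tryptic digestion and peptide classification for evaluating
# proteomics support of long (sAUG-initiated) versus N-terminally truncated
# (fdAUG-initiated) proteoforms.

#' Translate a transcript from a given start codon
#'
#' Standard genetic code translation starting at an AUG at `start_pos`,
#' running to the first stop codon or the transcript end. A translation
#' that runs off the end without a stop is flagged `terminated = FALSE`.
#'
#' @param seq transcript sequence (DNA or RNA).
#' @param start_pos 0-based position of the AUG.
#' @return list with `protein` (amino-acid string, no stop symbol) and
#'   `terminated` (logical).
#' @export
translate_from <- function(seq, start_pos) {
  seq <- normalize_nt(seq)
  n <- nchar(seq)
  stopifnot(start_pos >= 0, start_pos + 3L <= n)
  if (substr(seq, start_pos + 1L, start_pos + 3L) != "AUG") {
    stop("no AUG at position ", start_pos, " (0-based)")
  }
  starts <- seq.int(start_pos, n - 3L, by = 3L)
  codons <- substring(seq, starts + 1L, starts + 3L)
  aa <- Biostrings::RNA_GENETIC_CODE[codons]
  stop_at <- which(aa == "*")
  if (length(stop_at) > 0L) {
    list(protein = paste(aa[seq_len(stop_at[1L] - 1L)], collapse = ""),
         terminated = TRUE)
  } else {
    list(protein = paste(aa, collapse = ""), terminated = FALSE)
  }
}

#' In-silico tryptic digest
#'
#' Cleaves after K or R except when the next residue is P. With
#' `missed_cleavages = 0` (default) the returned spans tile the protein
#' exactly; with `missed_cleavages = k` all concatenations of up to `k + 1`
#' consecutive fragments are additionally emitted.
#'
#' @param protein amino-acid string.
#' @param missed_cleavages non-negative integer.
#' @return data frame `peptide`, `start`, `end` (0-based half-open residue
#'   spans in the input protein), `n_missed`.
#' @export
tryptic_digest <- function(protein, missed_cleavages = 0L) {
  stopifnot(nchar(protein) > 0, missed_cleavages >= 0L)
  n <- nchar(protein)
  res <- strsplit(protein, "")[[1L]]
  # cut after position i when residue i is K/R and residue i+1 is not P
  cuts <- which(res[-n] %in% c("K", "R") & res[-1L] != "P")
  bounds <- c(0L, cuts, n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  out <- data.frame(
    peptide = substring(protein, starts + 1L, ends),
    start = starts, end = ends, n_missed = 0L,
    stringsAsFactors = FALSE
  )
  if (missed_cleavages > 0L) {
    base_n <- nrow(out)
    extra <- list()
    for (m in seq_len(missed_cleavages)) {
      from <- seq_len(base_n - m)
      if (length(from) == 0L) break
      extra[[m]] <- data.frame(
        peptide = substring(protein, out$start[from] + 1L,
                            out$end[from + m]),
        start = out$start[from], end = out$end[from + m], n_missed = m,
        stringsAsFactors = FALSE
      )
    }
    out <- rbind(out, do.call(rbind, extra))
  }
  rownames(out) <- NULL
  out
}

#' Classify tryptic peptides of the long proteoform
#'
#' A peptide of the long (sAUG-initiated) proteoform is `unique_long` when
#' its span includes any residue upstream of the fdAUG-encoded Met
#' (`fd_met_index`), i.e. sequence absent from the truncated proteoform;
#' otherwise it is `shared`. A straddling peptide therefore counts as
#' `unique_long`. Peptides are `detectable` when their length falls within
#' the detectability window (default 7-30 residues, the usual mass-spec
#' heuristic; configurable).
#'
#' @param digest data frame from [tryptic_digest()] of the long proteoform.
#' @param fd_met_index 0-based residue index of the fdAUG-encoded Met in
#'   the long proteoform.
#' @param detect_range `c(min, max)` peptide length window.
#' @return the digest with added columns `class` and `detectable`.
#' @export
classify_peptides <- function(digest, fd_met_index,
                              detect_range = c(7L, 30L)) {
  stopifnot(fd_met_index > 0, detect_range[1] <= detect_range[2])
  len <- nchar(digest$peptide)
  digest$class <- ifelse(digest$start < fd_met_index, "unique_long",
                         "shared")
  digest$detectable <- len >= detect_range[1] & len <= detect_range[2]
  digest
}

#' Summarize peptide observation support per class
#'
#' Joins observation frequencies (e.g. spectral library observation counts)
#' to classified peptides and reports, per class over detectable peptides,
#' the median and maximum observation frequency, plus the shared-to-unique
#' ratio of medians. If both proteoforms are expressed, shared-region
#' peptides should be observed at least as often as peptides unique to the
#' long form; a much higher shared frequency is consistent with most
#' product arising from the downstream start.
#'
#' @param calls classified digest from [classify_peptides()].
#' @param frequencies data frame `peptide`, `frequency` (non-negative).
#' @return list with `by_class` (data frame `class`, `n_detectable`,
#'   `median_frequency`, `max_frequency`), `ratio_shared_to_unique`
#'   (`Inf` when the unique-class median is 0) and `ratio_infinite`.
#' @export
support_summary <- function(calls, frequencies) {
  stopifnot(all(c("peptide", "frequency") %in% names(frequencies)),
            all(frequencies$frequency >= 0))
  det <- calls[calls$detectable, , drop = FALSE]
  det$frequency <- frequencies$frequency[match(det$peptide,
                                               frequencies$peptide)]
  det$frequency[is.na(det$frequency)] <- 0
  by_class <- do.call(rbind, lapply(c("unique_long", "shared"), function(cl) {
    v <- det$frequency[det$class == cl]
    if (length(v) == 0L) {
      data.frame(class = cl, n_detectable = 0L,
                 median_frequency = NA_real_, max_frequency = NA_real_)
    } else {
      data.frame(class = cl, n_detectable = length(v),
                 median_frequency = stats::median(v), max_frequency = max(v))
    }
  }))
  med_u <- by_class$median_frequency[by_class$class == "unique_long"]
  med_s <- by_class$median_frequency[by_class$class == "shared"]
  ratio <- if (is.na(med_u) || is.na(med_s)) {
    NA_real_
  } else if (med_u == 0) {
    Inf
  } else {
    med_s / med_u
  }
  list(by_class = by_class, ratio_shared_to_unique = ratio,
       ratio_infinite = is.infinite(ratio))
}

#' Write classified peptides as TSV
#'
#' @param calls classified digest data frame.
#' @param path output path.
#' @export
write_peptide_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
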