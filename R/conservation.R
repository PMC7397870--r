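# Translation Initiation Efficiency Selection Score (TIESS) over ortholog
# context panels, conserved-strong/weak sets, and frame-stratified
# comparisons.
#
# TIESS for a gene is the sum over its orthologs i of
# log10(TIE_i / TIE_bar), where TIE_bar is the arithmetic mean TIE over all
# sAUG contexts in the whole panel collection (reference species included
# by default).  Large positive scores mean consistently stronger-than-
# average contexts across the phylogeny; large negative scores mean
# consistently weaker.

#' Read ortholog context panels from TSV
#'
#' Format: `gene_id<TAB>species<TAB>context` with a header row; `NA` marks
#' an ortholog without an intact aligned context. `#` lines are comments.
#'
#' @param path path to the panel TSV.
#' @return data frame `gene_id`, `species`, `context`.
#' @export
read_ortholog_panels <- function(path) {
  p <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = "NA")
  need <- c("gene_id", "species", "context")
  if (!all(need %in% names(p))) {
    stop("panel table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  if (anyDuplicated(p[, c("gene_id", "species")])) {
    stop("panel table '", path, "': duplicated (gene_id, species) entry")
  }
  p$context <- ifelse(is.na(p$context), NA_character_,
                      normalize_nt(p$context))
  p
}

#' Write ortholog panels as TSV
#'
#' @param panels panel data frame.
#' @param path output path.
#' @export
write_ortholog_panels <- function(panels, path) {
  utils::write.table(panels[, c("gene_id", "species", "context")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

# mark panel rows whose context is intact (valid 11-mer around an AUG) and
# present in the TIE table; returns the TIE vector with NA elsewhere
panel_ties <- function(panels, table) {
  tie <- rep(NA_real_, nrow(panels))
  ok <- !is.na(panels$context) & is_valid_context(panels$context)
  tie[ok] <- tie_lookup(table, panels$context[ok])
  tie
}

#' Global mean TIE over all panel entries
#'
#' Arithmetic mean of TIE over every scoreable (gene, species) context in
#' the collection — the `TIE_bar` denominator of the selection score.
#' Entries with a missing or non-intact context, or absent from the TIE
#' table, are skipped.
#'
#' @param panels panel data frame.
#' @param table a `tie_table`.
#' @param exclude_reference if `TRUE`, rows with `species == reference` are
#'   left out of the mean.
#' @param reference reference species label (default `"human"`).
#' @return positive scalar mean TIE.
#' @export
global_mean_tie <- function(panels, table, exclude_reference = FALSE,
                            reference = "human") {
  if (exclude_reference) panels <- panels[panels$species != reference, ]
  tie <- panel_ties(panels, table)
  if (all(is.na(tie))) stop("no scoreable panel entries")
  mean(tie, na.rm = TRUE)
}

#' TIESS scores for a collection of ortholog panels
#'
#' For each gene, sums `log10(TIE_i / tie_bar)` over the orthologs whose
#' aligned context is an intact AUG 11-mer present in the TIE table;
#' skipped entries are excluded from `n_orthologs`. Genes with fewer than
#' `min_orthologs` scoreable entries are dropped (scored as absent, never
#' as 0). The raw sum is the score; `mean_log_dev = tiess / n_orthologs`
#' is reported alongside because the raw magnitude grows with ortholog
#' count.
#'
#' @param panels panel data frame (`gene_id`, `species`, `context`).
#' @param table a `tie_table`.
#' @param tie_bar global mean TIE; computed from `panels` when `NULL`.
#' @param min_orthologs minimum scoreable orthologs per gene (default 1).
#' @param exclude_reference,reference see [global_mean_tie()].
#' @return data frame `gene_id`, `tiess`, `n_orthologs`, `mean_log_dev`.
#' @export
tiess_scores <- function(panels, table, tie_bar = NULL, min_orthologs = 1L,
                         exclude_reference = FALSE, reference = "human") {
  if (exclude_reference) panels <- panels[panels$species != reference, ]
  if (is.null(tie_bar)) tie_bar <- global_mean_tie(panels, table)
  stopifnot(tie_bar > 0)
  tie <- panel_ties(panels, table)
  ok <- !is.na(tie)
  dev <- log10(tie[ok] / tie_bar)
  gene <- panels$gene_id[ok]
  tiess <- tapply(dev, gene, sum)
  n_orth <- tapply(dev, gene, length)
  out <- data.frame(
    gene_id = names(tiess),
    tiess = as.numeric(tiess),
    n_orthologs = as.integer(n_orth),
    stringsAsFactors = FALSE
  )
  out$mean_log_dev <- out$tiess / out$n_orthologs
  out <- out[out$n_orthologs >= min_orthologs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select conserved-strong and conserved-weak gene sets
#'
#' Identical mechanics to [select_deciles()] but keyed on the TIESS score:
#' the top fraction (most consistently stronger-than-average contexts) form
#' the conserved-strong set, the bottom fraction the conserved-weak set.
#' Ties broken by `gene_id`; membership is independent of input order.
#'
#' @param records TIESS data frame from [tiess_scores()].
#' @param fraction cohort fraction in (0, 0.5].
#' @return list with `conserved_strong` and `conserved_weak` data frames.
#' @export
conserved_sets <- function(records, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 0.5)
  n_total <- nrow(records)
  size <- floor(fraction * n_total + 0.5)
  if (n_total < 2 / fraction || size < 1L || 2L * size > n_total) {
    stop("record set of ", n_total, " cannot support disjoint sets of ",
         "fraction ", fraction)
  }
  ord_hi <- order(-records$tiess, records$gene_id)
  ord_lo <- order(records$tiess, records$gene_id)
  strong <- records[ord_hi[seq_len(size)], , drop = FALSE]
  weak <- records[ord_lo[seq_len(size)], , drop = FALSE]
  rownames(strong) <- rownames(weak) <- NULL
  list(conserved_strong = strong, conserved_weak = weak)
}

#' Compare TIESS between in-frame and out-of-frame genes
#'
#' Joins TIESS records to their start pairs by `gene_id` and runs a
#' two-sided rank-sum test of the TIESS distribution for genes whose fdAUG
#' is in frame 0 against genes with out-of-frame (frame 1 or 2) fdAUGs.
#' When either stratum has fewer than 3 genes the comparison is skipped
#' with a logged reason rather than run underpowered.
#'
#' @param records TIESS data frame (any subset, e.g. a conserved set).
#' @param pairs start-pair data frame carrying `gene_id` and `frame`.
#' @return list with `result` (a `comparison_result`, or `NULL` if
#'   skipped), `skipped` (logical) and `reason` (character or `NA`).
#' @export
compare_tiess_by_frame <- function(records, pairs) {
  m <- match(records$gene_id, pairs$gene_id)
  frame <- pairs$frame[m]
  usable <- !is.na(frame)
  in_frame <- records$tiess[usable & frame == 0L]
  out_frame <- records$tiess[usable & frame != 0L]
  if (length(in_frame) < 3L || length(out_frame) < 3L) {
    return(list(result = NULL, skipped = TRUE,
                reason = sprintf("stratum too small (in=%d, out=%d)",
                                 length(in_frame), length(out_frame))))
  }
  list(result = rank_sum_test(in_frame, out_frame), skipped = FALSE,
       reason = NA_character_)
}

#' Write TIESS records as TSV
#'
#' @param records TIESS data frame.
#' @param path output path.
#' @export
write_tiess <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
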