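# Ribosome footprint track normalization, inclusion filters, and
# anchor-aligned metagene profiles.
#
# Tracks are per-nt count vectors in transcript coordinates, with counts
# already assigned to A-site positions (elongating libraries) or P-site
# positions (initiating libraries).  Densities are normalized per
# transcript so that 1 equals the transcript's average CDS density, then
# binned into codons phased from the anchor AUG (offset 0 = the anchor
# codon itself).

#' Metagene configuration
#'
#' Defaults follow the analysis conventions for footprint density around
#' start codons: density windows of -15..-3 codons (upstream) and +10..+44
#' codons (downstream) relative to the anchor AUG; transcripts with a CDS
#' shorter than 200 nt or fewer than 200 total footprints are excluded;
#' sAUG-anchored profiles additionally require a 5' leader of at least
#' 45 nt, and fdAUG-anchored profiles a sAUG-fdAUG spacer strictly greater
#' than 40 nt (so the upstream window is not contaminated by initiation at
#' the sAUG).
#'
#' @param upstream,downstream closed codon-offset windows `c(lo, hi)`.
#' @param min_cds_nt minimum CDS length in nt.
#' @param min_footprints minimum total footprint count per transcript.
#' @param min_leader_nt minimum 5' leader length (sAUG anchor).
#' @param min_spacer_nt spacer threshold (fdAUG anchor; strict `>`).
#' @return a `metagene_config` list.
#' @export
metagene_config <- function(upstream = c(-15L, -3L),
                            downstream = c(10L, 44L),
                            min_cds_nt = 200L, min_footprints = 200L,
                            min_leader_nt = 45L, min_spacer_nt = 40L) {
  stopifnot(upstream[1] <= upstream[2], downstream[1] <= downstream[2],
            upstream[2] < downstream[1],
            min_cds_nt > 0, min_footprints > 0, min_leader_nt > 0,
            min_spacer_nt > 0)
  structure(list(upstream = as.integer(upstream),
                 downstream = as.integer(downstream),
                 min_cds_nt = as.integer(min_cds_nt),
                 min_footprints = as.integer(min_footprints),
                 min_leader_nt = as.integer(min_leader_nt),
                 min_spacer_nt = as.integer(min_spacer_nt)),
            class = "metagene_config")
}

#' Read footprint tracks from a bedGraph-like TSV
#'
#' Format: `transcript_id<TAB>start<TAB>end<TAB>count` runs in 0-based
#' half-open transcript coordinates, header row required, `#` comments
#' allowed. Positions not covered by a run have count 0. A run extending
#' past the transcript length is a hard error.
#'
#' @param path path to the track TSV.
#' @param transcripts catalog data frame supplying transcript lengths.
#' @param mode `"elongating_A_site"` or `"initiating_P_site"`.
#' @return a `footprint_tracks` object: list with `counts` (named list of
#'   per-nt numeric vectors) and `mode`.
#' @export
read_footprint_tracks <- function(path, transcripts,
                                  mode = c("elongating_A_site",
                                           "initiating_P_site")) {
  mode <- match.arg(mode)
  runs <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
  need <- c("transcript_id", "start", "end", "count")
  if (!all(need %in% names(runs))) {
    stop("track table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  len <- stats::setNames(nchar(transcripts$seq), transcripts$transcript_id)
  unknown <- setdiff(unique(runs$transcript_id), names(len))
  if (length(unknown) > 0L) {
    stop("track references unknown transcript '", unknown[1L], "'")
  }
  counts <- lapply(stats::setNames(nm = names(len)),
                   function(id) numeric(len[[id]]))
  for (grp in split(runs, runs$transcript_id)) {
    id <- grp$transcript_id[1L]
    if (any(grp$end > len[[id]]) || any(grp$start < 0)) {
      stop("track run out of bounds for transcript '", id, "' (length ",
           len[[id]], ")")
    }
    v <- counts[[id]]
    for (j in seq_len(nrow(grp))) {
      v[(grp$start[j] + 1L):grp$end[j]] <-
        v[(grp$start[j] + 1L):grp$end[j]] + grp$count[j]
    }
    counts[[id]] <- v
  }
  footprint_tracks(counts, mode)
}

#' Construct a footprint track set from per-nt count vectors
#'
#' @param counts named list of non-negative per-nt count vectors; each
#'   vector's length must equal its transcript's length.
#' @param mode `"elongating_A_site"` or `"initiating_P_site"`.
#' @return a `footprint_tracks` object.
#' @export
footprint_tracks <- function(counts, mode = c("elongating_A_site",
                                              "initiating_P_site")) {
  mode <- match.arg(mode)
  stopifnot(is.list(counts), !is.null(names(counts)))
  structure(list(counts = counts, mode = mode), class = "footprint_tracks")
}

#' Write footprint tracks as a bedGraph-like TSV
#'
#' Runs of equal non-zero counts are merged; zero runs are omitted.
#'
#' @param tracks a `footprint_tracks` object.
#' @param path output path.
#' @export
write_footprint_tracks <- function(tracks, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("transcript_id\tstart\tend\tcount", con)
  for (id in names(tracks$counts)) {
    v <- tracks$counts[[id]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(paste(id, starts[keep], ends[keep], r$values[keep],
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Apply metagene inclusion filters
#'
#' Keeps transcripts with CDS length at least `min_cds_nt`, total
#' footprints at least `min_footprints`, and — depending on the anchor —
#' a 5' leader of at least `min_leader_nt` (sAUG) or a sAUG-fdAUG spacer
#' strictly greater than `min_spacer_nt` (fdAUG). Transcripts whose CDS
#' carries zero footprints are also excluded (their density cannot be
#' normalized). A track/transcript length mismatch is a hard error;
#' everything else is a logged exclusion. Inclusion depends only on each
#' transcript's own record, so the filter is order-independent.
#'
#' @param transcripts catalog data frame.
#' @param tracks a `footprint_tracks` object.
#' @param pairs start-pair data frame (supplies `spacer_nt`).
#' @param cfg a `metagene_config`.
#' @param anchor `"saug"` or `"fdaug"`.
#' @return list with `included` (character vector of transcript ids) and
#'   `log` (data frame `transcript_id`, `reason`). Reasons: `short_cds`,
#'   `low_coverage`, `short_leader`, `short_spacer`, `zero_cds_counts`,
#'   `no_track`, `no_pair`.
#' @export
apply_metagene_filters <- function(transcripts, tracks, pairs, cfg,
                                   anchor = c("saug", "fdaug")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(cfg, "metagene_config"))
  ids <- transcripts$transcript_id
  reason <- rep(NA_character_, length(ids))
  spacer <- pairs$spacer_nt[match(ids, pairs$transcript_id)]
  for (j in seq_along(ids)) {
    id <- ids[j]
    v <- tracks$counts[[id]]
    if (is.null(v)) { reason[j] <- "no_track"; next }
    if (length(v) != nchar(transcripts$seq[j])) {
      stop("track length ", length(v), " != transcript length ",
           nchar(transcripts$seq[j]), " for '", id, "'")
    }
    cs <- transcripts$cds_start[j]; ce <- transcripts$cds_end[j]
    if (ce - cs < cfg$min_cds_nt) { reason[j] <- "short_cds"; next }
    if (sum(v) < cfg$min_footprints) { reason[j] <- "low_coverage"; next }
    if (anchor == "saug") {
      if (cs < cfg$min_leader_nt) { reason[j] <- "short_leader"; next }
    } else {
      if (is.na(spacer[j])) { reason[j] <- "no_pair"; next }
      if (spacer[j] <= cfg$min_spacer_nt) { reason[j] <- "short_spacer"; next }
    }
    if (sum(v[(cs + 1L):ce]) == 0) { reason[j] <- "zero_cds_counts"; next }
  }
  list(included = ids[is.na(reason)],
       log = data.frame(transcript_id = ids[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE))
}

#' Normalized codon-level density vector around an anchor
#'
#' Sums per-nt counts into codons phased from `anchor_pos` (codon offset k
#' covers nts `anchor_pos + 3k .. anchor_pos + 3k + 2`) and divides by the
#' transcript's average CDS density per codon (total CDS counts / CDS codon
#' count), so the transcript's mean CDS density becomes exactly 1. Offsets
#' whose codon does not lie fully within the transcript are `NA`.
#'
#' @param counts per-nt count vector.
#' @param cds_start,cds_end 0-based half-open CDS interval.
#' @param anchor_pos 0-based anchor AUG position.
#' @param offsets integer codon offsets to report.
#' @return named numeric vector of normalized densities over `offsets`.
#' @export
codon_densities <- function(counts, cds_start, cds_end, anchor_pos,
                            offsets = -20:50) {
  n <- length(counts)
  cds_total <- sum(counts[(cds_start + 1L):cds_end])
  if (cds_total == 0) stop("zero CDS counts: density cannot be normalized")
  norm <- cds_total / ((cds_end - cds_start) / 3)
  out <- rep(NA_real_, length(offsets))
  nt0 <- anchor_pos + 3L * offsets
  ok <- nt0 >= 0L & nt0 + 3L <= n
  out[ok] <- vapply(nt0[ok], function(p) sum(counts[(p + 1L):(p + 3L)]),
                    numeric(1)) / norm
  names(out) <- offsets
  out
}

#' Build an anchor-aligned metagene matrix
#'
#' Applies the inclusion filters and assembles one normalized codon-density
#' row per included transcript, aligned at the sAUG or fdAUG.
#'
#' @param transcripts catalog data frame.
#' @param tracks a `footprint_tracks` object.
#' @param pairs start-pair data frame.
#' @param cfg a `metagene_config`.
#' @param anchor `"saug"` or `"fdaug"`.
#' @param offsets integer codon offsets (columns of the matrix).
#' @return a `metagene_matrix` object: list with `densities` (matrix,
#'   rows = transcripts, columns = offsets), `anchor`, `mode`, `offsets`,
#'   `log` (exclusion log).
#' @export
metagene_matrix <- function(transcripts, tracks, pairs, cfg = metagene_config(),
                            anchor = c("saug", "fdaug"), offsets = -20:50) {
  anchor <- match.arg(anchor)
  flt <- apply_metagene_filters(transcripts, tracks, pairs, cfg, anchor)
  ids <- flt$included
  anchor_pos <- if (anchor == "saug") {
    transcripts$cds_start[match(ids, transcripts$transcript_id)]
  } else {
    pairs$fdaug_pos[match(ids, pairs$transcript_id)]
  }
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(offsets),
                dimnames = list(ids, offsets))
  for (j in seq_along(ids)) {
    k <- match(ids[j], transcripts$transcript_id)
    mat[j, ] <- codon_densities(tracks$counts[[ids[j]]],
                                transcripts$cds_start[k],
                                transcripts$cds_end[k],
                                anchor_pos[j], offsets)
  }
  structure(list(densities = mat, anchor = anchor, mode = tracks$mode,
                 offsets = offsets, log = flt$log),
            class = "metagene_matrix")
}

#' Median metagene profile
#'
#' Per-offset median of normalized codon densities across transcripts.
#' Offsets with fewer than `min_n` contributing transcripts are masked
#' (`NA`).
#'
#' @param matrix a `metagene_matrix`.
#' @param min_n minimum contributing transcripts per offset.
#' @return data frame `offset`, `median_density`, `n`.
#' @export
metagene_profile <- function(matrix, min_n = 1L) {
  stopifnot(inherits(matrix, "metagene_matrix"))
  m <- matrix$densities
  n <- colSums(!is.na(m))
  med <- apply(m, 2L, stats::median, na.rm = TRUE)
  med[n < min_n] <- NA_real_
  data.frame(offset = matrix$offsets, median_density = unname(med),
             n = unname(n))
}

#' Per-transcript upstream/downstream window mean densities
#'
#' Arithmetic means of normalized codon densities within the closed
#' upstream and downstream windows of `cfg`. Transcripts whose vector does
#' not fully cover both windows are skipped with a reason.
#'
#' @param matrix a `metagene_matrix`.
#' @param cfg a `metagene_config`.
#' @return list with `densities` (data frame `transcript_id`, `upstream`,
#'   `downstream`) and `log` (skipped transcripts).
#' @export
window_densities <- function(matrix, cfg = metagene_config()) {
  stopifnot(inherits(matrix, "metagene_matrix"),
            inherits(cfg, "metagene_config"))
  up_cols <- as.character(seq.int(cfg$upstream[1], cfg$upstream[2]))
  dn_cols <- as.character(seq.int(cfg$downstream[1], cfg$downstream[2]))
  if (!all(c(up_cols, dn_cols) %in% colnames(matrix$densities))) {
    stop("matrix offsets do not span the configured windows")
  }
  m <- matrix$densities
  up <- rowMeans(m[, up_cols, drop = FALSE])
  dn <- rowMeans(m[, dn_cols, drop = FALSE])
  ok <- !is.na(up) & !is.na(dn)
  list(
    densities = data.frame(transcript_id = rownames(m)[ok],
                           upstream = unname(up[ok]),
                           downstream = unname(dn[ok]),
                           stringsAsFactors = FALSE),
    log = data.frame(transcript_id = rownames(m)[!ok],
                     reason = rep("window_out_of_range", sum(!ok)),
                     stringsAsFactors = FALSE)
  )
}

#' Rank-sum comparison of window densities between two cohorts
#'
#' Two-sided Mann-Whitney U tests on the per-transcript downstream-window
#' means and, separately, the upstream-window means of two metagene
#' cohorts (e.g. weak vs strong sAUG contexts).
#'
#' @param wd_a,wd_b outputs of [window_densities()] for the two cohorts.
#' @return list with `downstream` and `upstream` `comparison_result`s.
#' @export
compare_window_densities <- function(wd_a, wd_b) {
  a <- wd_a$densities; b <- wd_b$densities
  if (nrow(a) < 3L || nrow(b) < 3L) {
    stop("fewer than 3 transcripts on one side")
  }
  list(downstream = rank_sum_test(a$downstream, b$downstream),
       upstream = rank_sum_test(a$upstream, b$upstream))
}

#' Step change in footprint density at the fdAUG
#'
#' Recovery diagnostic for the leaky-scanning model: the ratio of the mean
#' normalized density in the downstream window to that in the upstream
#' window, both re-anchored at the fdAUG. Under the leak model the expected
#' ratio is `(flux_s + flux_fd) / flux_s`. The closed form assumes both
#' windows lie inside the two constant-flux regions, so the upstream window
#' must fit between sAUG and fdAUG: `clean` is `FALSE` when the spacer is
#' shorter than the upstream window reach (45 nt at the default -15..-3
#' codon window) and such transcripts should be excluded from pooled
#' estimates.
#'
#' @param counts per-nt count vector.
#' @param cds_start,cds_end 0-based half-open CDS interval.
#' @param fdaug_pos 0-based fdAUG position.
#' @param cfg a `metagene_config`.
#' @return list `ratio` (NA when the upstream mean is 0 or windows are out
#'   of range), `upstream`, `downstream`, `undefined`, `clean`.
#' @export
step_change <- function(counts, cds_start, cds_end, fdaug_pos,
                        cfg = metagene_config()) {
  offs <- c(seq.int(cfg$upstream[1], cfg$upstream[2]),
            seq.int(cfg$downstream[1], cfg$downstream[2]))
  dens <- codon_densities(counts, cds_start, cds_end, fdaug_pos,
                          offsets = offs)
  n_up <- cfg$upstream[2] - cfg$upstream[1] + 1L
  up <- mean(dens[seq_len(n_up)])
  dn <- mean(dens[-seq_len(n_up)])
  spacer <- fdaug_pos - cds_start
  clean <- spacer >= -3L * cfg$upstream[1] &&
    !anyNA(dens)
  if (is.na(up) || is.na(dn) || up == 0) {
    return(list(ratio = NA_real_, upstream = up, downstream = dn,
                undefined = TRUE, clean = FALSE))
  }
  list(ratio = dn / up, upstream = up, downstream = dn,
       undefined = FALSE, clean = clean)
}

#' Pooled step-change estimate across transcripts
#'
#' Ratio of the across-transcript mean downstream-window density to the
#' mean upstream-window density, using only transcripts whose windows lie
#' cleanly inside the two-flux region (see [step_change()]). Pooling means
#' before taking the ratio avoids the small-count bias of averaging
#' per-transcript ratios.
#'
#' @param transcripts catalog data frame.
#' @param tracks a `footprint_tracks` object.
#' @param pairs start-pair data frame.
#' @param cfg a `metagene_config`.
#' @return list `ratio`, `n_used`, `n_skipped`.
#' @export
step_change_summary <- function(transcripts, tracks, pairs,
                                cfg = metagene_config()) {
  ups <- c(); dns <- c(); skipped <- 0L
  for (j in seq_len(nrow(pairs))) {
    id <- pairs$transcript_id[j]
    k <- match(id, transcripts$transcript_id)
    v <- tracks$counts[[id]]
    if (is.null(v) || is.na(k)) { skipped <- skipped + 1L; next }
    sc <- tryCatch(
      step_change(v, transcripts$cds_start[k], transcripts$cds_end[k],
                  pairs$fdaug_pos[j], cfg),
      error = function(e) NULL)
    if (is.null(sc) || !sc$clean) { skipped <- skipped + 1L; next }
    ups <- c(ups, sc$upstream); dns <- c(dns, sc$downstream)
  }
  if (length(ups) == 0L) stop("no transcripts with clean windows")
  list(ratio = mean(dns) / mean(ups), n_used = length(ups),
       n_skipped = skipped)
}

#' Write a metagene profile as TSV
#'
#' @param profile data frame from [metagene_profile()].
#' @param path output path.
#' @export
write_metagene_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
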