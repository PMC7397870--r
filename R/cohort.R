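# Strong/weak context decile cohorts and the frame/distance/context-strength
# comparisons between them.

#' Construct a comparison result record
#'
#' Common return shape of all two-cohort statistical comparisons.
#'
#' @param test one of `"chi2_2x2"`, `"rank_sum_two_sided"`, `"welch_t"`.
#' @param statistic test statistic.
#' @param p_value two-sided p-value in \[0, 1\].
#' @param n1,n2 per-side sample sizes.
#' @param warning optional character flag (e.g. low expected cell counts).
#' @return a one-row data frame of class `comparison_result`.
#' @export
comparison_result <- function(test, statistic, p_value, n1, n2,
                              warning = NA_character_) {
  stopifnot(test %in% c("chi2_2x2", "rank_sum_two_sided", "welch_t"),
            is.na(p_value) || (p_value >= 0 && p_value <= 1),
            n1 >= 1, n2 >= 1)
  out <- data.frame(test = test, statistic = statistic, p_value = p_value,
                    n1 = as.integer(n1), n2 = as.integer(n2),
                    warning = warning, stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", class(out))
  out
}

#' Two-sided rank-sum (Mann-Whitney U) test
#'
#' Exact null distribution when both samples have at most 50 observations
#' and no ties are present; otherwise the normal approximation with tie
#' correction (no continuity correction). Degenerate all-equal input
#' returns p = 1.
#'
#' @param x,y numeric samples.
#' @return a `comparison_result` with the Mann-Whitney `W` statistic of `x`
#'   versus `y`.
#' @export
rank_sum_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(comparison_result("rank_sum_two_sided",
                             statistic = length(x) * length(y) / 2,
                             p_value = 1, n1 = length(x), n2 = length(y)))
  }
  exact <- length(x) <= 50L && length(y) <= 50L && !anyDuplicated(pooled)
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = FALSE)
  )
  comparison_result("rank_sum_two_sided", statistic = unname(res$statistic),
                    p_value = min(1, res$p.value),
                    n1 = length(x), n2 = length(y))
}

# Welch two-sample t-test; degenerate constant input returns t = 0, p = 1
welch_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    return(comparison_result("welch_t", statistic = 0, p_value = 1,
                             n1 = length(x), n2 = length(y)))
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  comparison_result("welch_t", statistic = unname(res$statistic),
                    p_value = res$p.value, n1 = length(x), n2 = length(y))
}

#' Select strong and weak context cohorts by TIE decile
#'
#' Sorts start pairs by sAUG TIE and takes the top and bottom
#' `round(fraction * N)` (round half away from zero, so a catalog of 18,297
#' yields cohorts of 1830). Ties in TIE are broken by transcript id, making
#' membership a pure function of the data independent of input order.
#'
#' @param pairs start-pair data frame; every row must have a non-missing
#'   `saug_tie`.
#' @param fraction cohort fraction in (0, 0.5].
#' @return list with `strong` and `weak` data frames (disjoint), sorted by
#'   descending / ascending `saug_tie` respectively.
#' @export
select_deciles <- function(pairs, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 0.5)
  if (anyNA(pairs$saug_tie)) {
    stop("all pairs must have a non-missing saug_tie; drop misses first")
  }
  n_total <- nrow(pairs)
  size <- floor(fraction * n_total + 0.5)
  if (n_total < 2 / fraction || size < 1L || 2L * size > n_total) {
    stop("catalog of ", n_total, " cannot support disjoint cohorts of ",
         "fraction ", fraction)
  }
  ord_strong <- order(-pairs$saug_tie, pairs$transcript_id)
  ord_weak <- order(pairs$saug_tie, pairs$transcript_id)
  strong <- pairs[ord_strong[seq_len(size)], , drop = FALSE]
  weak <- pairs[ord_weak[seq_len(size)], , drop = FALSE]
  rownames(strong) <- rownames(weak) <- NULL
  list(strong = strong, weak = weak)
}

#' Frame counts and proportions of a cohort
#'
#' @param pairs start-pair data frame.
#' @return data frame with one row per frame 0/1/2: `frame`, `count`,
#'   `proportion` (proportions sum to 1).
#' @export
frame_proportions <- function(pairs) {
  stopifnot(nrow(pairs) >= 1)
  counts <- vapply(0:2, function(f) sum(pairs$frame == f), integer(1))
  data.frame(frame = 0:2, count = counts,
             proportion = counts / sum(counts))
}

#' Chi-squared test of frame-0 enrichment between cohorts
#'
#' 2x2 chi-squared (frame 0 vs not-0, strong vs weak) without continuity
#' correction. The single-degree contrast matches reporting a single
#' p-value for the in-frame enrichment; a 2x3 test would dilute it. An
#' expected cell below 5 sets a warning flag on the result.
#'
#' @param strong,weak start-pair data frames (cohort members).
#' @return a `comparison_result` with `test = "chi2_2x2"`.
#' @export
compare_frame0 <- function(strong, weak) {
  stopifnot(nrow(strong) >= 20, nrow(weak) >= 20)
  m <- rbind(
    strong = c(frame0 = sum(strong$frame == 0L),
               other = sum(strong$frame != 0L)),
    weak = c(frame0 = sum(weak$frame == 0L),
             other = sum(weak$frame != 0L))
  )
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  warn <- if (any(res$expected < 5)) "expected_cell_below_5" else NA_character_
  comparison_result("chi2_2x2", statistic = unname(res$statistic),
                    p_value = res$p.value,
                    n1 = nrow(strong), n2 = nrow(weak), warning = warn)
}

# restrict a cohort to given frames and pull a metric column
frame_metric <- function(pairs, frames, metric) {
  v <- pairs[[metric]][pairs$frame %in% frames]
  v[!is.na(v)]
}

#' Rank-sum comparison of spacer or ORF-length distributions
#'
#' Two-sided Mann-Whitney U test on the chosen metric (`spacer_nt`, the
#' sAUG-to-fdAUG A-to-A distance, or `fd_stop_nt`, the fdAUG-to-stop coding
#' length) restricted to the chosen frames. Unterminated `fd_stop_nt`
#' values are excluded from the test and counted in the result's warning
#' field.
#'
#' @param strong,weak cohort start-pair data frames.
#' @param frames subset of `c(0, 1, 2)` to retain.
#' @param metric `"spacer_nt"` or `"fd_stop_nt"`.
#' @return a `comparison_result`.
#' @export
compare_distances <- function(strong, weak, frames = 0:2,
                              metric = c("spacer_nt", "fd_stop_nt")) {
  metric <- match.arg(metric)
  x <- frame_metric(strong, frames, metric)
  y <- frame_metric(weak, frames, metric)
  if (length(x) < 3L || length(y) < 3L) {
    stop("fewer than 3 usable members on one side after frame filtering")
  }
  n_dropped <- sum(strong$frame %in% frames) - length(x) +
    sum(weak$frame %in% frames) - length(y)
  res <- rank_sum_test(x, y)
  if (n_dropped > 0L) {
    res$warning <- paste0("excluded_unterminated=", n_dropped)
  }
  res
}

#' Welch t-test of fdAUG context strength between cohorts
#'
#' Compares `fd_tie` (fdAUG Kozak context strength) between cohorts with an
#' unequal-variance t-test, restricted to the chosen frames; TIE misses are
#' dropped.
#'
#' @inheritParams compare_distances
#' @return a `comparison_result` with `test = "welch_t"`.
#' @export
compare_fd_context <- function(strong, weak, frames = 0:2) {
  x <- frame_metric(strong, frames, "fd_tie")
  y <- frame_metric(weak, frames, "fd_tie")
  if (length(x) < 3L || length(y) < 3L) {
    stop("fewer than 3 non-miss fd_tie values on one side")
  }
  welch_test(x, y)
}

#' Rank-sum comparison of nested (out-of-frame) ORF lengths
#'
#' Two-sided Mann-Whitney U test on `fd_stop_nt` restricted to frames 1 and
#' 2 — the lengths of ORFs under control of out-of-frame fdAUGs.
#' Unterminated ORFs are excluded.
#'
#' @param strong,weak cohort start-pair data frames.
#' @return a `comparison_result`.
#' @export
compare_nested_orf_lengths <- function(strong, weak) {
  compare_distances(strong, weak, frames = c(1L, 2L), metric = "fd_stop_nt")
}
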