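# Synthetic data generator: transcripts with controlled sAUG context
# strength and fdAUG frame/spacing, ortholog context panels with tunable
# conservation, and footprint tracks under a leaky-scanning initiation
# model.  Every draw is governed by the config seed; ground truth is
# emitted for parameter-recovery testing.

#' Simulation configuration
#'
#' Defaults encode the study conditions the generator emulates: half the
#' genes carry weak sAUG contexts; the fdAUG is in frame 0 with probability
#' 0.524 for weak-context genes and 0.380 for strong-context genes (the
#' observed in-frame proportions of the weak and strong decile sets); among
#' out-of-frame fdAUGs, frame 2 takes roughly a fifth (frame 2 is depleted
#' because an A after the AUG creates a frame-0 UGA); sAUG-fdAUG spacers
#' are geometric with means of 60 nt (weak) and 90 nt (strong) above a
#' 4-nt minimum; leaders are at least 45 nt; CDS tails after the fdAUG
#' average ~110 codons, giving CDS lengths around the human median; 50
#' ortholog species with context-conservation probability 0.9; and a
#' leaky-scanning initiation model `P_init(TIE) = min(1, TIE / tie_ref)`
#' with `tie_ref` equal to the synthetic scheme's base, so the optimal
#' context initiates every scanning ribosome. Footprint counts are Poisson
#' with expected depth 0.5 reads per nt at relative density 1
#' (negative-binomial overdispersion available via `nb_size`).
#'
#' @param n_genes number of genes (one transcript each).
#' @param p_weak fraction of genes assigned weak sAUG contexts.
#' @param p_frame0_given_weak,p_frame0_given_strong in-frame fdAUG
#'   probabilities per class.
#' @param p_frame2_given_out probability that an out-of-frame fdAUG is in
#'   frame 2 (rather than 1).
#' @param spacer_mean_weak,spacer_mean_strong,spacer_min spacer
#'   distribution parameters (nt).
#' @param leader_min,leader_extra_mean leader length = `leader_min` plus a
#'   geometric excess.
#' @param tail_codons_min,tail_codons_mean codons after the fdAUG codon
#'   before the CDS stop.
#' @param utr_min,utr_mean 3' UTR length parameters (nt).
#' @param n_species ortholog species per panel (reference "human" is
#'   emitted additionally).
#' @param conservation probability an ortholog context is drawn from the
#'   gene's own context stratum rather than the background.
#' @param conservation_band percentile half-width of the "same stratum"
#'   band used when the reference context is not in the strong/weak decile
#'   (fdAUG-anchored panels).
#' @param na_rate fraction of ortholog entries emitted as `NA`.
#' @param tie_ref TIE at which initiation saturates; `NULL` = scheme base.
#' @param depth expected reads per nt at relative density 1.
#' @param background_density relative density outside modeled regions.
#' @param init_peak_factor point-mass scale of initiating-ribosome peaks.
#' @param nb_size negative-binomial size parameter; `NULL` = Poisson.
#' @param stratum_fraction fraction of the context distribution defining
#'   the strong/weak strata (default 0.10: top/bottom deciles).
#' @param seed integer seed fixing every downstream draw.
#' @param scheme `weight_scheme` of the synthetic context model.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 200L, p_weak = 0.5,
                       p_frame0_given_weak = 0.524,
                       p_frame0_given_strong = 0.380,
                       p_frame2_given_out = 0.2,
                       spacer_mean_weak = 60, spacer_mean_strong = 90,
                       spacer_min = 4L,
                       leader_min = 45L, leader_extra_mean = 25,
                       tail_codons_min = 40L, tail_codons_mean = 110,
                       utr_min = 20L, utr_mean = 100,
                       n_species = 50L, conservation = 0.9,
                       conservation_band = 10,
                       na_rate = 0.05, tie_ref = NULL, depth = 0.5,
                       background_density = 0.01, init_peak_factor = 50,
                       nb_size = NULL, stratum_fraction = 0.10,
                       seed = 1L, scheme = default_weight_scheme()) {
  probs <- c(p_weak, p_frame0_given_weak, p_frame0_given_strong,
             p_frame2_given_out, conservation, na_rate)
  stopifnot(all(probs >= 0 & probs <= 1), n_genes >= 1, depth > 0,
            spacer_min >= 4L, spacer_mean_weak > spacer_min,
            spacer_mean_strong > spacer_min, leader_min >= 45L,
            stratum_fraction > 0, stratum_fraction <= 0.5)
  if (is.null(tie_ref)) tie_ref <- scheme$base
  structure(list(
    n_genes = as.integer(n_genes), p_weak = p_weak,
    p_frame0_given_weak = p_frame0_given_weak,
    p_frame0_given_strong = p_frame0_given_strong,
    p_frame2_given_out = p_frame2_given_out,
    spacer_mean_weak = spacer_mean_weak,
    spacer_mean_strong = spacer_mean_strong,
    spacer_min = as.integer(spacer_min),
    leader_min = as.integer(leader_min),
    leader_extra_mean = leader_extra_mean,
    tail_codons_min = as.integer(tail_codons_min),
    tail_codons_mean = tail_codons_mean,
    utr_min = as.integer(utr_min), utr_mean = utr_mean,
    n_species = as.integer(n_species), conservation = conservation,
    conservation_band = conservation_band,
    na_rate = na_rate, tie_ref = tie_ref, depth = depth,
    background_density = background_density,
    init_peak_factor = init_peak_factor, nb_size = nb_size,
    stratum_fraction = stratum_fraction,
    seed = as.integer(seed), scheme = scheme
  ), class = "sim_config")
}

# context pools of the synthetic model: full enumeration plus the strong
# (top fraction) and weak (bottom fraction) strata, deterministically
# ordered by (tie, context); memoized per (scheme, fraction) since the
# enumeration is identical across calls
.pool_cache <- new.env(parent = emptyenv())

context_pools <- function(cfg) {
  key <- paste(cfg$scheme$base, paste(cfg$scheme$weights, collapse = ","),
               cfg$stratum_fraction, sep = "|")
  hit <- .pool_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- context_pools_build(cfg)
  .pool_cache[[key]] <- out
  out
}

context_pools_build <- function(cfg) {
  tab <- synthetic_tie_table(cfg$scheme)
  ctx <- names(tab$entries)
  tie <- unname(tab$entries)
  ord <- order(tie, ctx)
  n <- length(ctx)
  k <- floor(cfg$stratum_fraction * n + 0.5)
  list(all = ctx, tie = stats::setNames(tie, ctx), table = tab,
       weak = ctx[ord[seq_len(k)]],
       strong = ctx[ord[seq.int(n - k + 1L, n)]],
       sorted = ctx[ord])
}

# geometric draw with given mean above a minimum (mean > min)
rgeom_min <- function(n, mean, min) {
  min + stats::rgeom(n, 1 / (mean - min + 1))
}

STOP_SET <- c("UAA", "UAG", "UGA")

# find 0-based start positions of AUG in a character vector
aug_starts_chr <- function(s) {
  n <- length(s)
  if (n < 3L) return(integer(0))
  which(s[1:(n - 2L)] == "A" & s[2:(n - 1L)] == "U" & s[3:n] == "G") - 1L
}

# assemble one gene's transcript; returns NULL when the constraint fix-up
# failed (caller redraws)
build_transcript <- function(saug_ctx, fd_ctx, spacer, leader_len,
                             tail_codons, utr_len, stop_codon) {
  body_nt <- spacer + 3L
  pad <- (3L - body_nt %% 3L) %% 3L
  cds_len <- body_nt + 3L * tail_codons + pad + 3L
  len <- leader_len + cds_len + utr_len
  s <- sample(RNA_LETTERS, len, replace = TRUE)
  L <- leader_len
  sctx <- strsplit(saug_ctx, "")[[1L]]
  fctx <- strsplit(fd_ctx, "")[[1L]]

  # implants, lowest priority first (later writes win)
  s[(L - 5L):L] <- sctx[1:6]                      # sAUG upstream flank
  s[(L + 4L):(L + 5L)] <- sctx[10:11]             # sAUG +4,+5
  r <- (L + spacer - 5L):(L + spacer)             # fd upstream flank
  keep <- r >= 1L & !(r %in% (L + 1L):(L + 3L))   # never the sAUG codon
  s[r[keep]] <- fctx[1:6][keep]
  s[(L + spacer + 4L):(L + spacer + 5L)] <- fctx[10:11]  # fd +4,+5
  s[(L + 1L):(L + 3L)] <- c("A", "U", "G")        # sAUG codon
  s[(L + spacer + 1L):(L + spacer + 3L)] <- c("A", "U", "G")  # fd codon
  s[(L + cds_len - 2L):(L + cds_len)] <- strsplit(stop_codon, "")[[1L]]

  core <- c((L + 1L):(L + 3L), (L + spacer + 1L):(L + spacer + 3L),
            (L + cds_len - 2L):(L + cds_len))
  flank <- c((L - 5L):L, (L + 4L):(L + 5L), r[keep],
             (L + spacer + 4L):(L + spacer + 5L))

  # break a codon at 1-based start i by setting one non-core position to C
  # (C can participate in neither AUG nor a stop codon)
  break_codon <- function(s, i) {
    cand <- i:(i + 2L)
    cand <- cand[!(cand %in% core)]
    if (length(cand) == 0L) return(NULL)
    free <- cand[!(cand %in% flank)]
    s[if (length(free) > 0L) free[1L] else cand[1L]] <- "C"
    s
  }

  for (pass in 1:5) {
    dirty <- FALSE
    # suppress AUGs upstream of the engineered fdAUG (leader + pre-fd CDS);
    # an AUG lying fully inside the implanted sAUG upstream flank is kept
    # (a harmless uAUG that is part of the sampled context itself)
    p <- aug_starts_chr(s[1:(L + spacer + 2L)])
    bad <- p[p != L & p != (L + spacer) & !(p >= L - 6L & p <= L - 3L)]
    for (b in bad) {
      s2 <- break_codon(s, b + 1L)
      if (is.null(s2)) return(NULL)
      s <- s2; dirty <- TRUE
    }
    # suppress premature in-frame stops inside the CDS
    cstarts <- seq.int(L + 4L, L + cds_len - 5L, by = 3L)
    cods <- paste0(s[cstarts], s[cstarts + 1L], s[cstarts + 2L])
    for (b in cstarts[cods %in% STOP_SET]) {
      s2 <- break_codon(s, b)
      if (is.null(s2)) return(NULL)
      s <- s2; dirty <- TRUE
    }
    if (!dirty) break
  }
  if (dirty) return(NULL)

  seq <- paste(s, collapse = "")
  cds_start <- L
  cds_end <- L + cds_len
  # verify the engineered structure end to end
  if (find_fdaug(seq, cds_start, cds_end) != cds_start + spacer) return(NULL)
  # the main ORF must terminate exactly at the engineered CDS stop
  if (is.na(stop_distance(seq, cds_start)) ||
      stop_distance(seq, cds_start) != cds_len - 3L) return(NULL)
  list(seq = seq, cds_start = cds_start, cds_end = cds_end)
}

#' Simulate a transcript catalog with ground truth
#'
#' Each gene receives an AUG-free leader of at least 45 nt ending in its
#' sampled sAUG context, a CDS whose start context is drawn from the strong
#' or weak stratum of the synthetic context model, exactly one engineered
#' fdAUG at the drawn spacer and frame with no earlier accidental AUG (in
#' any frame), no premature in-frame stop, a terminal in-frame stop codon,
#' and a 3' UTR. Deterministic under `cfg$seed`. The returned truth table
#' records the realized contexts, TIEs, frames, spacers and the initiation
#' fluxes of the leak model (`flux_s = P_init(sAUG)`,
#' `flux_fd = (1 - P_init(sAUG)) * P_init(fdAUG)`).
#'
#' @param cfg a `sim_config`.
#' @return list with `transcripts` (catalog data frame) and `truth`.
#' @export
simulate_transcripts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$spacer_min < 4L) stop("spacer_min below 4 is infeasible")
  set.seed(cfg$seed)
  pools <- context_pools(cfg)
  n <- cfg$n_genes
  seq_v <- character(n); cds_start_v <- integer(n); cds_end_v <- integer(n)
  class_v <- character(n); sctx_v <- character(n); fctx_v <- character(n)
  ties_v <- numeric(n); tiefd_v <- numeric(n)
  frame_v <- integer(n); spacer_v <- integer(n)
  fs_v <- numeric(n); ffd_v <- numeric(n)
  for (g in seq_len(n)) {
    for (attempt in 1:100) {
      weak <- stats::runif(1) < cfg$p_weak
      class <- if (weak) "weak" else "strong"
      saug_ctx <- sample(if (weak) pools$weak else pools$strong, 1L)
      p_f0 <- if (weak) cfg$p_frame0_given_weak else cfg$p_frame0_given_strong
      frame <- if (stats::runif(1) < p_f0) 0L else {
        if (stats::runif(1) < cfg$p_frame2_given_out) 2L else 1L
      }
      mean_sp <- if (weak) cfg$spacer_mean_weak else cfg$spacer_mean_strong
      g0 <- rgeom_min(1L, mean_sp, cfg$spacer_min)
      spacer <- g0 + (frame - g0) %% 3L
      repeat {
        fd_ctx <- sample(pools$all, 1L)
        if (!grepl("AUG", substr(fd_ctx, 1L, 6L), fixed = TRUE)) break
      }
      leader_len <- rgeom_min(1L, cfg$leader_min + cfg$leader_extra_mean,
                              cfg$leader_min)
      tail_codons <- cfg$tail_codons_min +
        stats::rpois(1L, cfg$tail_codons_mean - cfg$tail_codons_min)
      utr_len <- rgeom_min(1L, cfg$utr_mean, cfg$utr_min)
      stop_codon <- sample(STOP_SET, 1L)
      tr <- build_transcript(saug_ctx, fd_ctx, spacer, leader_len,
                             tail_codons, utr_len, stop_codon)
      if (!is.null(tr)) break
    }
    if (is.null(tr)) stop("could not satisfy constraints for gene ", g)
    seq_v[g] <- tr$seq
    cds_start_v[g] <- tr$cds_start
    cds_end_v[g] <- tr$cds_end
    class_v[g] <- class
    sctx_v[g] <- extract_context(tr$seq, tr$cds_start)
    fctx_v[g] <- extract_context(tr$seq, tr$cds_start + spacer)
    frame_v[g] <- frame
    spacer_v[g] <- spacer
  }
  ties_v <- synthetic_tie(sctx_v, cfg$scheme)
  tiefd_v <- synthetic_tie(fctx_v, cfg$scheme)
  p_init_s <- pmin(1, ties_v / cfg$tie_ref)
  p_init_fd <- pmin(1, tiefd_v / cfg$tie_ref)
  ids <- sprintf("TX%05d", seq_len(n))
  genes <- sprintf("G%05d", seq_len(n))
  transcripts <- data.frame(
    transcript_id = ids, gene_id = genes, seq = seq_v,
    cds_start = cds_start_v, cds_end = cds_end_v, length = nchar(seq_v),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    gene_id = genes, transcript_id = ids, class = class_v,
    saug_context = sctx_v, saug_tie = ties_v,
    frame = frame_v, spacer_nt = spacer_v,
    fd_context = fctx_v, fd_tie = tiefd_v,
    flux_s = p_init_s, flux_fd = (1 - p_init_s) * p_init_fd,
    stringsAsFactors = FALSE
  )
  list(transcripts = transcripts, truth = truth)
}

#' Simulate ortholog context panels
#'
#' For each gene and each of `cfg$n_species` species: with probability
#' `cfg$conservation` the context is drawn from the gene's own stratum
#' (sAUG anchor: the strong or weak decile pool of its class; fdAUG anchor:
#' the percentile band of width `2 * conservation_band` around the
#' reference context's rank), otherwise uniformly from the background
#' context distribution. `NA` entries are injected at `cfg$na_rate`. A
#' reference row (`species = "human"`) carrying the gene's own realized
#' context is always emitted.
#'
#' @param cfg a `sim_config`.
#' @param truth truth table from [simulate_transcripts()].
#' @param anchor `"saug"` or `"fdaug"`.
#' @return panel data frame `gene_id`, `species`, `context`.
#' @export
simulate_ortholog_panels <- function(cfg, truth, anchor = c("saug", "fdaug")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + if (anchor == "saug") 1L else 4L)
  pools <- context_pools(cfg)
  n_all <- length(pools$sorted)
  species <- sprintf("sp%03d", seq_len(cfg$n_species))
  out <- vector("list", nrow(truth))
  for (g in seq_len(nrow(truth))) {
    ref_ctx <- if (anchor == "saug") truth$saug_context[g] else truth$fd_context[g]
    stratum <- if (anchor == "saug") {
      if (truth$class[g] == "weak") pools$weak else pools$strong
    } else {
      # percentile band around the reference context's rank
      r <- match(ref_ctx, pools$sorted)
      half <- ceiling(cfg$conservation_band / 100 * n_all)
      pools$sorted[max(1L, r - half):min(n_all, r + half)]
    }
    conserved <- stats::runif(cfg$n_species) < cfg$conservation
    ctx <- character(cfg$n_species)
    n_c <- sum(conserved)
    ctx[conserved] <- sample(stratum, n_c, replace = TRUE)
    ctx[!conserved] <- sample(pools$all, cfg$n_species - n_c, replace = TRUE)
    ctx[stats::runif(cfg$n_species) < cfg$na_rate] <- NA_character_
    out[[g]] <- data.frame(
      gene_id = truth$gene_id[g],
      species = c("human", species),
      context = c(ref_ctx, ctx),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate ribosome footprint tracks under the leaky-scanning model
#'
#' Elongating mode: expected per-nt relative density is `flux_s` on
#' `[sAUG, fdAUG)` and `flux_s + flux_fd` on `[fdAUG, CDS stop)`, over a
#' small uniform background. Initiating mode: point masses at the sAUG and
#' fdAUG codons proportional to their fluxes (scale `init_peak_factor`)
#' over the background. Counts are drawn independently per nt from a
#' Poisson law (negative binomial when `cfg$nb_size` is set) whose mean is
#' the relative density rescaled per transcript so that `cfg$depth` equals
#' the expected reads per CDS nt; since the analysis normalizes per
#' transcript, the rescaling leaves every density ratio and profile
#' unchanged while keeping the footprint-count filter meaningful across
#' flux levels. Deterministic under the config seed.
#'
#' @param cfg a `sim_config`.
#' @param transcripts catalog data frame from [simulate_transcripts()].
#' @param truth matching truth table (supplies the fluxes).
#' @param mode `"elongating_A_site"` or `"initiating_P_site"`.
#' @return a `footprint_tracks` object.
#' @export
simulate_footprints <- function(cfg, transcripts, truth,
                                mode = c("elongating_A_site",
                                         "initiating_P_site")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + if (mode == "elongating_A_site") 2L else 3L)
  m <- match(transcripts$transcript_id, truth$transcript_id)
  counts <- vector("list", nrow(transcripts))
  names(counts) <- transcripts$transcript_id
  for (j in seq_len(nrow(transcripts))) {
    len <- nchar(transcripts$seq[j])
    cs <- transcripts$cds_start[j]; ce <- transcripts$cds_end[j]
    fd <- cs + truth$spacer_nt[m[j]]
    fs <- truth$flux_s[m[j]]; ff <- truth$flux_fd[m[j]]
    rel <- rep(cfg$background_density, len)
    if (mode == "elongating_A_site") {
      rel[(cs + 1L):fd] <- rel[(cs + 1L):fd] + fs
      rel[(fd + 1L):ce] <- rel[(fd + 1L):ce] + fs + ff
    } else {
      rel[(cs + 1L):(cs + 3L)] <- rel[(cs + 1L):(cs + 3L)] +
        cfg$init_peak_factor * fs / 3
      rel[(fd + 1L):(fd + 3L)] <- rel[(fd + 1L):(fd + 3L)] +
        cfg$init_peak_factor * ff / 3
    }
    # scale so that `depth` is the expected read count per CDS nt for
    # every transcript (the analysis normalizes per transcript, so this
    # scaling leaves all density ratios and profiles unchanged)
    mu <- cfg$depth * rel / mean(rel[(cs + 1L):ce])
    counts[[j]] <- if (is.null(cfg$nb_size)) {
      stats::rpois(len, mu)
    } else {
      stats::rnbinom(len, size = cfg$nb_size, mu = mu)
    }
  }
  footprint_tracks(counts, mode)
}

#' Write a truth table as TSV
#'
#' @param truth truth data frame.
#' @param path output path.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a truth table from TSV
#'
#' @param path path to the TSV written by [write_truth_table()].
#' @return truth data frame.
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
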