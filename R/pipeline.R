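# End-to-end pipeline: simulate -> annotate -> cohorts -> conservation ->
# metagene, with a figure-keyed JSON report.  Each stage is an exported
# function reading and writing the package's file formats; run_pipeline()
# chains them inside one output directory.

cr_to_list <- function(cr) {
  if (is.null(cr)) return(NULL)
  list(test = cr$test, statistic = cr$statistic, p_value = cr$p_value,
       n1 = cr$n1, n2 = cr$n2,
       warning = if (is.na(cr$warning)) NULL else cr$warning)
}

frames_to_list <- function(fp) {
  list(counts = fp$count, proportions = fp$proportion)
}

#' Simulation stage: write synthetic inputs to a directory
#'
#' Emits exactly the formats the analysis stages read: transcript FASTA +
#' CDS TSV, the synthetic TIE table, sAUG- and fdAUG-anchored ortholog
#' panel TSVs, elongating and initiating footprint track TSVs, the truth
#' table, and the serialized config for provenance.
#'
#' @param cfg a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
pipeline_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  sim <- simulate_transcripts(cfg)
  write_transcript_catalog(sim$transcripts, p("transcripts.fa"),
                           p("cds.tsv"))
  write_truth_table(sim$truth, p("truth.tsv"))
  write_tie_table(synthetic_tie_table(cfg$scheme), p("tie_table.tsv"))
  write_ortholog_panels(simulate_ortholog_panels(cfg, sim$truth, "saug"),
                        p("panels_saug.tsv"))
  write_ortholog_panels(simulate_ortholog_panels(cfg, sim$truth, "fdaug"),
                        p("panels_fdaug.tsv"))
  write_footprint_tracks(
    simulate_footprints(cfg, sim$transcripts, sim$truth, "elongating_A_site"),
    p("tracks_elongating.tsv"))
  write_footprint_tracks(
    simulate_footprints(cfg, sim$transcripts, sim$truth, "initiating_P_site"),
    p("tracks_initiating.tsv"))
  cfg_out <- cfg
  cfg_out$scheme <- list(base = cfg$scheme$base,
                         weights = as.data.frame(cfg$scheme$weights))
  jsonlite::write_json(unclass(cfg_out), p("sim_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(
    fasta = p("transcripts.fa"), cds = p("cds.tsv"), truth = p("truth.tsv"),
    tie_table = p("tie_table.tsv"),
    panels_saug = p("panels_saug.tsv"), panels_fdaug = p("panels_fdaug.tsv"),
    tracks_elongating = p("tracks_elongating.tsv"),
    tracks_initiating = p("tracks_initiating.tsv"),
    config = p("sim_config.json")
  ))
}

#' Annotation stage: catalog filtering and start-pair table
#'
#' @param dir directory holding `transcripts.fa`, `cds.tsv`,
#'   `tie_table.tsv` (as written by [pipeline_simulate()] or supplied by
#'   the user).
#' @return list with `transcripts`, `kept`, `pairs`, `rejection_log`;
#'   writes `start_pairs.tsv` and `rejections.tsv` into `dir`.
#' @export
pipeline_annotate <- function(dir) {
  transcripts <- read_transcript_catalog(file.path(dir, "transcripts.fa"),
                                         file.path(dir, "cds.tsv"))
  table <- load_tie_table(file.path(dir, "tie_table.tsv"))
  flt <- filter_catalog(transcripts)
  pairs <- annotate_pairs(flt$kept, table)
  write_start_pairs(pairs, file.path(dir, "start_pairs.tsv"))
  utils::write.table(flt$log, file.path(dir, "rejections.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(transcripts = transcripts, kept = flt$kept, pairs = pairs,
       rejection_log = flt$log, tie_table = table)
}

#' Cohort stage: strong/weak deciles and the frame/distance comparisons
#'
#' @param pairs start-pair data frame (non-miss `saug_tie` rows are used).
#' @param fraction cohort fraction.
#' @return list with `cohorts`, per-cohort frame summaries and the
#'   comparison results keyed by figure panel.
#' @export
pipeline_cohorts <- function(pairs, fraction = 0.10) {
  scored <- pairs[!is.na(pairs$saug_tie), , drop = FALSE]
  cohorts <- select_deciles(scored, fraction)
  res <- list(
    fig1a = list(
      strong = frames_to_list(frame_proportions(cohorts$strong)),
      weak = frames_to_list(frame_proportions(cohorts$weak)),
      chi2 = cr_to_list(compare_frame0(cohorts$strong, cohorts$weak))
    ),
    fig1b = list(
      all_frames = cr_to_list(
        compare_distances(cohorts$strong, cohorts$weak, 0:2, "spacer_nt")),
      in_frame = cr_to_list(
        compare_distances(cohorts$strong, cohorts$weak, 0L, "spacer_nt"))
    ),
    fig1c = cr_to_list(
      compare_distances(cohorts$strong, cohorts$weak, 0L, "fd_stop_nt")),
    fig1d = cr_to_list(compare_fd_context(cohorts$strong, cohorts$weak)),
    supp_s1 = cr_to_list(
      compare_nested_orf_lengths(cohorts$strong, cohorts$weak))
  )
  list(cohorts = cohorts, results = res)
}

#' Conservation stage: TIESS scores and frame-stratified comparisons
#'
#' Scores sAUG- and fdAUG-anchored panels, builds conserved-strong /
#' conserved-weak sets, and compares TIESS between in-frame and
#' out-of-frame genes within each set and anchor.
#'
#' @param dir directory holding `panels_saug.tsv`, `panels_fdaug.tsv` and
#'   `tie_table.tsv`.
#' @param pairs start-pair data frame (frames joined by gene).
#' @param fraction conserved-set fraction.
#' @param min_orthologs minimum scoreable orthologs per gene.
#' @return list with per-anchor records, conserved sets and the `fig3`
#'   comparison block; writes `tiess_<anchor>.tsv` into `dir`.
#' @export
pipeline_tiess <- function(dir, pairs, fraction = 0.10, min_orthologs = 1L) {
  table <- load_tie_table(file.path(dir, "tie_table.tsv"))
  out <- list()
  fig3 <- list()
  for (anchor in c("saug", "fdaug")) {
    panels <- read_ortholog_panels(
      file.path(dir, paste0("panels_", anchor, ".tsv")))
    records <- tiess_scores(panels, table, min_orthologs = min_orthologs)
    write_tiess(records, file.path(dir, paste0("tiess_", anchor, ".tsv")))
    sets <- conserved_sets(records, fraction)
    for (set_name in names(sets)) {
      cmp <- compare_tiess_by_frame(sets[[set_name]], pairs)
      fig3[[paste(anchor, set_name, sep = "_")]] <-
        if (cmp$skipped) list(skipped = TRUE, reason = cmp$reason)
        else cr_to_list(cmp$result)
    }
    out[[anchor]] <- list(records = records, sets = sets)
  }
  out$fig3 <- fig3
  out
}

#' Metagene stage: fdAUG-anchored profiles and window-density comparisons
#'
#' Builds fdAUG-anchored metagene matrices for the weak and strong cohorts
#' from the elongating and initiating tracks, compares downstream-window
#' densities (weak vs strong), and reports the initiating-mode peak height
#' at the anchor.
#'
#' @param dir directory holding the track TSVs.
#' @param transcripts catalog data frame.
#' @param cohorts list with `strong` and `weak` start-pair cohorts.
#' @param cfg a `metagene_config`.
#' @return list with `fig2a` (elongating) and `fig2b` (initiating) blocks;
#'   writes per-cohort median profiles into `dir`.
#' @export
pipeline_metagene <- function(dir, transcripts, cohorts,
                              cfg = metagene_config()) {
  out <- list()
  specs <- list(
    fig2a = list(file = "tracks_elongating.tsv", mode = "elongating_A_site"),
    fig2b = list(file = "tracks_initiating.tsv", mode = "initiating_P_site")
  )
  for (key in names(specs)) {
    tracks <- read_footprint_tracks(file.path(dir, specs[[key]]$file),
                                    transcripts, specs[[key]]$mode)
    block <- list()
    wd <- list()
    for (side in c("strong", "weak")) {
      sub_ids <- cohorts[[side]]$transcript_id
      sub_tr <- transcripts[transcripts$transcript_id %in% sub_ids, ,
                            drop = FALSE]
      mat <- metagene_matrix(sub_tr, tracks, cohorts[[side]], cfg,
                             anchor = "fdaug")
      prof <- metagene_profile(mat)
      write_metagene_profile(
        prof, file.path(dir, paste0("profile_", key, "_", side, ".tsv")))
      wd[[side]] <- window_densities(mat, cfg)
      block[[side]] <- list(
        n_included = nrow(mat$densities),
        median_peak_offset0 =
          prof$median_density[match(0L, prof$offset)]
      )
    }
    cmp <- compare_window_densities(wd$weak, wd$strong)
    block$downstream_weak_vs_strong <- cr_to_list(cmp$downstream)
    block$upstream_weak_vs_strong <- cr_to_list(cmp$upstream)
    out[[key]] <- block
  }
  out
}

#' Proteoform stage: digest and classify one worked transcript
#'
#' Translates the long (sAUG) proteoform of a transcript with an in-frame
#' fdAUG, digests it, classifies peptides against the fdAUG-encoded Met,
#' and writes the classified peptide table.
#'
#' @param dir output directory.
#' @param transcripts catalog data frame.
#' @param pairs start-pair data frame.
#' @return summary list (or `NULL` when no in-frame pair exists).
#' @export
pipeline_peptides <- function(dir, transcripts, pairs) {
  cand <- pairs[pairs$frame == 0L, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  row <- cand[1L, ]
  k <- match(row$transcript_id, transcripts$transcript_id)
  long <- translate_from(transcripts$seq[k], row$saug_pos)
  calls <- classify_peptides(tryptic_digest(long$protein),
                             fd_met_index = row$spacer_nt / 3L)
  write_peptide_calls(calls, file.path(dir, "peptides.tsv"))
  list(transcript_id = row$transcript_id,
       n_unique_long = sum(calls$class == "unique_long" & calls$detectable),
       n_shared = sum(calls$class == "shared" & calls$detectable))
}

#' Run the full pipeline and write a figure-keyed JSON report
#'
#' Chains simulation, annotation, cohort statistics, TIESS conservation,
#' metagene analysis and the proteoform demonstration inside `out_dir`,
#' then writes `report.json` keyed by figure panel (`fig1a`..`fig1d`,
#' `supp_s1`, `fig2a`, `fig2b`, `fig3`, `fig4e`) plus the config hash and
#' seed. Re-running with identical inputs reproduces the report
#' byte-for-byte.
#'
#' @param out_dir output directory.
#' @param cfg a `sim_config`.
#' @param fraction cohort fraction for deciles and conserved sets.
#' @param mg_cfg a `metagene_config`.
#' @return the report list, invisibly; side effect: files in `out_dir`.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(), fraction = 0.10,
                         mg_cfg = metagene_config()) {
  pipeline_simulate(cfg, out_dir)
  ann <- pipeline_annotate(out_dir)
  coh <- pipeline_cohorts(ann$pairs, fraction)
  cons <- pipeline_tiess(out_dir, ann$pairs, fraction)
  mg <- pipeline_metagene(out_dir, ann$transcripts, coh$cohorts, mg_cfg)
  pep <- pipeline_peptides(out_dir, ann$transcripts, ann$pairs)
  report <- c(
    list(seed = cfg$seed,
         config_hash = config_hash(cfg),
         n_transcripts = nrow(ann$transcripts),
         n_kept = nrow(ann$pairs)),
    coh$results,
    mg,
    list(fig3 = cons$fig3, fig4e = pep)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

# config with the weight matrix flattened for stable serialization
sim_config_serializable <- function(cfg) {
  cfg$scheme <- list(base = cfg$scheme$base,
                     weights = as.vector(cfg$scheme$weights))
  cfg
}

#' Deterministic hash of a simulation config
#'
#' Serializes the config to canonical JSON and returns a short hex digest,
#' so equal configs map to equal hashes in run logs and reports.
#'
#' @param cfg a `sim_config`.
#' @return character scalar.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(sim_config_serializable(cfg)),
                        auto_unbox = TRUE, digits = NA)
  # small stable polynomial rolling hash; enough to key a run log
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
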