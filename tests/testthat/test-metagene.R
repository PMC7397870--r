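test_that("track TSV round-trips through the bedGraph-like format", {
  tx <- mg_tx()
  v <- step_track(tx, 1, 3)
  v[5] <- 7
  trk <- footprint_tracks(stats::setNames(list(v), tx$transcript_id),
                          "elongating_A_site")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_footprint_tracks(trk, path)
  back <- read_footprint_tracks(path, tx, "elongating_A_site")
  expect_equal(back$counts[[tx$transcript_id]], v)
  # out-of-bounds run is a hard error
  writeLines(c("transcript_id\tstart\tend\tcount",
               paste0("TX1\t0\t", tx$length + 10, "\t2")), path)
  expect_error(read_footprint_tracks(path, tx, "elongating_A_site"),
               "out of bounds")
})

test_that("inclusion filters trip each rule once, including strict >40 spacing", {
  cfg <- metagene_config()
  txs <- rbind(
    mg_tx("TXok", leader = 60, spacer = 60),
    mg_tx("TXshortcds", leader = 60, spacer = 60, tail_nt = 30, utr = 150),
    mg_tx("TXlowcov", leader = 60, spacer = 60),
    mg_tx("TXleader", leader = 30, spacer = 60),
    mg_tx("TXspacer40", leader = 60, spacer = 40, tail_nt = 170),
    mg_tx("TXspacer41", leader = 60, spacer = 41, tail_nt = 170),
    mg_tx("TXzerocds", leader = 60, spacer = 60),
    mg_tx("TXnotrack", leader = 60, spacer = 60)
  )
  # TXshortcds: CDS = 30 + 63 = under construction; verify the intent
  expect_lt(txs$cds_end[2] - txs$cds_start[2], 200)
  counts <- list(
    TXok = step_track(txs[1, ], 1, 1),
    TXshortcds = step_track(txs[2, ], 3, 3),
    TXlowcov = step_track(txs[3, ], 0.2, 0.2) * 0 + 0.3,
    TXleader = step_track(txs[4, ], 1, 1),
    TXspacer40 = step_track(txs[5, ], 1, 1),
    TXspacer41 = step_track(txs[6, ], 1, 1),
    TXzerocds = step_track(txs[7, ], 0, 0, leader_bg = 300, utr_bg = 300)
  )
  trk <- footprint_tracks(counts, "elongating_A_site")
  pairs <- mg_pairs(txs)

  res_s <- apply_metagene_filters(txs, trk, pairs, cfg, "saug")
  expect_true(all(c("TXok", "TXspacer40", "TXspacer41") %in% res_s$included))
  expect_identical(
    res_s$log$reason[match(c("TXshortcds", "TXlowcov", "TXleader",
                             "TXzerocds", "TXnotrack"),
                           res_s$log$transcript_id)],
    c("short_cds", "low_coverage", "short_leader", "zero_cds_counts",
      "no_track"))

  res_f <- apply_metagene_filters(txs, trk, pairs, cfg, "fdaug")
  # spacer exactly 40 is excluded (strict >), 41 is kept
  expect_false("TXspacer40" %in% res_f$included)
  expect_true("TXspacer41" %in% res_f$included)
  expect_identical(
    res_f$log$reason[res_f$log$transcript_id == "TXspacer40"],
    "short_spacer")
  # order independence: a permuted catalog gives the same partition
  perm <- sample(nrow(txs))
  res_p <- apply_metagene_filters(txs[perm, ], trk, pairs, cfg, "saug")
  expect_setequal(res_p$included, res_s$included)
})

test_that("codon densities normalize the CDS mean to 1 and match a binning oracle", {
  tx <- mg_tx()
  uni <- step_track(tx, 2, 2, leader_bg = 2, utr_bg = 2)
  d <- codon_densities(uni, tx$cds_start, tx$cds_end, tx$cds_start, 0:20)
  expect_equal(unname(d), rep(1, 21))
  # 1 before the fdAUG, 3 after: post/pre codon-density ratio is exactly 3
  stp <- step_track(tx, 1, 3)
  fd <- find_fdaug(tx$seq, tx$cds_start, tx$cds_end)
  ds <- codon_densities(stp, tx$cds_start, tx$cds_end, fd, -10:10)
  expect_equal(unname(ds["5"] / ds["-5"]), 3)
  # CDS-mean normalization invariant
  n_codons <- (tx$cds_end - tx$cds_start) / 3
  full <- codon_densities(stp, tx$cds_start, tx$cds_end, tx$cds_start,
                          0:(n_codons - 1))
  expect_equal(mean(full), 1, tolerance = 1e-9)
  # random track against a brute-force 3-nt binning oracle
  set.seed(17)
  v <- stats::rpois(tx$length, 2) + 1
  offs <- -5:30
  got <- codon_densities(v, tx$cds_start, tx$cds_end, tx$cds_start, offs)
  norm <- sum(v[(tx$cds_start + 1):tx$cds_end]) / n_codons
  want <- vapply(offs, function(k) {
    p <- tx$cds_start + 3 * k
    if (p < 0 || p + 3 > tx$length) return(NA_real_)
    sum(v[(p + 1):(p + 3)]) / norm
  }, numeric(1))
  expect_equal(unname(got), want)
  # zero CDS counts cannot be normalized
  expect_error(codon_densities(numeric(tx$length), tx$cds_start, tx$cds_end,
                               tx$cds_start, 0:5), "zero CDS")
})

test_that("normalization is idempotent and scale-invariant", {
  tx <- mg_tx()
  set.seed(19)
  v <- stats::rpois(tx$length, 3) + 1
  offs <- -10:40
  d1 <- codon_densities(v, tx$cds_start, tx$cds_end, tx$cds_start, offs)
  # feeding back per-nt densities whose codon sums equal d1: scaling by any
  # positive constant changes nothing
  expect_equal(codon_densities(v * 17.3, tx$cds_start, tx$cds_end,
                               tx$cds_start, offs), d1)
  # normalizing an already-normalized per-nt track is a no-op
  norm <- sum(v[(tx$cds_start + 1):tx$cds_end]) /
    ((tx$cds_end - tx$cds_start))
  expect_equal(codon_densities(v / norm, tx$cds_start, tx$cds_end,
                               tx$cds_start, offs), d1)
})

test_that("metagene profile takes per-offset medians with masking", {
  tx <- rbind(mg_tx("TX1"), mg_tx("TX2"), mg_tx("TX3"))
  counts <- list(TX1 = step_track(tx[1, ], 1, 1),
                 TX2 = step_track(tx[2, ], 1, 1),
                 TX3 = step_track(tx[3, ], 4, 4))
  trk <- footprint_tracks(counts, "elongating_A_site")
  pairs <- mg_pairs(tx)
  mat <- metagene_matrix(tx, trk, pairs, metagene_config(), "fdaug",
                         offsets = -15:44)
  prof <- metagene_profile(mat)
  # constant per-transcript densities {1,1,4} -> median 1 (within the CDS)
  inside <- prof$offset >= -15 & prof$offset <= 44
  expect_true(all(abs(prof$median_density[prof$n == 3] - 1) < 1e-9))
  # single transcript: profile equals its own vector
  mat1 <- metagene_matrix(tx[1, ], trk, pairs[1, ], metagene_config(),
                          "fdaug", offsets = -15:44)
  prof1 <- metagene_profile(mat1)
  expect_equal(prof1$median_density, unname(mat1$densities[1, ]))
  # masking: min_n above the cohort size blanks everything
  expect_true(all(is.na(metagene_profile(mat, min_n = 10)$median_density)))
  # median invariant to adding an all-median transcript
  tx4 <- rbind(tx, mg_tx("TX4"))
  counts$TX4 <- step_track(tx4[4, ], 1, 1)
  mat4 <- metagene_matrix(tx4, footprint_tracks(counts, "elongating_A_site"),
                          mg_pairs(tx4), metagene_config(), "fdaug",
                          offsets = -15:44)
  prof4 <- metagene_profile(mat4)
  expect_equal(prof4$median_density, prof$median_density)
})

test_that("window densities equal slice means and identical cohorts give p = 1", {
  cfg <- metagene_config()
  tx <- rbind(mg_tx("TX1"), mg_tx("TX2"), mg_tx("TX3"))
  counts <- list(TX1 = step_track(tx[1, ], 1, 2),
                 TX2 = step_track(tx[2, ], 1, 2),
                 TX3 = step_track(tx[3, ], 1, 2))
  trk <- footprint_tracks(counts, "elongating_A_site")
  mat <- metagene_matrix(tx, trk, mg_pairs(tx), cfg, "fdaug")
  wd <- window_densities(mat, cfg)
  expect_equal(nrow(wd$densities), 3)
  # slice-mean oracle straight off the matrix
  m <- mat$densities
  up_cols <- as.character(-15:-3); dn_cols <- as.character(10:44)
  expect_equal(wd$densities$upstream, unname(rowMeans(m[, up_cols])))
  expect_equal(wd$densities$downstream, unname(rowMeans(m[, dn_cols])))
  cmp <- compare_window_densities(wd, wd)
  expect_equal(cmp$downstream$p_value, 1)
  expect_equal(cmp$upstream$p_value, 1)
})

test_that("step change reads 1.0 on uniform tracks and the constructed ratio on steps", {
  tx <- mg_tx()
  fd <- find_fdaug(tx$seq, tx$cds_start, tx$cds_end)
  uni <- step_track(tx, 2, 2)
  sc <- step_change(uni, tx$cds_start, tx$cds_end, fd)
  expect_equal(sc$ratio, 1)
  expect_true(sc$clean)
  stp <- step_track(tx, 1, 3)
  sc3 <- step_change(stp, tx$cds_start, tx$cds_end, fd)
  expect_equal(sc3$ratio, 3)
  # zero upstream flags undefined
  z <- step_track(tx, 0, 3)
  scz <- step_change(z, tx$cds_start, tx$cds_end, fd)
  expect_true(scz$undefined)
  # spacer below the upstream window reach is flagged not clean
  tx2 <- mg_tx("TX2", spacer = 42)
  fd2 <- find_fdaug(tx2$seq, tx2$cds_start, tx2$cds_end)
  sc2 <- step_change(step_track(tx2, 1, 3), tx2$cds_start, tx2$cds_end, fd2)
  expect_false(sc2$clean)
})
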