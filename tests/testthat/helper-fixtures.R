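# Shared fixtures and independent oracles used across the test files.

# one-row transcript catalog from explicit leader/CDS/UTR parts
make_tx <- function(cds, leader = "CCACCA", utr = "CCCCCC",
                    id = "TX1", gene = "G1") {
  seq <- paste0(leader, cds, utr)
  data.frame(
    transcript_id = id, gene_id = gene, seq = seq,
    cds_start = nchar(leader), cds_end = nchar(leader) + nchar(cds),
    length = nchar(seq), stringsAsFactors = FALSE
  )
}

# naive left-to-right scan for the first downstream AUG within the CDS
oracle_find_fdaug <- function(seq, cds_start, cds_end) {
  for (p in seq.int(cds_start + 1L, cds_end - 3L)) {
    if (substr(seq, p + 1L, p + 3L) == "AUG") return(p)
  }
  NA_integer_
}

# codon-walk frame oracle: step 3 nt from the sAUG and see where we land
oracle_frame <- function(saug_pos, fdaug_pos) {
  p <- saug_pos
  while (p + 3L <= fdaug_pos) p <- p + 3L
  as.integer(fdaug_pos - p)
}

# brute-force codon enumeration for the first in-frame stop
oracle_stop_distance <- function(seq, start_pos) {
  p <- start_pos + 3L
  while (p + 3L <= nchar(seq)) {
    if (substr(seq, p + 1L, p + 3L) %in% c("UAA", "UAG", "UGA")) {
      return(p - start_pos)
    }
    p <- p + 3L
  }
  NA_integer_
}

# regex-free scan oracle for tryptic cleavage boundaries
oracle_digest_bounds <- function(protein) {
  res <- strsplit(protein, "")[[1L]]
  bounds <- 0L
  for (i in seq_len(nchar(protein) - 1L)) {
    if (res[i] %in% c("K", "R") && res[i + 1L] != "P") {
      bounds <- c(bounds, i)
    }
  }
  c(bounds, nchar(protein))
}

# panel rows for one gene from a vector of contexts
panel_one <- function(gene, contexts, species = NULL) {
  if (is.null(species)) species <- sprintf("sp%03d", seq_along(contexts))
  data.frame(gene_id = gene, species = species, context = contexts,
             stringsAsFactors = FALSE)
}

# a transcript long enough for the default metagene windows, with an fdAUG
# at a controllable spacer
mg_tx <- function(id = "TX1", leader = 60L, spacer = 60L, tail_nt = 150L,
                  utr = 30L) {
  cds_len <- spacer + 3L + tail_nt
  cds_len <- cds_len + (3L - cds_len %% 3L) %% 3L
  seq <- strrep("C", leader + cds_len + utr)
  substr(seq, leader + 1L, leader + 3L) <- "AUG"
  substr(seq, leader + spacer + 1L, leader + spacer + 3L) <- "AUG"
  substr(seq, leader + cds_len - 2L, leader + cds_len) <- "UAA"
  data.frame(transcript_id = id, gene_id = sub("TX", "G", id), seq = seq,
             cds_start = leader, cds_end = leader + cds_len,
             length = nchar(seq), stringsAsFactors = FALSE)
}

mg_pairs <- function(tx) {
  fd <- vapply(seq_len(nrow(tx)), function(j)
    find_fdaug(tx$seq[j], tx$cds_start[j], tx$cds_end[j]), integer(1))
  data.frame(transcript_id = tx$transcript_id,
             gene_id = tx$gene_id,
             saug_pos = tx$cds_start,
             fdaug_pos = fd,
             spacer_nt = fd - tx$cds_start,
             stringsAsFactors = FALSE)
}

# per-nt track with distinct rates before/after the fdAUG
step_track <- function(tx, before = 1, after = 1, leader_bg = 0, utr_bg = 0) {
  fd <- find_fdaug(tx$seq, tx$cds_start, tx$cds_end)
  v <- numeric(tx$length)
  if (tx$cds_start > 0) v[1:tx$cds_start] <- leader_bg
  v[(tx$cds_start + 1):fd] <- before
  v[(fd + 1):tx$cds_end] <- after
  if (tx$cds_end < tx$length) v[(tx$cds_end + 1):tx$length] <- utr_bg
  v
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# small measured-style TIE table over hand-picked contexts
toy_tie_table <- function() {
  tie_table(c(
    ACCACCAUGGC = 120, UUUUUUAUGUU = 8, GCCGCCAUGGA = 95,
    CCAACCAUGGU = 60, AAAAAAAUGAA = 25, ACCACCAUGAA = 70,
    AUGAAAAUGUA = 15
  ), provenance = "measured")
}
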