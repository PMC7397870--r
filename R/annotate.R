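# Transcript catalog parsing, filtering and sAUG/fdAUG start-pair
# annotation.
#
# Conventions: all positions are 0-based, CDS intervals are half-open
# [cds_start, cds_end).  1-based coordinates appear only in rendered
# reports.  The sAUG is the annotated start codon at cds_start; the fdAUG
# is the first AUG starting at or after cds_start+1 whose codon fits fully
# before cds_end.

#' Read a transcript catalog (FASTA + CDS coordinate TSV)
#'
#' The TSV must have a header `transcript_id gene_id cds_start cds_end`
#' (tab-separated, 0-based half-open coordinates). Every FASTA record needs
#' a CDS row; a missing row is an error naming the transcript.
#'
#' @param fasta_path path to a FASTA file of transcript sequences.
#' @param cds_path path to the CDS coordinate TSV.
#' @return data frame with columns `transcript_id`, `gene_id`, `seq`
#'   (RNA alphabet), `cds_start`, `cds_end`, `length`.
#' @export
read_transcript_catalog <- function(fasta_path, cds_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  cds <- utils::read.delim(cds_path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id", "cds_start", "cds_end")
  if (!all(need %in% names(cds))) {
    stop("CDS table '", cds_path, "' must have columns: ",
         paste(need, collapse = ", "))
  }
  m <- match(ids, cds$transcript_id)
  if (anyNA(m)) {
    stop("no CDS entry for transcript '", ids[which(is.na(m))[1L]], "'")
  }
  seq_chr <- normalize_nt(as.character(seqs))
  data.frame(
    transcript_id = ids,
    gene_id = cds$gene_id[m],
    seq = seq_chr,
    cds_start = as.integer(cds$cds_start[m]),
    cds_end = as.integer(cds$cds_end[m]),
    length = nchar(seq_chr),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a transcript catalog as FASTA + CDS TSV
#'
#' @param transcripts catalog data frame as from [read_transcript_catalog()].
#' @param fasta_path,cds_path output paths.
#' @export
write_transcript_catalog <- function(transcripts, fasta_path, cds_path) {
  seqs <- Biostrings::BStringSet(transcripts$seq)
  names(seqs) <- transcripts$transcript_id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 70L)
  utils::write.table(
    transcripts[, c("transcript_id", "gene_id", "cds_start", "cds_end")],
    cds_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

# 0-based start positions of all (overlapping) AUG occurrences in seq
aug_positions <- function(seq) {
  hits <- gregexpr("(?=AUG)", seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

#' Locate the first downstream AUG (fdAUG) within the CDS
#'
#' Returns the smallest 0-based position `p >= cds_start + 1` with an AUG at
#' `p` and `p + 3 <= cds_end`, i.e. the codon must fit fully inside the CDS.
#' AUGs overlapping the sAUG (p = cds_start+1, +2) are legal hits. `NA` when
#' the CDS contains no downstream AUG.
#'
#' @param seq transcript sequence (RNA alphabet).
#' @param cds_start,cds_end 0-based half-open CDS interval.
#' @return 0-based position or `NA`.
#' @export
find_fdaug <- function(seq, cds_start, cds_end) {
  p <- aug_positions(seq)
  p <- p[p >= cds_start + 1L & p + 3L <= cds_end]
  if (length(p) == 0L) NA_integer_ else p[1L]
}

#' Reading frame of an fdAUG relative to the sAUG
#'
#' `(fdaug_pos - saug_pos) mod 3`; 0 means in-frame.
#'
#' @param saug_pos,fdaug_pos 0-based positions; `fdaug_pos` must be
#'   downstream of `saug_pos`.
#' @return integer vector of frames in `{0, 1, 2}`.
#' @export
classify_frame <- function(saug_pos, fdaug_pos) {
  if (any(fdaug_pos <= saug_pos)) {
    stop("fdaug_pos must be strictly downstream of saug_pos")
  }
  as.integer((fdaug_pos - saug_pos) %% 3L)
}

STOP_CODONS <- c("UAA", "UAG", "UGA")

#' Distance from a start codon to its first in-frame stop
#'
#' Walks codons downstream of `start_pos` to the transcript end (not the CDS
#' end, so ORFs from out-of-frame fdAUGs may terminate inside the 3' UTR).
#' Returns the smallest `k > 0`, divisible by 3, such that the codon at
#' `start_pos + k` is a stop; `k` counts coding nucleotides only (the stop
#' codon itself is excluded). `NA` when no in-frame stop exists before the
#' transcript end (an unterminated ORF).
#'
#' @param seq transcript sequence (RNA alphabet).
#' @param start_pos 0-based position of the AUG.
#' @return integer nt count, or `NA` if unterminated.
#' @export
stop_distance <- function(seq, start_pos) {
  n <- nchar(seq)
  stopifnot(start_pos + 3L <= n)
  if (substr(seq, start_pos + 1L, start_pos + 3L) != "AUG") {
    stop("no AUG at position ", start_pos, " (0-based)")
  }
  if (start_pos + 3L > n - 3L) return(NA_integer_)
  starts <- seq.int(start_pos + 3L, n - 3L, by = 3L)
  codons <- substring(seq, starts + 1L, starts + 3L)
  hit <- which(codons %in% STOP_CODONS)
  if (length(hit) == 0L) NA_integer_ else starts[hit[1L]] - start_pos
}

#' First AUG downstream of the CDS (3' UTR scan)
#'
#' For transcripts whose CDS has no internal AUG after the sAUG, scans the
#' 3' UTR: the first AUG with 0-based start `>= cds_end` and a full codon
#' before the transcript end. `NA` if none.
#'
#' @param seq transcript sequence.
#' @param cds_end 0-based exclusive CDS end.
#' @return 0-based position or `NA`.
#' @export
scan_downstream_of_cds <- function(seq, cds_end) {
  p <- aug_positions(seq)
  p <- p[p >= cds_end & p + 3L <= nchar(seq)]
  if (length(p) == 0L) NA_integer_ else p[1L]
}

# the deduplication stretch: 6 nt upstream of the sAUG through 15 nt after
# the fdAUG codon, clipped at the transcript end
dedup_stretch <- function(seq, cds_start, fdaug_pos) {
  from <- cds_start - 6L + 1L                 # 1-based
  to <- min(nchar(seq), fdaug_pos + 3L + 15L) # 1-based inclusive
  substr(seq, from, to)
}

#' Apply the catalog filtering and deduplication rules
#'
#' In order: (1) reject transcripts whose CDS is malformed (out of bounds or
#' length not divisible by 3); (2) reject transcripts without an AUG at
#' `cds_start`; (3) reject transcripts with fewer than 6 nt upstream of the
#' sAUG; (4) reject transcripts with no fdAUG inside the CDS; (5) within
#' each gene, group surviving transcripts by the stretch from 6 nt upstream
#' of the sAUG through 15 nt past the fdAUG codon — among transcripts with
#' an identical stretch only the longest is kept (ties broken by the
#' lexicographically smallest id); transcripts with differing stretches are
#' all kept. Every rejection is logged; nothing errors.
#'
#' @param transcripts catalog data frame.
#' @return list with `kept` (catalog rows that survive, with an added
#'   `fdaug_pos` column) and `log` (data frame `transcript_id`, `reason`
#'   covering the rejected transcripts). Reasons: `malformed_cds`,
#'   `no_aug_start`, `short_upstream_flank`, `no_fdaug_in_cds`,
#'   `duplicate_stretch`.
#' @export
filter_catalog <- function(transcripts) {
  t <- transcripts
  n <- nrow(t)
  reason <- rep(NA_character_, n)
  len <- nchar(t$seq)

  bad_cds <- is.na(t$cds_start) | is.na(t$cds_end) |
    t$cds_start < 0L | t$cds_end <= t$cds_start | t$cds_end > len |
    (t$cds_end - t$cds_start) %% 3L != 0L
  reason[bad_cds] <- "malformed_cds"

  i <- which(is.na(reason))
  no_aug <- substr(t$seq[i], t$cds_start[i] + 1L, t$cds_start[i] + 3L) != "AUG"
  reason[i[no_aug]] <- "no_aug_start"

  i <- which(is.na(reason))
  reason[i[t$cds_start[i] < 6L]] <- "short_upstream_flank"

  i <- which(is.na(reason))
  fdaug <- rep(NA_integer_, n)
  fdaug[i] <- vapply(i, function(j) {
    find_fdaug(t$seq[j], t$cds_start[j], t$cds_end[j])
  }, integer(1))
  reason[i[is.na(fdaug[i])]] <- "no_fdaug_in_cds"

  # deduplication within genes on the identity of the stretch
  i <- which(is.na(reason))
  if (length(i) > 0L) {
    stretch <- vapply(i, function(j) {
      dedup_stretch(t$seq[j], t$cds_start[j], fdaug[j])
    }, character(1))
    key <- paste(t$gene_id[i], stretch, sep = "\r")
    for (grp in split(seq_along(i), key)) {
      if (length(grp) < 2L) next
      jj <- i[grp]
      ord <- order(-len[jj], t$transcript_id[jj])
      reason[jj[ord[-1L]]] <- "duplicate_stretch"
    }
  }

  kept <- t[is.na(reason), , drop = FALSE]
  kept$fdaug_pos <- fdaug[is.na(reason)]
  rownames(kept) <- NULL
  log <- data.frame(
    transcript_id = t$transcript_id[!is.na(reason)],
    reason = reason[!is.na(reason)],
    stringsAsFactors = FALSE
  )
  list(kept = kept, log = log)
}

#' Annotate sAUG/fdAUG start pairs for a filtered catalog
#'
#' For each kept transcript: locates the fdAUG, classifies its frame,
#' measures the sAUG-to-fdAUG spacer (A-to-A distance in nt, so
#' `frame == spacer mod 3` exactly), extracts both Kozak contexts (misses
#' where flanks are short), looks up TIE values (misses propagate as `NA`),
#' and measures the distance from the fdAUG to its first in-frame stop.
#'
#' @param kept filtered catalog (output of [filter_catalog()]`$kept`).
#' @param table a `tie_table` for context strength lookup.
#' @return data frame of start pairs, one row per transcript: columns
#'   `transcript_id`, `gene_id`, `saug_pos`, `fdaug_pos`, `frame`,
#'   `spacer_nt`, `saug_context`, `fd_context`, `saug_tie`, `fd_tie`,
#'   `fd_stop_nt` (`NA` when unterminated), `fd_unterminated`.
#' @export
annotate_pairs <- function(kept, table) {
  if (is.null(kept$fdaug_pos)) {
    kept$fdaug_pos <- vapply(seq_len(nrow(kept)), function(j) {
      find_fdaug(kept$seq[j], kept$cds_start[j], kept$cds_end[j])
    }, integer(1))
  }
  n <- nrow(kept)
  saug_ctx <- character(n)
  fd_ctx <- character(n)
  fd_stop <- integer(n)
  for (j in seq_len(n)) {
    saug_ctx[j] <- extract_context(kept$seq[j], kept$cds_start[j])
    fd_ctx[j] <- extract_context(kept$seq[j], kept$fdaug_pos[j])
    fd_stop[j] <- stop_distance(kept$seq[j], kept$fdaug_pos[j])
  }
  data.frame(
    transcript_id = kept$transcript_id,
    gene_id = kept$gene_id,
    saug_pos = kept$cds_start,
    fdaug_pos = kept$fdaug_pos,
    frame = classify_frame(kept$cds_start, kept$fdaug_pos),
    spacer_nt = kept$fdaug_pos - kept$cds_start,
    saug_context = saug_ctx,
    fd_context = fd_ctx,
    saug_tie = tie_lookup(table, saug_ctx),
    fd_tie = tie_lookup(table, fd_ctx),
    fd_stop_nt = fd_stop,
    fd_unterminated = is.na(fd_stop),
    stringsAsFactors = FALSE
  )
}

#' Write a start-pair table as TSV
#'
#' @param pairs start-pair data frame from [annotate_pairs()].
#' @param path output path.
#' @export
write_start_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
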