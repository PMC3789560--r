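#' Extract fixed-length flanks around SSR tracts
#'
#' Pulls the genomic sequence immediately left and right of every tract.
#' Loci too close to a contig end for a full flank, or whose flank contains
#' too many `N` bases, are dropped with a logged reason (returned in the
#' `"dropped"` attribute).
#'
#' @param tracts An `ssr_tracts` tibble (one genome).
#' @param genome The matching [genome_seq()].
#' @param config A [flank_config()].
#' @return A tibble of class `flanked_loci`: the tract columns plus
#'   `locus_id`, `left_flank`, `right_flank` and placeholder columns
#'   `left_hits`, `right_hits`, `unique` (set by [screen_uniqueness()]).
#' @export
extract_flanks <- function(tracts, genome, config = flank_config()) {
  stopifnot(inherits(genome, "genome_seq"))
  fl <- config$flank_len
  tr <- tibble::as_tibble(tracts)
  if (!all(tr$seq_id %in% names(genome$seq)))
    stop("tracts refer to seq_id(s) absent from the genome")
  lens <- genome_lengths(genome)[tr$seq_id]
  fits <- tr$start >= fl & tr$end + fl <= lens
  dropped <- tibble::tibble(seq_id = tr$seq_id[!fits],
                            start = tr$start[!fits],
                            reason = "flank truncated at contig end")
  tr <- tr[fits, , drop = FALSE]
  if (nrow(tr)) {
    tr$left_flank <- unname(mapply(function(sid, s)
      genome_sub(genome, sid, s - fl, s), tr$seq_id, tr$start))
    tr$right_flank <- unname(mapply(function(sid, e)
      genome_sub(genome, sid, e, e + fl), tr$seq_id, tr$end))
    n_frac <- function(x) (nchar(x) - nchar(gsub("N", "", x, fixed = TRUE))) /
      nchar(x)
    ok_n <- n_frac(tr$left_flank) < config$max_flank_n_frac &
      n_frac(tr$right_flank) < config$max_flank_n_frac
    dropped <- dplyr::bind_rows(dropped,
      tibble::tibble(seq_id = tr$seq_id[!ok_n], start = tr$start[!ok_n],
                     reason = "flank too N-rich"))
    tr <- tr[ok_n, , drop = FALSE]
  } else {
    tr$left_flank <- character(0); tr$right_flank <- character(0)
  }
  if (nrow(dropped))
    message(nrow(dropped), " locus/loci dropped during flank extraction")
  tr$locus_id <- sprintf("%s:%s:%d-%d", tr$genome_id, tr$seq_id, tr$start,
                         tr$end)
  tr$left_hits <- NA_integer_; tr$right_hits <- NA_integer_
  tr$unique <- NA
  out <- dplyr::relocate(tr, "locus_id")
  attr(out, "dropped") <- dropped
  class(out) <- c("flanked_loci", setdiff(class(out), "ssr_tracts"))
  out
}

#' Screen flank uniqueness against the genome
#'
#' Counts genomic hits for each flank with a seeded ungapped search: exact
#' `seed_len`-mer seeds on both strands, each seed diagonal extended without
#' gaps across the full flank, identity computed over the aligned columns.
#' A hit is any interval with identity strictly above `min_identity` over
#' strictly more than `min_coverage * flank_len` aligned columns. Hits
#' overlapping the flank's own interval by at least half the flank are
#' collapsed into the single self-hit, so `left_hits`/`right_hits` are at
#' least 1 for every locus. A locus is `unique` when both flanks have at
#' most `max_hits` hits (default: exactly the self-hit).
#'
#' This replaces a BLASTN screen: at 300 bp and >90% identity the identity
#' and coverage thresholds — not an e-value — are the binding constraints.
#' Precomputed tabular alignments can be supplied instead via `hits`.
#'
#' @param loci A `flanked_loci` tibble from [extract_flanks()].
#' @param genome The matching [genome_seq()].
#' @param config A [flank_config()].
#' @param hits Optional precomputed alignment table (BLAST outfmt-6 style
#'   columns `qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore`) with `qseqid` of the form
#'   `<locus_id>|left` / `<locus_id>|right`; only the filtering logic is
#'   applied.
#' @return `loci` with `left_hits`, `right_hits` and `unique` filled in.
#' @export
screen_uniqueness <- function(loci, genome, config = flank_config(),
                              hits = NULL) {
  stopifnot(inherits(genome, "genome_seq"))
  if (nrow(loci) == 0L) return(loci)
  if (!is.null(hits)) return(screen_from_hits(loci, config, hits))
  counts <- count_flank_hits(loci, genome, config)
  loci$left_hits <- counts$left
  loci$right_hits <- counts$right
  loci$unique <- loci$left_hits <= config$max_hits &
    loci$right_hits <= config$max_hits
  loci
}

# 2-bit-coded k-mers of a DNA string as exact doubles (k <= 26); windows
# touching an N come back NA
kmer_codes <- function(s, k) {
  code <- c(A = 0, C = 1, G = 2, T = 3)[seq_chars(s)]
  n <- length(code)
  if (n < k) return(numeric(0))
  acc <- stats::filter(code, 4^((k - 1L):0), sides = 1)
  as.numeric(acc[k:n])
}

# seeded ungapped search for all flanks at once (data.table k-mer join on
# numeric 2-bit codes)
count_flank_hits <- function(loci, genome, config) {
  k <- config$seed_len
  fl <- config$flank_len
  # genome k-mer index
  idx <- data.table::rbindlist(lapply(names(genome$seq), function(sid) {
    kc <- kmer_codes(genome$seq[[sid]], k)
    if (length(kc) == 0L) return(NULL)
    data.table::data.table(kmer = kc, seq_id = sid,
                           gpos = seq_along(kc) - 1L)
  }))
  idx <- idx[!is.na(idx$kmer)]
  data.table::setkey(idx, kmer)

  # one query per (locus, side, strand): forward and reverse-complement
  qtab <- data.table::CJ(row = seq_len(nrow(loci)), side = c("left", "right"),
                         strand = c("+", "-"), sorted = FALSE)
  qtab$qseq <- mapply(function(i, side, strand) {
    fseq <- if (side == "left") loci$left_flank[i] else loci$right_flank[i]
    if (strand == "+") fseq else revcomp(fseq)
  }, qtab$row, qtab$side, qtab$strand)
  qtab$qid <- seq_len(nrow(qtab))
  flanks <- data.table::rbindlist(lapply(seq_len(nrow(qtab)), function(j) {
    kc <- kmer_codes(qtab$qseq[j], k)
    data.table::data.table(qid = j, kmer = kc, fpos = seq_along(kc) - 1L)
  }))
  flanks <- flanks[!is.na(flanks$kmer)]
  seeds <- idx[flanks, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(seeds) == 0L) {          # cannot happen: self-hit always seeds
    return(list(left = rep(0L, nrow(loci)), right = rep(0L, nrow(loci))))
  }
  seeds[, diag := gpos - fpos]
  cand <- unique(seeds[, c("qid", "seq_id", "diag")])
  cand <- merge(cand, qtab, by = "qid")

  # evaluate each candidate ungapped alignment of the full flank
  lens <- genome_lengths(genome)
  min_cols <- config$min_coverage * fl
  n_left <- rep(0L, nrow(loci)); n_right <- rep(0L, nrow(loci))
  hit_rows <- vector("list", nrow(cand))
  for (j in seq_len(nrow(cand))) {
    d <- cand$diag[j]; sid <- cand$seq_id[j]
    a_start <- max(0L, d); a_end <- min(lens[[sid]], d + fl)
    cols <- a_end - a_start
    if (cols <= min_cols) next
    gseg <- genome_sub(genome, sid, a_start, a_end)
    qseg <- substr(cand$qseq[j], a_start - d + 1L, a_end - d)
    ident <- n_matching_chars(gseg, qseg) / cols
    if (ident <= config$min_identity) next
    hit_rows[[j]] <- data.frame(row = cand$row[j], side = cand$side[j],
                                seq_id = sid, h_start = a_start,
                                h_end = a_end)
  }
  hits <- do.call(rbind, hit_rows)
  tally_hits(loci, hits, fl)
}

# collapse near-self hits and count per flank
tally_hits <- function(loci, hits, fl) {
  n_left <- rep(0L, nrow(loci)); n_right <- rep(0L, nrow(loci))
  if (!is.null(hits) && nrow(hits)) {
    for (i in seq_len(nrow(loci))) {
      for (side in c("left", "right")) {
        h <- hits[hits$row == i & hits$side == side, , drop = FALSE]
        if (!nrow(h)) next
        own_start <- if (side == "left") loci$start[i] - fl else loci$end[i]
        own_end <- own_start + fl
        ovl <- pmax(0L, pmin(h$h_end, own_end) - pmax(h$h_start, own_start))
        is_self <- h$seq_id == loci$seq_id[i] & ovl >= fl / 2
        n <- sum(!is_self) + as.integer(any(is_self))
        if (side == "left") n_left[i] <- n else n_right[i] <- n
      }
    }
  }
  list(left = n_left, right = n_right)
}

# apply only the identity/coverage/uniqueness filter to precomputed hits
screen_from_hits <- function(loci, config, hits) {
  fl <- config$flank_len
  keep <- hits$pident / 100 > config$min_identity &
    hits$length > config$min_coverage * fl
  hits <- hits[keep, , drop = FALSE]
  qid <- strsplit(hits$qseqid, "|", fixed = TRUE)
  tab <- data.frame(row = match(vapply(qid, `[`, "", 1L), loci$locus_id),
                    side = vapply(qid, `[`, "", 2L),
                    seq_id = hits$sseqid,
                    h_start = pmin(hits$sstart, hits$send) - 1L,
                    h_end = pmax(hits$sstart, hits$send))
  tab <- tab[!is.na(tab$row), , drop = FALSE]
  counts <- tally_hits(loci, tab, fl)
  loci$left_hits <- counts$left
  loci$right_hits <- counts$right
  loci$unique <- loci$left_hits <= config$max_hits &
    loci$right_hits <= config$max_hits
  loci
}
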