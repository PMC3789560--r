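#' Detect perfect SSR tracts in a genome
#'
#' Scans every sequence for maximal perfect microsatellite tracts with motif
#' lengths 1–6, keeping tracts whose uninterrupted repeat count meets the
#' per-motif-length minima in `config`. Detection follows the MISA
#' conventions used in genome-wide surveys:
#'
#' * only perfect (single-motif, uninterrupted) tracts are reported; a
#'   compound repeat yields its perfect sub-tracts independently;
#' * a tract whose motif is a whole-number repetition of a shorter motif
#'   (e.g. `ATAT`) is reported once, under the shortest motif;
#' * `N` terminates any tract, so consensus gaps never fabricate repeats;
#' * reported tracts never overlap: partial overlaps resolve to the longer
#'   tract, ties to the smaller motif length, then leftmost;
#' * the motif is reported in its observed phase (the rotation starting at
#'   the tract's first base).
#'
#' @param genome A [genome_seq()].
#' @param config A [detection_config()].
#' @return A tibble of class `ssr_tracts` with columns `genome_id, seq_id,
#'   start, end` (0-based half-open), `motif, motif_len, repeat_count,
#'   tract_seq, motif_class`, sorted by `(seq_id, start)`.
#' @examples
#' g <- genome_seq(c(chr1 = "TGCCCCCCCCCCCCATGGATAACGATCGAT"), "demo")
#' find_ssrs(g)
#' @export
find_ssrs <- function(genome, config = detection_config()) {
  stopifnot(inherits(genome, "genome_seq"),
            inherits(config, "detection_config"))
  per_seq <- lapply(names(genome$seq), function(sid)
    scan_sequence(genome$seq[[sid]], sid, config))
  out <- dplyr::bind_rows(per_seq)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(genome_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          motif = character(), motif_len = integer(),
                          repeat_count = integer(), tract_seq = character(),
                          motif_class = character())
  } else {
    out$genome_id <- genome$genome_id
    out <- dplyr::arrange(out, .data$seq_id, .data$start)
    out <- dplyr::relocate(out, "genome_id")
    out$motif_class <- classify_motif(out$motif)
  }
  class(out) <- c("ssr_tracts", class(out))
  out
}

# candidate tracts for one sequence, then overlap resolution
scan_sequence <- function(s, seq_id, config) {
  cand <- list()
  for (m in seq_len(config$max_motif_len)) {
    k <- config$min_repeats[[as.character(m)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", m, k - 1L)
    hits <- gregexpr(pat, s, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    st <- as.integer(hits)
    len <- attr(hits, "match.length")
    motif <- substr(rep(s, length(st)), st, st + m - 1L)
    keep <- !vapply(motif, has_smaller_period, logical(1), m = m)
    if (!any(keep)) next
    cand[[m]] <- data.frame(start = st[keep] - 1L,
                            end = st[keep] - 1L + len[keep],
                            motif = motif[keep], motif_len = m,
                            repeat_count = as.integer(len[keep] / m))
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-(cand$end - cand$start), cand$motif_len, cand$start), ,
               drop = FALSE]
  acc_start <- integer(0); acc_end <- integer(0); take <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] < acc_end & cand$end[i] > acc_start)) {
      take[i] <- TRUE
      acc_start <- c(acc_start, cand$start[i])
      acc_end <- c(acc_end, cand$end[i])
    }
  }
  cand <- cand[take, , drop = FALSE]
  tibble::tibble(seq_id = seq_id, start = cand$start, end = cand$end,
                 motif = cand$motif, motif_len = cand$motif_len,
                 repeat_count = cand$repeat_count,
                 tract_seq = strrep(cand$motif, cand$repeat_count))
}

# TRUE if motif is a whole-number repetition of a shorter motif
has_smaller_period <- function(motif, m = nchar(motif)) {
  if (m == 1L) return(FALSE)
  for (d in seq_len(m - 1L)) {
    if (m %% d == 0L && strrep(substr(motif, 1L, d), m / d) == motif)
      return(TRUE)
  }
  FALSE
}

#' Canonical motif class label
#'
#' Groups a motif with its reverse complement: the label lists the
#' lexicographically smaller of the two first (`"AG/CT"`); self-complementary
#' motifs get a single-name label (`"AT"`). Cyclic rotations (phase) are NOT
#' collapsed, so `"GA/TC"` stays distinct from `"AG/CT"` — the convention of
#' repeat-class composition tables.
#'
#' @param motif Character vector of motifs over `A,C,G,T`, lengths 1–6.
#' @return Character vector of class labels.
#' @examples
#' classify_motif(c("AG", "GA", "AT", "C"))
#' @export
classify_motif <- function(motif) {
  if (any(grepl("[^ACGT]", motif)) || any(!nzchar(motif)))
    stop("motifs must be non-empty strings over A,C,G,T")
  rc <- revcomp(motif)
  ifelse(motif == rc, motif,
         ifelse(motif < rc, paste0(motif, "/", rc), paste0(rc, "/", motif)))
}

#' Fully canonical motif group (rotation + reverse complement collapsed)
#'
#' The minimal string among all cyclic rotations of the motif and of its
#' reverse complement. Used for cross-genome locus merging, where boundary
#' jitter between genomes shifts the observed phase.
#'
#' @param motif Character vector of motifs.
#' @return Character vector of canonical group strings.
#' @export
canonical_motif <- function(motif) {
  vapply(motif, function(mm) {
    rots <- function(x) {
      n <- nchar(x)
      vapply(seq_len(n) - 1L, function(i)
        paste0(substr(x, i + 1L, n), substr(x, 1L, i)), character(1))
    }
    min(c(rots(mm), rots(revcomp(mm))))
  }, character(1), USE.NAMES = FALSE)
}

#' Repeat-class composition table
#'
#' Tabulates tracts by motif class and repeat-count bin, with the mean
#' repeat number and mean repeat length (bp) per class — the layout of
#' repeat-class tables in genome-wide SSR surveys. Bin edges: `<5, 5–7,
#' 8–10, 11–15, 16–20, 21–25, 26–30, 31–40, >40` repeats.
#'
#' @param tracts An `ssr_tracts` tibble from one genome.
#' @return A tibble with one row per motif class: the nine bin counts,
#'   `total`, `avg_repeat_number`, `avg_repeat_length_bp` (both rounded
#'   half-up to 2 decimals), ordered by motif length then descending count.
#' @export
repeat_class_table <- function(tracts) {
  bins <- c(-Inf, 4, 7, 10, 15, 20, 25, 30, 40, Inf)
  bin_labels <- c("<5", "5-7", "8-10", "11-15", "16-20", "21-25", "26-30",
                  "31-40", ">40")
  tr <- tibble::as_tibble(tracts)
  tr$bin <- cut(tr$repeat_count, breaks = bins, labels = bin_labels)
  tr$motif_class <- tr$motif_class %||% classify_motif(tr$motif)
  wide <- tr |>
    dplyr::count(.data$motif_class, .data$bin, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "bin", values_from = "n",
                       values_fill = 0L)
  stats_tbl <- tr |>
    dplyr::group_by(.data$motif_class) |>
    dplyr::summarise(
      motif_len = nchar(sub("/.*", "", .data$motif_class[1])),
      total = dplyr::n(),
      avg_repeat_number = round_half_up(mean(.data$repeat_count), 2),
      avg_repeat_length_bp = round_half_up(
        mean(.data$repeat_count) * nchar(sub("/.*", "", .data$motif_class[1])), 2),
      .groups = "drop")
  out <- dplyr::inner_join(stats_tbl, wide, by = "motif_class") |>
    dplyr::arrange(.data$motif_len, dplyr::desc(.data$total)) |>
    dplyr::relocate("motif_class", "motif_len", dplyr::all_of(bin_labels),
                    "total")
  out
}
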