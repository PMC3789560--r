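#' Write marker candidates to TSV, GFF3 or BED
#'
#' The TSV layout is fixed: `marker_id, seq_id, start, end, motif, repeats,
#' fwd_primer, rev_primer, product_len, status` with internal 0-based
#' half-open coordinates. GFF3 output converts to 1-based inclusive; BED
#' stays 0-based half-open (so `BED start = GFF3 start - 1`). An empty
#' marker set yields a header-only (TSV) or track-line-only file.
#'
#' @param markers Tibble with at least `marker_id, seq_id, start, end`;
#'   missing annotation columns are filled with `NA`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"gff3"`, `"bed"`.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path, format = c("tsv", "gff3", "bed")) {
  format <- match.arg(format)
  need <- c("marker_id", "seq_id", "start", "end")
  if (!all(need %in% names(markers)))
    stop("markers must carry columns: ", paste(need, collapse = ", "))
  fill <- function(col) if (col %in% names(markers)) markers[[col]] else
    rep(NA, nrow(markers))
  out <- tibble::tibble(
    marker_id = markers$marker_id, seq_id = markers$seq_id,
    start = as.integer(markers$start), end = as.integer(markers$end),
    motif = fill("motif"), repeats = fill("repeat_count"),
    fwd_primer = fill("fwd_seq"), rev_primer = fill("rev_seq"),
    product_len = fill("product_len"), status = fill("status"))
  switch(format,
    tsv = readr::write_tsv(out, path),
    gff3 = {
      attrs <- paste0("ID=", out$marker_id,
                      ifelse(is.na(out$motif), "",
                             paste0(";motif=", out$motif)))
      lines <- paste(out$seq_id, "ssrmine", "microsatellite",
                     out$start + 1L, out$end, ".", "+", ".", attrs,
                     sep = "\t")
      writeLines(c("##gff-version 3", lines), path)
    },
    bed = {
      lines <- paste(out$seq_id, out$start, out$end, out$marker_id,
                     sep = "\t")
      writeLines(lines, path)
    })
  invisible(path)
}

#' Read a tract/marker TSV written by this package
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_markers_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Export a per-window SSR density track in BED format
#'
#' Counts tracts per fixed-size window along each sequence, a plotting-free
#' stand-in for genome-wide density figures.
#'
#' @param tracts SSR tract tibble (see [find_ssrs()]).
#' @param lengths Named vector of sequence lengths (bp).
#' @param path Output BED path (`chrom, start, end, count`).
#' @param window_size Window width in bp.
#' @return `path`, invisibly.
#' @export
write_density_bed <- function(tracts, lengths, path, window_size = 10000L) {
  rows <- lapply(names(lengths), function(sid) {
    len <- lengths[[sid]]
    starts <- seq(0L, len - 1L, by = window_size)
    ends <- pmin(starts + window_size, len)
    pos <- tracts$start[tracts$seq_id == sid]
    counts <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos < ends[i]), integer(1))
    data.frame(seq_id = sid, start = starts, end = ends, count = counts)
  })
  bed <- do.call(rbind, rows)
  writeLines(paste(bed$seq_id, bed$start, bed$end, bed$count, sep = "\t"),
             path)
  invisible(path)
}
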