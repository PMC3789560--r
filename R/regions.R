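#' Build a genomic-region model from gene annotation
#'
#' Partitions every base of the genome into exactly one of six labels —
#' `CDS`, `five_prime_UTR`, `three_prime_UTR`, `intron`, `promoter`,
#' `intergenic` — from a GFF3 feature table. Introns are gene spans minus
#' exons; promoters are the `promoter_len` bp upstream of each gene's
#' transcription initiation site (strand aware, clipped at contig ends);
#' overlaps between labels are resolved by the configured precedence (CDS
#' wins by default, so a base inside a coding exon that also lies in another
#' gene's promoter is `CDS`).
#'
#' @param features Feature tibble from [read_gff3()] (1-based inclusive
#'   coordinates, as read).
#' @param lengths Named vector of sequence lengths (bp), e.g.
#'   [genome_lengths()].
#' @param config A [region_config()].
#' @return A `region_model`: a tibble `(seq_id, start, end, region)` of
#'   disjoint 0-based half-open intervals covering every base, with the
#'   config attached as an attribute.
#' @export
build_region_model <- function(features, lengths, config = region_config()) {
  if (any(!features$seq_id %in% names(lengths)))
    stop("features refer to seq_id(s) with unknown length")
  if (any(features$end > lengths[features$seq_id]))
    stop("feature extends beyond contig length")
  f0 <- features
  f0$start0 <- f0$start - 1L          # to 0-based half-open
  f0$end0 <- f0$end
  genes <- f0[f0$type == "gene", , drop = FALSE]
  exons <- f0[f0$type == "exon", , drop = FALSE]
  per_seq <- lapply(names(lengths), function(sid) {
    len <- lengths[[sid]]
    ir <- function(tbl) {
      t2 <- tbl[tbl$seq_id == sid, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(t2$start0 + 1L, t2$end0))
    }
    gene_ir <- ir(genes)
    exon_ir <- ir(exons)
    g <- genes[genes$seq_id == sid, , drop = FALSE]
    prom_start <- ifelse(g$strand == "-", g$end0,
                         g$start0 - config$promoter_len)
    prom_end <- ifelse(g$strand == "-", g$end0 + config$promoter_len,
                       g$start0)
    prom_start <- pmax(prom_start, 0L)
    prom_end <- pmin(prom_end, len)
    keep <- prom_end > prom_start
    pool <- list(
      CDS = ir(f0[f0$type == "CDS", , drop = FALSE]),
      five_prime_UTR = ir(f0[f0$type == "five_prime_UTR", , drop = FALSE]),
      three_prime_UTR = ir(f0[f0$type == "three_prime_UTR", , drop = FALSE]),
      intron = BiocGenerics::setdiff(gene_ir, exon_ir),
      promoter = IRanges::reduce(IRanges::IRanges(prom_start[keep] + 1L,
                                                  prom_end[keep])),
      intergenic = IRanges::IRanges(1L, len))
    assigned <- IRanges::IRanges()
    rows <- lapply(config$precedence, function(lab) {
      r <- BiocGenerics::setdiff(pool[[lab]], assigned)
      assigned <<- IRanges::reduce(c(assigned, r))
      if (length(r) == 0L) return(NULL)
      tibble::tibble(seq_id = sid, start = BiocGenerics::start(r) - 1L,
                     end = BiocGenerics::end(r), region = lab)
    })
    dplyr::bind_rows(rows)
  })
  model <- dplyr::bind_rows(per_seq)
  model <- dplyr::arrange(model, .data$seq_id, .data$start)
  attr(model, "config") <- config
  attr(model, "lengths") <- lengths
  class(model) <- c("region_model", class(model))
  model
}

#' Assign each SSR tract to a genomic region
#'
#' A tract's region is the region of its start base: tracts are short
#' relative to features, and a fixed rule keeps boundary-straddling tracts
#' deterministic.
#'
#' @param tracts An `ssr_tracts` tibble.
#' @param model A `region_model` from [build_region_model()].
#' @return `tracts` with an added `region` column.
#' @export
assign_regions <- function(tracts, model) {
  region <- character(nrow(tracts))
  for (sid in unique(tracts$seq_id)) {
    mi <- model[model$seq_id == sid, , drop = FALSE]
    ti <- which(tracts$seq_id == sid)
    if (nrow(mi) == 0L) stop("no region model for seq_id ", sid)
    idx <- findInterval(tracts$start[ti], mi$start)
    if (any(idx == 0L | tracts$start[ti] >= mi$end[idx]))
      stop("tract start outside the region model for seq_id ", sid)
    region[ti] <- mi$region[idx]
  }
  tracts$region <- region
  tracts
}

#' Region-wise SSR summary
#'
#' Counts, mean marker interval, mean tract length and mean GC content per
#' genomic region — the layout of region-distribution tables in genome-wide
#' SSR surveys. Intervals use the total bp assigned to each region.
#'
#' @param tracts An `ssr_tracts` tibble with a `region` column (see
#'   [assign_regions()]).
#' @param model The `region_model` used for assignment.
#' @return A tibble: `region, n, interval_kb, mean_len_bp, gc_pct`, plus a
#'   `Total` row; means rounded half-up to 2 decimals.
#' @export
region_summary <- function(tracts, model) {
  region_bp <- tapply(model$end - model$start, model$region, sum)
  labs <- attr(model, "config")$precedence
  rows <- lapply(labs, function(lab) {
    tr <- tracts[tracts$region == lab, , drop = FALSE]
    tibble::tibble(
      region = lab, n = nrow(tr),
      interval_kb = if (nrow(tr)) round_half_up(
        region_bp[[lab]] / nrow(tr) / 1000, 2) else NA_real_,
      mean_len_bp = if (nrow(tr)) round_half_up(
        mean(tr$end - tr$start), 2) else NA_real_,
      gc_pct = if (nrow(tr)) round_half_up(
        mean(gc_content(tr$tract_seq)), 2) else NA_real_)
  })
  total <- tibble::tibble(
    region = "Total", n = nrow(tracts),
    interval_kb = round_half_up(sum(region_bp) / nrow(tracts) / 1000, 2),
    mean_len_bp = round_half_up(mean(tracts$end - tracts$start), 2),
    gc_pct = round_half_up(mean(gc_content(tracts$tract_seq)), 2))
  dplyr::bind_rows(c(rows, list(total)))
}
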