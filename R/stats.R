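#' Mean marker interval
#'
#' The average spacing between SSR loci: `genome_size / count`, in kb. At
#' the 2.1 Gb default genome size, 135,693 loci give one SSR every 15.48 kb.
#'
#' @param count Number of loci (> 0); vectorised.
#' @param config A [density_config()] supplying the genome size in bp.
#' @return Mean interval(s) in kb (unrounded; reports round half-up to 2
#'   decimals).
#' @examples
#' round_half_up(interval_stats(135693), 2)
#' @export
interval_stats <- function(count, config = density_config()) {
  if (any(count <= 0)) stop("count must be positive")
  config$genome_size / count / 1000
}

#' Allele frequencies from observed calls
#'
#' @param alleles Vector of allele calls (e.g. band lengths in bp); `NA`
#'   entries are dropped.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
allele_freqs <- function(alleles) {
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L) stop("no observed alleles")
  tab <- table(alleles)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

#' Polymorphism information content
#'
#' `PIC = 1 - sum(p_i^2)` over allele frequencies — the discriminating
#' power of a marker; 0 for a monomorphic locus, bounded by `1 - 1/k` for
#' `k` alleles.
#'
#' @param freqs Numeric vector of allele frequencies; must be non-negative
#'   and sum to 1 (within 1e-9).
#' @return PIC value in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))          # 0.5
#' pic(rep(0.25, 4))         # 0.75
#' @export
pic <- function(freqs) {
  if (any(freqs < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9)
    stop("allele frequencies must sum to 1")
  1 - sum(freqs^2)
}

#' PIC of each merged panel locus
#'
#' Treats each panel genome as one sampled line and the per-genome tract
#' lengths (plus an explicit absence class when the locus is missing from
#' some genomes) as band-length alleles, unweighted.
#'
#' @param loci A `panel_loci` tibble from [merge_panel()].
#' @param count_absent Include absence as its own allele class (default
#'   `FALSE`: PIC is computed over the present genomes only).
#' @return `loci` with an added `pic` column.
#' @export
panel_pic <- function(loci, count_absent = FALSE) {
  panel_size <- length(attr(loci, "panel"))
  loci$pic <- vapply(loci$alleles, function(a) {
    calls <- as.character(a$tract_length)
    if (count_absent && length(calls) < panel_size)
      calls <- c(calls, rep("ABSENT", panel_size - length(calls)))
    pic(allele_freqs(calls))
  }, numeric(1))
  loci
}

#' Marker-refinement funnel report
#'
#' Tabulates the marker discovery cascade — all SSR tracts, unique-flank
#' loci, designed primer pairs, e-PCR-verified markers, polymorphic markers
#' — by motif class, with each stage's share of its parent stage and each
#' class's share within a stage. Percentages are `stage / parent * 100`
#' rounded half-up to 2 decimals, so motif-class shares sum to 100 within
#' rounding.
#'
#' @param stages Named list of tibbles in funnel order (e.g. `all`,
#'   `unique_flanks`, `primers`, `epcr_unique`, `polymorphic`); each must
#'   carry a `motif_class` (or `motif_group`) column.
#' @return A tibble: `stage, motif_class, n, pct_of_parent, pct_of_stage`,
#'   including a `Total` row per stage.
#' @export
funnel_report <- function(stages) {
  stopifnot(is.list(stages), length(stages) >= 1L, !is.null(names(stages)))
  get_class <- function(tbl) {
    cls <- tbl[["motif_class"]] %||% tbl[["motif_group"]]
    if (is.null(cls)) stop("each stage needs a motif_class or motif_group column")
    cls
  }
  classes <- sort(unique(unlist(lapply(stages, get_class))))
  rows <- list()
  parent_counts <- NULL
  for (si in seq_along(stages)) {
    cls <- get_class(stages[[si]])
    n_by <- table(factor(cls, levels = classes))
    n_tot <- length(cls)
    parent_by <- parent_counts %||% n_by
    parent_tot <- sum(parent_by)
    rows[[si]] <- tibble::tibble(
      stage = names(stages)[si],
      motif_class = c(classes, "Total"),
      n = c(as.integer(n_by), n_tot),
      pct_of_parent = c(
        ifelse(as.integer(parent_by) > 0,
               pct_of(as.integer(n_by), pmax(as.integer(parent_by), 1L)),
               NA_real_),
        if (parent_tot > 0) pct_of(n_tot, parent_tot) else NA_real_),
      pct_of_stage = c(
        if (n_tot > 0) pct_of(as.integer(n_by), n_tot) else
          rep(NA_real_, length(classes)),
        if (n_tot > 0) 100 else NA_real_))
    parent_counts <- n_by
  }
  dplyr::bind_rows(rows)
}
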