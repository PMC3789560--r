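#' Merge per-genome SSR tracts into panel loci
#'
#' The cross-genome step: tracts from different genomes of a
#' reference-anchored panel are merged into one locus when they lie on the
#' same sequence, share the canonical motif group (reverse complement and
#' cyclic rotation collapsed — boundary jitter between genomes shifts the
#' observed phase), and their start positions chain within `window` bp
#' (single linkage). Within one genome the nearest tract joins a locus;
#' surplus same-genome tracts found a new locus. Locus ids derive from
#' reference coordinates, so the result is invariant to genome input order.
#'
#' @param tracts A tall tibble of SSR tracts from all panel genomes
#'   (rows carry `genome_id`), e.g. `dplyr::bind_rows()` of [find_ssrs()]
#'   outputs.
#' @param config A [merge_config()].
#' @param panel Character vector of all panel genome ids; defaults to the
#'   genomes present in `tracts`. Genomes with no tract at a locus are
#'   recorded as absent.
#' @return A tibble of class `panel_loci`: `locus_id, seq_id, ref_start,
#'   ref_end, motif_group, n_present, poly_class`, and one list-column
#'   `alleles` holding per-genome `(genome_id, tract_length, repeat_count)`
#'   for the genomes where the locus is present.
#' @export
merge_panel <- function(tracts, config = merge_config(), panel = NULL) {
  tr <- tibble::as_tibble(tracts)
  stopifnot(all(c("genome_id", "seq_id", "start", "end", "motif") %in%
                  names(tr)))
  panel <- panel %||% sort(unique(tr$genome_id))
  if (!all(tr$genome_id %in% panel))
    stop("tracts carry genome_id(s) outside the declared panel")
  panel_size <- length(panel)
  tr$motif_group <- if (config$require_same_motif)
    canonical_motif(tr$motif) else "any"
  tr <- dplyr::arrange(tr, .data$seq_id, .data$motif_group, .data$start)
  key <- paste(tr$seq_id, tr$motif_group)
  out <- lapply(split(seq_len(nrow(tr)), key), function(ix) {
    g <- tr[ix, , drop = FALSE]
    # single-linkage chains on start positions
    gap_break <- c(FALSE, diff(g$start) > config$window)
    chain <- cumsum(gap_break)
    dplyr::bind_rows(lapply(split(seq_len(nrow(g)), chain), function(cx) {
      cl <- g[cx, , drop = FALSE]
      # surplus same-genome tracts start a new locus (sweep in start order)
      sub <- integer(nrow(cl))
      seen <- list(character(0))
      cur <- 1L
      for (r in seq_len(nrow(cl))) {
        if (cl$genome_id[r] %in% seen[[cur]]) {
          cur <- cur + 1L
          seen[[cur]] <- character(0)
        }
        seen[[cur]] <- c(seen[[cur]], cl$genome_id[r])
        sub[r] <- cur
      }
      dplyr::bind_rows(lapply(split(seq_len(nrow(cl)), sub), function(sx) {
        mem <- cl[sx, , drop = FALSE]
        tibble::tibble(
          seq_id = mem$seq_id[1],
          ref_start = min(mem$start), ref_end = max(mem$end),
          motif_group = mem$motif_group[1],
          n_present = length(unique(mem$genome_id)),
          alleles = list(tibble::tibble(
            genome_id = mem$genome_id,
            tract_length = mem$end - mem$start,
            repeat_count = mem$repeat_count)))
      }))
    }))
  })
  loci <- dplyr::bind_rows(out)
  if (nrow(loci) == 0L)
    return(structure(tibble::tibble(locus_id = character(),
                                    seq_id = character(),
                                    ref_start = integer(), ref_end = integer(),
                                    motif_group = character(),
                                    n_present = integer(),
                                    poly_class = character(),
                                    alleles = list()),
                     class = c("panel_loci", "tbl_df", "tbl", "data.frame"),
                     panel = panel))
  loci <- dplyr::arrange(loci, .data$seq_id, .data$ref_start,
                         .data$motif_group)
  loci$locus_id <- sprintf("%s:%d-%d:%s", loci$seq_id, loci$ref_start,
                           loci$ref_end, loci$motif_group)
  loci$poly_class <- vapply(loci$alleles, function(a)
    classify_polymorphism(a$tract_length, panel_size), character(1))
  loci <- dplyr::relocate(loci, "locus_id")
  attr(loci, "panel") <- panel
  class(loci) <- c("panel_loci", class(loci))
  loci
}

#' Classify the polymorphism of one panel locus
#'
#' @param tract_lengths Tract lengths (bp) of the genomes where the locus is
#'   present.
#' @param panel_size Total number of panel genomes.
#' @return One of `"monomorphic"` (present in all genomes, all lengths
#'   equal), `"length_polymorphic"` (at least two distinct lengths, present
#'   everywhere), `"presence_absence"` (absent from at least one genome,
#'   present lengths equal), `"both"`.
#' @examples
#' classify_polymorphism(c(20, 20, 20), 3)
#' classify_polymorphism(c(20, 22), 2)
#' classify_polymorphism(c(20, 20), 3)
#' @export
classify_polymorphism <- function(tract_lengths, panel_size) {
  n_present <- length(tract_lengths)
  stopifnot(n_present >= 1L, n_present <= panel_size)
  len_poly <- length(unique(tract_lengths)) >= 2L
  pav <- n_present < panel_size
  if (len_poly && pav) "both"
  else if (len_poly) "length_polymorphic"
  else if (pav) "presence_absence"
  else "monomorphic"
}

#' Loci present in every panel genome
#'
#' @param loci A `panel_loci` tibble.
#' @param panel_size Panel size; defaults to the panel recorded on `loci`.
#' @return The subset of `loci` with `n_present == panel_size`.
#' @export
common_loci <- function(loci, panel_size = NULL) {
  panel_size <- panel_size %||% length(attr(loci, "panel"))
  if (is.null(panel_size) || panel_size == 0L)
    stop("panel_size not given and no panel recorded on loci")
  loci[loci$n_present == panel_size, , drop = FALSE]
}

#' Wide per-genome allele table of a merged panel
#'
#' @param loci A `panel_loci` tibble.
#' @param absent How absent alleles are encoded (default `NA`).
#' @return A tibble with one row per locus and one tract-length column per
#'   panel genome.
#' @export
allele_table <- function(loci, absent = NA_integer_) {
  panel <- attr(loci, "panel")
  tall <- tidyr::unnest(loci[, c("locus_id", "alleles")], "alleles")
  wide <- tidyr::pivot_wider(tall[, c("locus_id", "genome_id",
                                      "tract_length")],
                             names_from = "genome_id",
                             values_from = "tract_length")
  missing_g <- setdiff(panel, names(wide))
  for (g in missing_g) wide[[g]] <- absent
  if (!is.na(absent))
    wide[is.na(wide)] <- absent
  wide[, c("locus_id", panel)]
}
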