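#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a merged panel into one row per locus-genome allele
#'
#' @param x A `panel_loci` tibble from [merge_panel()].
#' @param ... Unused.
#' @return A tall tibble: `locus_id, seq_id, motif_group, poly_class,
#'   genome_id, tract_length, repeat_count`.
#' @method tidy panel_loci
#' @export
tidy.panel_loci <- function(x, ...) {
  tall <- tidyr::unnest(
    tibble::as_tibble(x)[, c("locus_id", "seq_id", "motif_group",
                             "poly_class", "alleles")], "alleles")
  tall
}

#' One-row summary of a merged panel
#'
#' @param x A `panel_loci` tibble.
#' @param ... Unused.
#' @return A one-row tibble: locus count, panel size, counts per
#'   polymorphism class, share of polymorphic loci (%).
#' @method glance panel_loci
#' @export
glance.panel_loci <- function(x, ...) {
  panel_size <- length(attr(x, "panel"))
  n_poly <- sum(x$poly_class != "monomorphic")
  tibble::tibble(
    n_loci = nrow(x), panel_size = panel_size,
    n_monomorphic = sum(x$poly_class == "monomorphic"),
    n_length_polymorphic = sum(x$poly_class == "length_polymorphic"),
    n_presence_absence = sum(x$poly_class == "presence_absence"),
    n_both = sum(x$poly_class == "both"),
    pct_polymorphic = if (nrow(x)) pct_of(n_poly, nrow(x)) else NA_real_)
}

#' One-row summary of a tract scan
#'
#' @param x An `ssr_tracts` tibble from [find_ssrs()].
#' @param ... Optional `config` ([density_config()]) for the mean marker
#'   interval; defaults to the scanned genome size if provided as
#'   `genome_size`.
#' @return A one-row tibble: tract count, counts by motif length, mean
#'   repeat count and tract length.
#' @method glance ssr_tracts
#' @export
glance.ssr_tracts <- function(x, ...) {
  by_len <- table(factor(x$motif_len, levels = 1:6))
  tibble::tibble(
    n_tracts = nrow(x),
    n_mono = as.integer(by_len[["1"]]), n_di = as.integer(by_len[["2"]]),
    n_tri = as.integer(by_len[["3"]]), n_tetra = as.integer(by_len[["4"]]),
    n_penta = as.integer(by_len[["5"]]), n_hexa = as.integer(by_len[["6"]]),
    mean_repeat_count = if (nrow(x)) round_half_up(mean(x$repeat_count), 2)
      else NA_real_,
    mean_tract_len = if (nrow(x)) round_half_up(mean(x$end - x$start), 2)
      else NA_real_)
}

#' One-row summary of an e-PCR batch
#'
#' @param x A `specificity_calls` tibble from [epcr_batch()].
#' @param ... Unused.
#' @return A one-row tibble with marker counts by specificity status.
#' @method glance specificity_calls
#' @export
glance.specificity_calls <- function(x, ...) {
  s <- attr(x, "summary")
  tibble::tibble(n_markers = nrow(x),
                 n_unique = s$unique, n_multi_site = s$multi_site,
                 n_no_site = s$no_site,
                 pct_unique = if (nrow(x)) pct_of(s$unique, nrow(x))
                   else NA_real_)
}
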