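#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the motif-length and repeat-count spectrum of a tract scan
#'
#' @param object An `ssr_tracts` tibble from [find_ssrs()].
#' @param ... Unused.
#' @return A ggplot: tract counts by repeat-count bin, faceted by motif
#'   length.
#' @method autoplot ssr_tracts
#' @export
autoplot.ssr_tracts <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$motif_len <- factor(df$motif_len, levels = 1:6,
                         labels = c("mono", "di", "tri", "tetra", "penta",
                                    "hexa"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$repeat_count)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~motif_len, scales = "free") +
    ggplot2::labs(x = "repeat count", y = "tracts",
                  title = "Perfect SSR tracts by motif length")
}

#' Plot polymorphism-class composition of a merged panel
#'
#' @param object A `panel_loci` tibble from [merge_panel()].
#' @param ... Unused.
#' @return A ggplot bar chart of locus counts per polymorphism class.
#' @method autoplot panel_loci
#' @export
autoplot.panel_loci <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$poly_class)) +
    ggplot2::geom_bar(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "panel loci",
                  title = "Polymorphism classes across the panel")
}

#' Plot SSR density along each sequence
#'
#' @param tracts An `ssr_tracts` tibble.
#' @param lengths Named vector of sequence lengths (bp).
#' @param window_size Window width in bp.
#' @return A ggplot of tract counts per window, one panel per sequence.
#' @export
plot_ssr_density <- function(tracts, lengths, window_size = 10000L) {
  rows <- lapply(names(lengths), function(sid) {
    starts <- seq(0L, lengths[[sid]] - 1L, by = window_size)
    pos <- tracts$start[tracts$seq_id == sid]
    data.frame(seq_id = sid, mid = starts + window_size / 2,
               count = vapply(starts, function(s0)
                 sum(pos >= s0 & pos < s0 + window_size), integer(1)))
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1e3, y = .data$count)) +
    ggplot2::geom_col(width = window_size / 1e3, fill = "grey30") +
    ggplot2::facet_wrap(~seq_id, ncol = 1) +
    ggplot2::labs(x = "position (kb)", y = paste0("SSRs per ",
                                                  window_size / 1e3, " kb"),
                  title = "SSR density")
}
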