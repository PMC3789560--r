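#' Detection thresholds for perfect SSR tracts
#'
#' Minimum numbers of uninterrupted repeat units per motif length. The
#' defaults are the MISA-style thresholds used for genome-wide maize SSR
#' surveys: at least 10 repeats for mononucleotide motifs, 7 for di-, 6 for
#' tri-, 5 for tetra-, and 4 for penta- and hexanucleotide motifs.
#'
#' @param min_repeats Named integer vector; names are motif lengths
#'   `"1"`..`"6"`, values the minimum repeat count.
#' @param max_motif_len Longest motif length scanned (1–6).
#' @return A `detection_config` list.
#' @export
detection_config <- function(min_repeats = c(`1` = 10L, `2` = 7L, `3` = 6L,
                                             `4` = 5L, `5` = 4L, `6` = 4L),
                             max_motif_len = 6L) {
  max_motif_len <- as.integer(max_motif_len)
  stopifnot(max_motif_len >= 1L, max_motif_len <= 6L)
  min_repeats <- stats::setNames(as.integer(min_repeats), names(min_repeats))
  if (!identical(sort(as.integer(names(min_repeats))), seq_len(max_motif_len)))
    stop("min_repeats must have one entry per motif length 1..max_motif_len")
  if (any(min_repeats < 2L))
    stop("all minimum repeat counts must be >= 2")
  structure(list(min_repeats = min_repeats[as.character(seq_len(max_motif_len))],
                 max_motif_len = max_motif_len),
            class = c("detection_config", "ssrmine_config"))
}

#' Flank extraction and uniqueness-screen settings
#'
#' @param flank_len Flank length extracted on each side of a tract (bp).
#' @param min_identity A genomic hit must exceed this identity fraction.
#' @param min_coverage A hit must span more than this fraction of the flank.
#' @param max_hits Maximum hit count (including the self-hit) for a flank to
#'   count as unique.
#' @param seed_len Exact-match seed length for the search index (bp).
#' @param max_flank_n_frac Loci whose flank contains at least this fraction
#'   of `N` bases are dropped before screening.
#' @return A `flank_config` list.
#' @export
flank_config <- function(flank_len = 300L, min_identity = 0.90,
                         min_coverage = 0.85, max_hits = 1L,
                         seed_len = 16L, max_flank_n_frac = 0.10) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_coverage > 0, min_coverage <= 1,
            flank_len >= seed_len, seed_len >= 8L)
  structure(list(flank_len = as.integer(flank_len),
                 min_identity = min_identity, min_coverage = min_coverage,
                 max_hits = as.integer(max_hits), seed_len = as.integer(seed_len),
                 max_flank_n_frac = max_flank_n_frac),
            class = c("flank_config", "ssrmine_config"))
}

#' Primer-design box constraints
#'
#' The Primer3-style constraint box used for SSR marker design: primer
#' length 18–27 nt (optimum 20), GC content 20–80%, melting temperature
#' 57–63 degrees C (optimum 60) under a nearest-neighbor model, product size
#' 30–500 bp spanning the full repeat tract.
#'
#' @param len_min,len_opt,len_max Primer length bounds and optimum (nt).
#' @param gc_min,gc_max GC content bounds (%).
#' @param tm_min,tm_opt,tm_max Melting-temperature bounds and optimum (C).
#' @param product_min,product_max Amplicon size bounds (bp).
#' @param max_poly_x Longest allowed single-base run inside a primer.
#' @param mv_conc Monovalent cation concentration for the Tm model (mM).
#' @param oligo_conc Total oligo concentration for the Tm model (nM).
#' @param tm_penalty_weight Penalty units per degree C of Tm deviation.
#' @return A `primer_config` list.
#' @export
primer_config <- function(len_min = 18L, len_opt = 20L, len_max = 27L,
                          gc_min = 20, gc_max = 80,
                          tm_min = 57, tm_opt = 60, tm_max = 63,
                          product_min = 30L, product_max = 500L,
                          max_poly_x = 5L, mv_conc = 50, oligo_conc = 50,
                          tm_penalty_weight = 1) {
  stopifnot(len_min <= len_opt, len_opt <= len_max,
            tm_min <= tm_opt, tm_opt <= tm_max,
            product_min < product_max)
  structure(list(len_min = as.integer(len_min), len_opt = as.integer(len_opt),
                 len_max = as.integer(len_max),
                 gc_min = gc_min, gc_max = gc_max,
                 tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
                 product_min = as.integer(product_min),
                 product_max = as.integer(product_max),
                 max_poly_x = as.integer(max_poly_x),
                 mv_conc = mv_conc, oligo_conc = oligo_conc,
                 tm_penalty_weight = tm_penalty_weight),
            class = c("primer_config", "ssrmine_config"))
}

#' Electronic-PCR settings
#'
#' Defaults follow the classic e-PCR parameterisation for SSR marker
#' verification: seed word size 9 with one discontiguous (wildcard)
#' position, at most 1 mismatch and 1 indel in the remaining 5' portion of
#' each primer, and a product-size deviation window of 100 bp around the
#' expected amplicon.
#'
#' @param word_size Length of the 3'-terminal seed word (nt).
#' @param discontig_words Number of wildcard positions allowed inside the
#'   seed word (the 3'-terminal base itself must always match).
#' @param size_deviation Allowed deviation from the expected product size (bp).
#' @param max_mismatches Mismatch budget for the 5' portion of a primer.
#' @param max_indels Indel budget for the 5' portion of a primer.
#' @param max_product Largest product length considered when pairing sites (bp).
#' @return An `epcr_config` list.
#' @export
epcr_config <- function(word_size = 9L, discontig_words = 1L,
                        size_deviation = 100L, max_mismatches = 1L,
                        max_indels = 1L, max_product = 5000L) {
  stopifnot(word_size >= 4L, discontig_words >= 0L, size_deviation >= 0L,
            max_mismatches >= 0L, max_indels >= 0L, max_product > 0L)
  structure(list(word_size = as.integer(word_size),
                 discontig_words = as.integer(discontig_words),
                 size_deviation = as.integer(size_deviation),
                 max_mismatches = as.integer(max_mismatches),
                 max_indels = as.integer(max_indels),
                 max_product = as.integer(max_product)),
            class = c("epcr_config", "ssrmine_config"))
}

#' Cross-genome locus merging settings
#'
#' @param window Tracts from different genomes whose start positions lie
#'   within this distance (bp) are merged into one panel locus.
#' @param require_same_motif Merge only tracts sharing the canonical motif
#'   group (reverse complement and cyclic rotation collapsed).
#' @return A `merge_config` list.
#' @export
merge_config <- function(window = 5000L, require_same_motif = TRUE) {
  stopifnot(window > 0)
  structure(list(window = as.integer(window),
                 require_same_motif = isTRUE(require_same_motif)),
            class = c("merge_config", "ssrmine_config"))
}

#' Genomic-region classification settings
#'
#' @param promoter_len Promoter length upstream of the transcription
#'   initiation site (bp), strand aware.
#' @param precedence Order in which overlapping region labels win; must be a
#'   permutation of the six labels.
#' @return A `region_config` list.
#' @export
region_config <- function(promoter_len = 2000L,
                          precedence = c("CDS", "five_prime_UTR",
                                         "three_prime_UTR", "intron",
                                         "promoter", "intergenic")) {
  labels <- c("CDS", "five_prime_UTR", "three_prime_UTR", "intron",
              "promoter", "intergenic")
  if (!setequal(precedence, labels) || length(precedence) != 6L)
    stop("precedence must be a permutation of the six region labels")
  structure(list(promoter_len = as.integer(promoter_len),
                 precedence = precedence),
            class = c("region_config", "ssrmine_config"))
}

#' Density / marker-interval settings
#'
#' @param genome_size Genome size in bp used for marker-interval statistics.
#'   The default is the 2.1 Gb maize reference genome size.
#' @return A `density_config` list.
#' @export
density_config <- function(genome_size = 2.1e9) {
  stopifnot(genome_size > 0)
  structure(list(genome_size = genome_size),
            class = c("density_config", "ssrmine_config"))
}

#' Bundle all pipeline settings
#'
#' One object holding every threshold of the pipeline, serialisable to a
#' single YAML file so a complete parameterisation travels with results.
#'
#' @param detection,flank,primer,epcr,merge,region,density Sub-configs; see
#'   the individual constructors.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detection = detection_config(),
                            flank = flank_config(),
                            primer = primer_config(),
                            epcr = epcr_config(),
                            merge = merge_config(),
                            region = region_config(),
                            density = density_config()) {
  stopifnot(inherits(detection, "detection_config"),
            inherits(flank, "flank_config"),
            inherits(primer, "primer_config"),
            inherits(epcr, "epcr_config"),
            inherits(merge, "merge_config"),
            inherits(region, "region_config"),
            inherits(density, "density_config"))
  structure(list(detection = detection, flank = flank, primer = primer,
                 epcr = epcr, merge = merge, region = region,
                 density = density),
            class = c("pipeline_config", "ssrmine_config"))
}

#' Read / write a pipeline configuration file
#'
#' The file is flat YAML with one block per pipeline stage; unknown keys are
#' rejected so typos never silently fall back to defaults.
#'
#' @param path File path.
#' @param config A `pipeline_config` object.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  constructors <- list(detection = detection_config, flank = flank_config,
                       primer = primer_config, epcr = epcr_config,
                       merge = merge_config, region = region_config,
                       density = density_config)
  unknown <- setdiff(names(raw), names(constructors))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "))
  parts <- lapply(names(constructors), function(nm) {
    args <- raw[[nm]] %||% list()
    if (nm == "detection" && !is.null(args$min_repeats))
      args$min_repeats <- unlist(args$min_repeats)
    bad <- setdiff(names(args), names(formals(constructors[[nm]])))
    if (length(bad))
      stop("unknown key(s) in [", nm, "]: ", paste(bad, collapse = ", "))
    do.call(constructors[[nm]], args)
  })
  names(parts) <- names(constructors)
  do.call(pipeline_config, parts)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  as_plain <- function(x) {
    x <- unclass(x)
    if (!is.null(x$min_repeats)) x$min_repeats <- as.list(x$min_repeats)
    x
  }
  yaml::write_yaml(lapply(unclass(config), as_plain), path)
  invisible(path)
}

#' @export
print.ssrmine_config <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}
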