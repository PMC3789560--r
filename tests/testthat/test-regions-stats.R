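# two genes on one 30 kb contig: a "+" gene and a "-" gene whose promoter
# overlaps the first gene's CDS
demo_features <- function() {
  tibble::tibble(
    seq_id = "chr1", source = "t",
    type = c("gene", "mRNA", "exon", "exon", "five_prime_UTR", "CDS", "CDS",
             "three_prime_UTR",
             "gene", "mRNA", "exon", "CDS"),
    start = c(5001, 5001, 5001, 6001, 5001, 5151, 6001, 6501,
              8001, 8001, 8001, 8001),
    end = c(7000, 7000, 5800, 7000, 5150, 5800, 6500, 7000,
            9000, 9000, 9000, 9000),
    strand = c(rep("+", 8), rep("-", 4)),
    id = c("g1", "m1", NA, NA, NA, NA, NA, NA, "g2", "m2", NA, NA),
    parent = c(NA, "g1", "m1", "m1", "m1", "m1", "m1", "m1",
               NA, "g2", "m2", "m2"))
}

test_that("the region model partitions every base exactly once", {
  lens <- c(chr1 = 30000L)
  model <- build_region_model(demo_features(), lens)
  expect_equal(sum(model$end - model$start), 30000L)
  # disjoint: sorted intervals never overlap
  expect_true(all(model$start[-1] >= model$end[-nrow(model)]))
  expect_setequal(unique(model$region),
                  c("CDS", "five_prime_UTR", "three_prime_UTR", "intron",
                    "promoter", "intergenic"))
})

test_that("promoters are 2 kb upstream of the TSS, strand aware", {
  model <- build_region_model(demo_features(), c(chr1 = 30000L))
  at <- function(pos0) model$region[model$start <= pos0 & model$end > pos0]
  expect_equal(at(3500), "promoter")        # 1.5 kb upstream of + gene
  expect_equal(at(2999), "intergenic")      # beyond the 2 kb promoter
  expect_equal(at(9500), "promoter")        # downstream of the "-" gene end
  expect_equal(at(11100), "intergenic")
})

test_that("precedence resolves overlaps: CDS beats a promoter", {
  # the "-" gene's promoter [9000, 11000) does not reach g1, so shift g2:
  feats <- demo_features()
  feats$start[feats$id %in% c("g2", "m2") | feats$parent == "m2"] <- 6601
  feats$start[is.na(feats$parent)][2] <- 6601   # gene row
  feats <- feats[1:12, ]
  feats$start[9:12] <- 6601; feats$end[9:12] <- 7600
  model <- build_region_model(feats, c(chr1 = 30000L))
  at <- function(pos0) model$region[model$start <= pos0 & model$end > pos0]
  # base 6200 lies in g1's CDS [6000,6500) and in g2's promoter: CDS wins
  expect_equal(at(6200), "CDS")
})

test_that("intron is gene span minus exons", {
  model <- build_region_model(demo_features(), c(chr1 = 30000L))
  intron <- model[model$region == "intron", ]
  expect_equal(intron$start, 5800)
  expect_equal(intron$end, 6000)
})

test_that("tracts are assigned by their start base", {
  model <- build_region_model(demo_features(), c(chr1 = 30000L))
  tr <- tibble::tibble(seq_id = "chr1",
                       start = c(5900L, 6490L, 20000L),
                       end = c(5920L, 6520L, 20020L),
                       tract_seq = c(strrep("AT", 10), strrep("AG", 15),
                                     strrep("C", 20)))
  got <- assign_regions(tr, model)
  # 6490 starts in CDS though the tract straddles into the 3' UTR
  expect_equal(got$region, c("intron", "CDS", "intergenic"))
})

test_that("region summary conserves counts across the partition", {
  sim <- sim_small()
  g1 <- sim$genomes$G01
  model <- build_region_model(sim$features, genome_lengths(g1))
  tr <- assign_regions(find_ssrs(g1), model)
  expect_equal(sum(tapply(rep(1, nrow(tr)), tr$region, sum)), nrow(tr))
  smry <- region_summary(tr, model)
  expect_equal(smry$n[smry$region == "Total"], nrow(tr))
  expect_equal(sum(smry$n[smry$region != "Total"]), nrow(tr))
})

test_that("marker intervals reproduce genome-size arithmetic", {
  expect_equal(round_half_up(interval_stats(135693), 2), 15.48)
  expect_equal(round_half_up(interval_stats(264658), 2), 7.93)
  expect_equal(round_half_up(interval_stats(1000,
    density_config(genome_size = 1e6)), 2), 1.00)
  expect_error(interval_stats(0), "positive")
  counts <- c(1000, 2000, 4000, 8000)
  expect_true(all(diff(interval_stats(counts)) < 0))
})

test_that("PIC follows the closed form with guards", {
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.5, 0.5)), 0.5)
  expect_equal(pic(rep(0.25, 4)), 0.75)
  expect_error(pic(c(0.5, 0.4)), "sum to 1")
  expect_error(pic(c(1.2, -0.2)), "non-negative")
  # bounds: 0 <= pic <= 1 - 1/k
  set.seed(71)
  for (k in 2:6) {
    p <- stats::runif(k); p <- p / sum(p)
    v <- pic(p)
    expect_gte(v, 0)
    expect_lte(v, 1 - 1 / k + 1e-12)
  }
})

test_that("allele frequencies and panel PIC work on merged loci", {
  expect_equal(unname(allele_freqs(c(180, 180, 184, NA))),
               c(2 / 3, 1 / 3))
  tr <- dplyr::bind_rows(
    tibble::tibble(genome_id = c("g1", "g2", "g3", "g4"), seq_id = "chr1",
                   start = c(100L, 110L, 100L, 105L),
                   end = c(120L, 130L, 120L, 129L), motif = "AG",
                   motif_len = 2L, repeat_count = c(10L, 10L, 10L, 12L)))
  loci <- panel_pic(merge_panel(tr))
  expect_equal(loci$pic, 1 - (0.75^2 + 0.25^2))
})

test_that("funnel report reproduces stage ratios and class shares", {
  mk_stage <- function(n_by_class) {
    tibble::tibble(motif_class = rep(names(n_by_class), n_by_class))
  }
  stages <- list(
    all = mk_stage(c(`A/T` = 60, `AG/CT` = 40)),
    unique_flanks = mk_stage(c(`A/T` = 45, `AG/CT` = 35)),
    primers = mk_stage(c(`A/T` = 30, `AG/CT` = 30)),
    epcr_unique = mk_stage(c(`A/T` = 25, `AG/CT` = 25)),
    polymorphic = mk_stage(c(`A/T` = 10, `AG/CT` = 10)))
  rep_tbl <- funnel_report(stages)
  tot <- rep_tbl[rep_tbl$motif_class == "Total", ]
  expect_equal(tot$n, c(100L, 80L, 60L, 50L, 20L))
  expect_equal(tot$pct_of_parent, c(100, 80, 75, round_half_up(100 * 50 / 60, 2), 40))
  shares <- rep_tbl[rep_tbl$stage == "all" & rep_tbl$motif_class != "Total", ]
  expect_equal(sum(shares$pct_of_stage), 100, tolerance = 0.0005)
  # printed-ratio identity: 9240 of 25437 is 36.33%
  expect_equal(pct_of(9240, 25437), 36.33)
})
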