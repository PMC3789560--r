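mk_tract <- function(genome_id, seq_id, start, motif, count) {
  tibble::tibble(genome_id = genome_id, seq_id = seq_id, start = start,
                 end = start + nchar(motif) * count, motif = motif,
                 motif_len = nchar(motif), repeat_count = count)
}

test_that("tracts within the merge window fuse into one panel locus", {
  tr <- dplyr::bind_rows(mk_tract("g1", "chr1", 10000, "AG", 10),
                         mk_tract("g2", "chr1", 12500, "AG", 12))
  loci <- merge_panel(tr)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$n_present, 2L)
  expect_equal(loci$ref_start, 10000)
  expect_equal(loci$ref_end, 12500 + 24)

  tr2 <- dplyr::bind_rows(mk_tract("g1", "chr1", 10000, "AG", 10),
                          mk_tract("g2", "chr1", 16001, "AG", 12))
  expect_equal(nrow(merge_panel(tr2)), 2)
})

test_that("strand-flipped motif calls merge through the canonical group", {
  tr <- dplyr::bind_rows(mk_tract("g1", "chr1", 10000, "AG", 10),
                         mk_tract("g2", "chr1", 10100, "CT", 10))
  loci <- merge_panel(tr)
  expect_equal(nrow(loci), 1)
  expect_equal(loci$motif_group, "AG")
})

test_that("different motif groups never merge", {
  tr <- dplyr::bind_rows(mk_tract("g1", "chr1", 10000, "AG", 10),
                         mk_tract("g2", "chr1", 10100, "GA", 10),
                         mk_tract("g2", "chr1", 10400, "AAC", 8))
  # GA is a rotation of AG: same canonical group; AAC is not
  loci <- merge_panel(tr)
  expect_equal(nrow(loci), 2)
})

test_that("surplus same-genome tracts found a new locus", {
  tr <- dplyr::bind_rows(mk_tract("g1", "chr1", 10000, "AG", 10),
                         mk_tract("g1", "chr1", 11000, "AG", 11),
                         mk_tract("g2", "chr1", 10020, "AG", 10))
  loci <- merge_panel(tr)
  expect_equal(nrow(loci), 2)
  expect_equal(sum(vapply(loci$alleles, nrow, integer(1))), 3L)
})

test_that("polymorphism classes follow the presence/length rules", {
  expect_equal(classify_polymorphism(c(20, 20, 20), 3), "monomorphic")
  expect_equal(classify_polymorphism(c(20, 22), 2), "length_polymorphic")
  expect_equal(classify_polymorphism(c(20, 20), 3), "presence_absence")
  expect_equal(classify_polymorphism(c(20, 22), 3), "both")
  expect_error(classify_polymorphism(numeric(0), 3))
})

test_that("common loci are exactly those present in every genome", {
  tr <- dplyr::bind_rows(mk_tract("g1", "chr1", 10000, "AG", 10),
                         mk_tract("g2", "chr1", 10050, "AG", 10),
                         mk_tract("g3", "chr1", 10100, "AG", 10),
                         mk_tract("g1", "chr1", 50000, "CAA", 8),
                         mk_tract("g2", "chr1", 50010, "CAA", 8))
  loci <- merge_panel(tr, panel = c("g1", "g2", "g3"))
  com <- common_loci(loci)
  expect_equal(nrow(com), 1)
  expect_equal(com$motif_group, "AG")
  expect_lte(nrow(com), nrow(loci))
})

test_that("merging is invariant to genome input order and conserves tracts", {
  sim <- sim_small()
  tracts <- dplyr::bind_rows(lapply(sim$genomes, find_ssrs))
  loci_a <- merge_panel(tracts, panel = names(sim$genomes))
  loci_b <- merge_panel(tracts[sample(nrow(tracts)), ],
                        panel = names(sim$genomes))
  expect_equal(loci_a$locus_id, loci_b$locus_id)
  expect_equal(loci_a$poly_class, loci_b$poly_class)
  expect_equal(sum(vapply(loci_a$alleles, nrow, integer(1))), nrow(tracts))
})

test_that("widening the merge window never increases the locus count", {
  sim <- sim_small()
  tracts <- dplyr::bind_rows(lapply(sim$genomes, find_ssrs))
  counts <- vapply(c(1000L, 5000L, 20000L), function(w)
    nrow(merge_panel(tracts, merge_config(window = w),
                     panel = names(sim$genomes))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("planted polymorphism classes are recovered exactly", {
  sim <- sim_small()
  tracts <- dplyr::bind_rows(lapply(sim$genomes, find_ssrs))
  loci <- merge_panel(tracts, panel = names(sim$genomes))
  m <- match_truth_to_panel(sim$loci, loci)
  expect_false(anyNA(m))
  expect_equal(loci$poly_class[m], sim$loci$expected_poly_class)
  expect_equal(loci$n_present[m], as.integer(sim$loci$n_present))
})

test_that("allele table spreads per-genome lengths with absences", {
  tr <- dplyr::bind_rows(mk_tract("g1", "chr1", 10000, "AG", 10),
                         mk_tract("g2", "chr1", 10050, "AG", 12),
                         mk_tract("g1", "chr1", 50000, "CAA", 8))
  loci <- merge_panel(tr, panel = c("g1", "g2"))
  wide <- allele_table(loci)
  expect_equal(names(wide), c("locus_id", "g1", "g2"))
  expect_equal(wide$g1, c(20L, 24L))
  expect_equal(wide$g2, c(24L, NA))
  tall <- tidy(loci)
  expect_equal(nrow(tall), 3)
})
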