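test_that("flanks are the 300 bp immediately adjacent to the tract", {
  set.seed(21)
  left <- ssrmine:::disrupt_repeats(random_seq(500))
  right <- ssrmine:::disrupt_repeats(random_seq(1500 - 24))
  s <- paste0(left, strrep("AG", 12), right)   # tract at [500, 524)
  g <- genome_seq(c(chr1 = s), "t")
  tr <- find_ssrs(g)
  tr <- tr[tr$start == 500, ]
  fl <- extract_flanks(tr, g)
  expect_equal(fl$left_flank, substr(s, 201, 500))
  expect_equal(fl$right_flank, substr(s, 525, 824))
})

test_that("loci too close to a contig end are dropped with a reason", {
  set.seed(22)
  s <- paste0(random_seq(100), strrep("C", 15),
              ssrmine:::disrupt_repeats(random_seq(600)))
  g <- genome_seq(c(chr1 = s), "t")
  tr <- find_ssrs(g)
  tr <- tr[tr$motif == "C", ]
  expect_message(fl <- extract_flanks(tr, g), "dropped")
  expect_equal(nrow(fl), 0)
  expect_match(attr(fl, "dropped")$reason, "contig end")
})

test_that("N-rich flanks are dropped", {
  set.seed(23)
  s <- paste0(strrep("N", 100), random_seq(250),
              strrep("C", 15), ssrmine:::disrupt_repeats(random_seq(400)))
  g <- genome_seq(c(chr1 = s), "t")
  tr <- find_ssrs(g)
  tr <- tr[tr$motif == "C", ]
  expect_message(fl <- extract_flanks(tr, g), "dropped")
  expect_equal(nrow(fl), 0)
  expect_match(attr(fl, "dropped")$reason, "N-rich")
})

test_that("a verbatim duplicate flips a locus to non-unique, hit count 2", {
  pg <- planted_genome("AG", 10, left = 600, right = 600, seed = 31)
  g <- pg$genome
  left_flank <- substr(g$seq[["chr1"]], pg$tract_start - 299,
                       pg$tract_start)
  g2 <- genome_seq(c(chr1 = g$seq[["chr1"]],
                     chr2 = paste0(random_seq(200), left_flank,
                                   random_seq(200))), "t")
  tr <- find_ssrs(g2)
  tr <- tr[tr$seq_id == "chr1" & tr$start == pg$tract_start, ]
  fl <- screen_uniqueness(extract_flanks(tr, g2), g2)
  expect_false(fl$unique)
  expect_equal(fl$left_hits, 2L)
  expect_equal(fl$right_hits, 1L)
})

test_that("a degenerate copy at 85% identity does not count as a hit", {
  pg <- planted_genome("AG", 10, left = 600, right = 600, seed = 32)
  g <- pg$genome
  left_flank <- substr(g$seq[["chr1"]], pg$tract_start - 299, pg$tract_start)
  # mutate every 7th base (~14% divergence, identity ~0.857) but keep the
  # first 40 bp intact so seeding still finds the copy
  ch <- strsplit(left_flank, "")[[1]]
  for (p in seq(45, 300, by = 7))
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  degen <- paste(ch, collapse = "")
  ident <- mean(strsplit(left_flank, "")[[1]] == ch)
  expect_lt(ident, 0.90)
  g2 <- genome_seq(c(chr1 = g$seq[["chr1"]],
                     chr2 = paste0(random_seq(150), degen,
                                   random_seq(150))), "t")
  tr <- find_ssrs(g2)
  tr <- tr[tr$seq_id == "chr1" & tr$start == pg$tract_start, ]
  fl <- screen_uniqueness(extract_flanks(tr, g2), g2)
  expect_true(fl$unique)
  expect_equal(fl$left_hits, 1L)
})

test_that("reverse-strand copies count toward the hit tally", {
  pg <- planted_genome("CTA", 8, left = 600, right = 600, seed = 33)
  g <- pg$genome
  right_flank <- substr(g$seq[["chr1"]], pg$tract_end + 1,
                        pg$tract_end + 300)
  g2 <- genome_seq(c(chr1 = g$seq[["chr1"]],
                     chr2 = paste0(random_seq(100), revcomp(right_flank),
                                   random_seq(100))), "t")
  tr <- find_ssrs(g2)
  tr <- tr[tr$seq_id == "chr1" & tr$start == pg$tract_start, ]
  fl <- screen_uniqueness(extract_flanks(tr, g2), g2)
  expect_false(fl$unique)
  expect_equal(fl$right_hits, 2L)
})

test_that("every extracted flank finds its self-hit", {
  sim <- sim_small()
  g <- sim$genomes$G02
  fl <- screen_uniqueness(extract_flanks(find_ssrs(g), g), g)
  expect_true(all(fl$left_hits >= 1L))
  expect_true(all(fl$right_hits >= 1L))
})

test_that("raising min_identity never decreases the unique-locus count", {
  sim <- sim_small()
  g <- sim$genomes$G01
  fl <- extract_flanks(find_ssrs(g), g)
  n_unique <- vapply(c(0.80, 0.90, 0.97), function(mi)
    sum(screen_uniqueness(fl, g, flank_config(min_identity = mi))$unique),
    numeric(1))
  expect_true(all(diff(n_unique) >= 0))
})

test_that("simulated duplications and only they fail the screen", {
  sim <- sim_small()
  g <- sim$genomes$G01
  fl <- screen_uniqueness(extract_flanks(find_ssrs(g), g), g)
  m <- match(paste(fl$seq_id, fl$start),
             paste(sim$loci$seq_id, sim$loci$ref_start))
  planted <- !is.na(m)
  expect_equal(fl$unique[planted], sim$loci$expected_unique[m[planted]])
})

test_that("precomputed tabular alignments drive the same filtering logic", {
  pg <- planted_genome("AG", 10, left = 600, right = 600, seed = 34)
  g <- pg$genome
  tr <- find_ssrs(g)
  tr <- tr[tr$start == pg$tract_start, ]
  fl <- extract_flanks(tr, g)
  mk_hit <- function(side, sstart, send, pident, length) data.frame(
    qseqid = paste0(fl$locus_id, "|", side), sseqid = "chr1",
    pident = pident, length = length, mismatch = 0, gapopen = 0,
    qstart = 1, qend = 300, sstart = sstart, send = send,
    evalue = 0, bitscore = 500)
  self_l <- mk_hit("left", pg$tract_start - 299, pg$tract_start, 100, 300)
  self_r <- mk_hit("right", pg$tract_end + 1, pg$tract_end + 300, 100, 300)
  far <- mk_hit("left", 10, 309, 95, 300)          # second strong hit
  weak <- mk_hit("left", 10, 309, 85, 300)         # below identity cutoff
  short <- mk_hit("left", 10, 230, 99, 220)        # below coverage cutoff
  out1 <- screen_uniqueness(fl, g, hits = rbind(self_l, self_r, far))
  expect_false(out1$unique)
  out2 <- screen_uniqueness(fl, g, hits = rbind(self_l, self_r, weak, short))
  expect_true(out2$unique)
})
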