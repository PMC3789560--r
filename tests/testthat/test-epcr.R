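# substitute a base at 1-based position p of a string
sub_base <- function(s, p) {
  old <- substr(s, p, p)
  substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  s
}

test_that("a verbatim primer is found with zero mismatches and indels", {
  set.seed(51)
  primer <- "GATTCGACCTGGCAATGCGT"
  s <- paste0(random_seq(300), primer, random_seq(300))
  g <- genome_seq(c(chr1 = s), "t")
  sites <- find_binding_sites(primer, g)
  hit <- sites[sites$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(c(hit$start, hit$end), c(300L, 320L))
  expect_equal(c(hit$mismatches, hit$indels), c(0L, 0L))
})

test_that("the 5' mismatch budget is enforced", {
  set.seed(52)
  primer <- "GATTCGACCTGGCAATGCGT"
  place <- function(copy) genome_seq(
    c(chr1 = paste0(random_seq(250), copy, random_seq(250))), "t")
  one_mm <- sub_base(primer, 4)              # 5' region (outside the word)
  two_mm <- sub_base(sub_base(primer, 4), 8)
  expect_equal(nrow(find_binding_sites(one_mm, place(primer))), 1)
  expect_equal(nrow(find_binding_sites(two_mm, place(primer))), 0)
})

test_that("the 3'-terminal base of the seed word must match exactly", {
  set.seed(53)
  primer <- "GATTCGACCTGGCAATGCGT"
  g_term <- genome_seq(
    c(chr1 = paste0(random_seq(250), sub_base(primer, 20), random_seq(250))),
    "t")
  g_word <- genome_seq(
    c(chr1 = paste0(random_seq(250), sub_base(primer, 15), random_seq(250))),
    "t")
  expect_equal(nrow(find_binding_sites(primer, g_term)), 0)  # terminal base
  expect_equal(nrow(find_binding_sites(primer, g_word)), 1)  # wildcard pos
})

test_that("a single indel in the 5' portion is tolerated, two are not", {
  set.seed(54)
  primer <- "GATTCGACCTGGCAATGCGT"
  with_del <- paste0(substr(primer, 1, 4), substr(primer, 6, 20))
  with_2del <- paste0(substr(primer, 1, 2), substr(primer, 4, 4),
                      substr(primer, 6, 20))
  place <- function(copy) genome_seq(
    c(chr1 = paste0(random_seq(250), copy, random_seq(250))), "t")
  s1 <- find_binding_sites(primer, place(with_del))
  expect_equal(nrow(s1), 1)
  expect_equal(s1$indels, 1L)
  expect_equal(nrow(find_binding_sites(primer, place(with_2del))), 0)
})

test_that("site search equals the full-scan oracle on small genomes", {
  set.seed(55)
  primer <- "CGATTGGCAGTCACGTTAGC"
  variants <- c(primer,
                sub_base(primer, 3),
                sub_base(primer, 13),              # wildcard inside word
                sub_base(primer, 20),              # terminal, must be missed
                paste0(substr(primer, 1, 6), substr(primer, 8, 20)),
                revcomp(primer),
                revcomp(sub_base(primer, 5)))
  s <- paste(c(random_seq(1500),
               unlist(lapply(variants, function(v) c(v, random_seq(700)))),
               random_seq(20000)), collapse = "")
  g <- genome_seq(c(chr1 = s, chr2 = random_seq(15000)), "t")
  for (p in c(primer, revcomp(primer), "ACGGATTTACGGCATTGCAA")) {
    got <- as.data.frame(find_binding_sites(p, g))
    want <- oracle_binding_sites(p, g)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = p)
  }
})

test_that("raising the mismatch budget never removes a site", {
  set.seed(56)
  primer <- "CGATTGGCAGTCACGTTAGC"
  s <- paste(c(random_seq(500), primer, random_seq(500),
               sub_base(primer, 2), random_seq(500),
               sub_base(sub_base(primer, 2), 6), random_seq(500)),
             collapse = "")
  g <- genome_seq(c(chr1 = s), "t")
  key <- function(d) paste(d$seq_id, d$start, d$strand)
  k0 <- key(find_binding_sites(primer, g, epcr_config(max_mismatches = 0)))
  k1 <- key(find_binding_sites(primer, g, epcr_config(max_mismatches = 1)))
  k2 <- key(find_binding_sites(primer, g, epcr_config(max_mismatches = 2)))
  expect_true(all(k0 %in% k1))
  expect_true(all(k1 %in% k2))
  expect_gt(length(k2), length(k1))
})

test_that("sites mirror under reverse complementation of the genome", {
  set.seed(57)
  primer <- "CGATTGGCAGTCACGTTAGC"
  s <- paste0(random_seq(400), primer, random_seq(300),
              revcomp(sub_base(primer, 4)), random_seq(400))
  g_fwd <- genome_seq(c(chr1 = s), "t")
  g_rev <- genome_seq(c(chr1 = revcomp(s)), "t")
  a <- find_binding_sites(primer, g_fwd)
  b <- find_binding_sites(primer, g_rev)
  n <- nchar(s)
  expect_equal(nrow(a), nrow(b))
  mirrored <- data.frame(start = n - b$end, end = n - b$start,
                         strand = ifelse(b$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(a$start, mirrored$start)
  expect_equal(a$end, mirrored$end)
  expect_equal(a$strand, mirrored$strand)
})

epcr_fixture <- function(n_copies = 1, seed = 58,
                         fwd = "GATTCGACCTGGCAATGCGT",
                         rev = "CCTGAAGCGTACGTTGGACA") {
  set.seed(seed)
  insert <- paste0(fwd, random_seq(160), revcomp(rev))  # 200 bp product
  s <- paste(c(random_seq(400),
               rep(c(insert, random_seq(9800)), n_copies),
               random_seq(400)), collapse = "")
  list(g = genome_seq(c(chr1 = s), "t"), fwd = fwd, rev = rev)
}

test_that("e-PCR classifies unique, duplicated and absent markers", {
  fx <- epcr_fixture(1)
  call <- epcr(fx$fwd, fx$rev, fx$g, expected_size = 200)
  expect_equal(call$status, "unique")
  expect_equal(call$amplicons$product_len, 200L)
  expect_true(call$amplicons$within_expected_size)

  fx2 <- epcr_fixture(2)
  call2 <- epcr(fx2$fwd, fx2$rev, fx2$g, expected_size = 200)
  expect_equal(call2$status, "multi_site")
  expect_equal(nrow(call2$amplicons), 2)

  set.seed(59)
  g0 <- genome_seq(c(chr1 = random_seq(5000)), "t")
  expect_equal(epcr(fx$fwd, fx$rev, g0, 200)$status, "no_site")
})

test_that("a single amplicon far outside the expected size is not unique", {
  fx <- epcr_fixture(1)
  call <- epcr(fx$fwd, fx$rev, fx$g, expected_size = 500,
               config = epcr_config(size_deviation = 100))
  expect_equal(call$status, "no_site")
  expect_equal(nrow(call$amplicons), 1)
  expect_false(call$amplicons$within_expected_size)
})

test_that("batch e-PCR summarises statuses and is order-independent", {
  fx <- epcr_fixture(1)
  fx2 <- epcr_fixture(2, seed = 60, fwd = "TCAGGCATCGAATGCCTGTC",
                      rev = "GTACCAGTTCGCAGGTCAAC")
  set.seed(61)
  pairs <- tibble::tibble(
    marker_id = c("m_unique", "m_multi", "m_absent"),
    fwd_seq = c(fx$fwd, fx2$fwd, "ACGGATTTACGGCATTGCAA"),
    rev_seq = c(fx$rev, fx2$rev, "TTGACCGGATACCGGTTACG"),
    expected_size = c(200, 200, 200))
  g <- genome_seq(c(chr1 = fx$g$seq[["chr1"]],
                    chr2 = fx2$g$seq[["chr1"]]), "t")
  calls <- epcr_batch(pairs, g)
  expect_equal(calls$status,
               c("unique", "multi_site", "no_site"))
  expect_equal(attr(calls, "summary"),
               list(unique = 1L, multi_site = 1L, no_site = 1L))
  shuffled <- epcr_batch(pairs[c(3, 1, 2), ], g)
  expect_equal(shuffled$status[order(shuffled$marker_id)],
               calls$status[order(calls$marker_id)])
})
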