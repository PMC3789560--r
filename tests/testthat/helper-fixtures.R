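# Shared fixture builders. Random sequences use local seeds so tests stay
# independent of execution order.

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a single-contig genome with one planted tract and clean surroundings
planted_genome <- function(motif, count, left = 400L, right = 400L,
                           seed = 11L, genome_id = "fix") {
  set.seed(seed)
  lg <- ssrmine:::guard_left(motif)
  rg <- ssrmine:::guard_right(motif)
  bgl <- ssrmine:::disrupt_repeats(random_seq(left))
  bgr <- ssrmine:::disrupt_repeats(random_seq(right))
  s <- paste0(bgl, lg, strrep(motif, count), rg, bgr)
  list(genome = genome_seq(c(chr1 = s), genome_id),
       tract_start = left + 6L,
       tract_end = left + 6L + nchar(motif) * count)
}

# memoised small simulated panel reused across test files
.sim_cache <- new.env(parent = emptyenv())
sim_small <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_panel(sim_config(
      seed = 42L, n_genomes = 3L, n_loci = 30L,
      contig_lengths = c(chr1 = 120000L, chr2 = 110000L)))
  }
  .sim_cache$sim
}

# match truth loci to merged panel loci by proximity on the same sequence
# and motif group (planted loci sit on a >5 kb grid, so matches are unique)
match_truth_to_panel <- function(truth_loci, panel) {
  vapply(seq_len(nrow(truth_loci)), function(i) {
    j <- which(panel$seq_id == truth_loci$seq_id[i] &
                 panel$motif_group == truth_loci$motif_group[i] &
                 abs(panel$ref_start - truth_loci$ref_start[i]) < 3000)
    if (length(j) == 1L) j else NA_integer_
  }, integer(1))
}
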