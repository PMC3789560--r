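#' Settings for the synthetic panel simulator
#'
#' Defines a multi-genome panel with planted SSR loci: a founder
#' (reference) genome carries one perfect tract per locus; every other
#' genome inherits the founder sequence and mutates it — repeat-count
#' changes under a symmetric stepwise (geometric-step) mutation model,
#' locus absence, and flank SNPs. One genome can be flagged low-coverage
#' (elevated absence rate), emulating a wild-relative sample whose reads map
#' poorly to the reference. A fraction of loci have their tract-plus-flanks
#' window copied onto a separate `chrDup` contig, making their flanks
#' non-unique.
#'
#' Loci are laid out on a fixed grid of `cell_width` bp cells, one locus per
#' cell, so planted tracts are far enough apart (> the 5 kb merge window)
#' that every planted locus maps to exactly one merged panel locus.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_genomes Panel size (founder included).
#' @param contig_lengths Lengths of the core contigs (bp).
#' @param n_loci Number of planted loci.
#' @param motif_length_mix Probabilities of motif lengths 1..6; defaults are
#'   the motif-length composition observed in genome-wide maize SSR surveys
#'   (~58% mono, ~25% di, ~10% tri, ~2% tetra, ~3% penta, ~2% hexa).
#' @param repeat_count_range List of `c(min, max)` founder repeat counts per
#'   motif length; minima default to the detection thresholds.
#' @param p_absent Probability a non-founder genome lacks a locus.
#' @param p_length_mut Probability a non-founder genome's repeat count
#'   differs from the founder's.
#' @param flank_snp_rate Per-base substitution rate in the 300 bp flanks of
#'   non-founder genomes.
#' @param duplication_rate Fraction of loci whose flanking window is copied
#'   elsewhere (expected flank-screen failure fraction).
#' @param lowcov_absent_mult Multiplier on `p_absent` for the last genome
#'   (the low-coverage panel member); set to 1 to disable.
#' @param gene_model_density Gene models per 10 kb in the synthetic GFF3.
#' @param cell_width Locus grid cell width (bp); must exceed the merge
#'   window plus the longest tract.
#' @param hard_mode Also plant, for each duplicated locus, a decoy flank
#'   copy at ~80% identity — below the 90% screen threshold — to stress the
#'   uniqueness screen without changing the expected outcome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genomes = 17L,
                       contig_lengths = c(chr1 = 750000L, chr2 = 700000L),
                       n_loci = 200L,
                       motif_length_mix = c(0.579, 0.246, 0.098, 0.025,
                                            0.033, 0.019),
                       repeat_count_range = list(c(10L, 25L), c(7L, 15L),
                                                 c(6L, 12L), c(5L, 10L),
                                                 c(4L, 8L), c(4L, 8L)),
                       p_absent = 0.05, p_length_mut = 0.3,
                       flank_snp_rate = 0.001, duplication_rate = 0.1,
                       lowcov_absent_mult = 4, gene_model_density = 1,
                       cell_width = 7000L, hard_mode = FALSE) {
  stopifnot(n_genomes >= 1L, n_loci >= 1L,
            length(motif_length_mix) == 6L,
            all(motif_length_mix >= 0), sum(motif_length_mix) > 0,
            all(c(p_absent, p_length_mut, flank_snp_rate,
                  duplication_rate) >= 0),
            all(c(p_absent, p_length_mut, flank_snp_rate,
                  duplication_rate) <= 1),
            cell_width >= 6000L)
  thresholds <- detection_config()$min_repeats
  for (m in 1:6) {
    if (repeat_count_range[[m]][1] < thresholds[[as.character(m)]])
      stop("repeat_count_range minimum for motif length ", m,
           " is below the detection threshold; planted loci must be",
           " detectable")
  }
  if (is.null(names(contig_lengths)))
    names(contig_lengths) <- paste0("chr", seq_along(contig_lengths))
  structure(list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
                 contig_lengths = contig_lengths, n_loci = as.integer(n_loci),
                 motif_length_mix = motif_length_mix / sum(motif_length_mix),
                 repeat_count_range = repeat_count_range,
                 p_absent = p_absent, p_length_mut = p_length_mut,
                 flank_snp_rate = flank_snp_rate,
                 duplication_rate = duplication_rate,
                 lowcov_absent_mult = lowcov_absent_mult,
                 gene_model_density = gene_model_density,
                 cell_width = as.integer(cell_width),
                 hard_mode = isTRUE(hard_mode)),
            class = c("sim_config", "ssrmine_config"))
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# break any tandem run close to a detection threshold by substituting its
# middle base; margin 1 below threshold absorbs single-base extensions at
# junctions
disrupt_repeats <- function(s, thresholds = detection_config()$min_repeats) {
  repeat {
    hit <- FALSE
    for (m in 1:6) {
      k <- thresholds[[as.character(m)]] - 1L
      pat <- sprintf("([ACGT]{%d})\\1{%d,}", m, k - 1L)
      g <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (g[1] == -1L) next
      hit <- TRUE
      for (i in seq_along(g)) {
        pos <- as.integer(g[i]) + attr(g, "match.length")[i] %/% 2L
        old <- substr(s, pos, pos)
        nb <- c(substr(s, pos - 1L, pos - 1L), substr(s, pos + 1L, pos + 1L))
        repl <- setdiff(BASES, c(old, nb))[1]
        substr(s, pos, pos) <- repl
      }
    }
    if (!hit) return(s)
  }
}

GUARD_STEM_L <- c(A = "TGCGC", C = "ATGAG", G = "TCATC", T = "GCACG")
GUARD_STEM_R <- c(A = "CGTGC", C = "ATGCG", G = "TACGC", T = "CAGCG")

# 6 bp guards flanking a planted tract: the left guard's last base differs
# from the motif's last base (no full-copy or phase-shifted extension to the
# left); the right guard's first base differs from the motif's first base
guard_left <- function(motif) {
  b <- setdiff(c("T", "G", "C", "A"),
               substr(motif, nchar(motif), nchar(motif)))[1]
  paste0(GUARD_STEM_L[[b]], b)
}
guard_right <- function(motif) {
  b <- setdiff(c("A", "C", "G", "T"), substr(motif, 1L, 1L))[1]
  paste0(b, GUARD_STEM_R[[b]])
}

random_motif <- function(m) {
  repeat {
    mm <- paste(sample(BASES, m, replace = TRUE), collapse = "")
    if (!has_smaller_period(mm)) return(mm)
  }
}

# scramble a tract into a same-length repeat-free spacer (absent allele)
neutral_spacer <- function(n) disrupt_repeats(random_dna(n))

mutate_snps <- function(s, rate) {
  n <- nchar(s)
  hits <- which(stats::runif(n) < rate)
  for (p in hits) {
    old <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(BASES, old), 1L)
  }
  s
}

# mutate a string to approximately the given identity (decoy planting)
degrade_identity <- function(s, identity) {
  mutate_snps(s, 1 - identity)
}

#' Simulate a multi-genome SSR panel with known truth
#'
#' Generates a founder genome with planted perfect SSR tracts on a fixed
#' locus grid (i.i.d. uniform background, spontaneous near-threshold repeats
#' disrupted, 6 bp non-extending guards around each tract), then derives the
#' other panel genomes by stepwise repeat-count mutation, locus dropout and
#' flank SNPs. Loci selected for duplication have their tract-plus-flanks
#' window copied onto an extra `chrDup` contig present in every genome.
#' Genome 1 is the founder/reference and is never mutated; gene models are
#' annotated on its coordinates.
#'
#' @param config A [sim_config()].
#' @return An `ssr_panel_sim` list: `genomes` (named list of [genome_seq()]),
#'   `features` (synthetic GFF3 feature tibble, 1-based), `truth` (tall
#'   tibble: `locus_id, genome_id, seq_id, start, end, motif, repeat_count,
#'   present`), `loci` (per-locus summary with `duplicated`,
#'   `expected_unique`, `expected_poly_class`, `n_present`), and `config`.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(config$seed)

  cw <- config$cell_width
  edge <- 500L
  tract_off <- 3000L                      # tract offset inside its cell
  contigs <- names(config$contig_lengths)
  n_cells <- floor((config$contig_lengths - 2L * edge) / cw)
  if (sum(n_cells) < config$n_loci)
    stop("loci cannot be placed: grid capacity ", sum(n_cells),
         " < n_loci ", config$n_loci)

  # locus plan: cell assignment, motif, founder repeat count, duplication
  cells <- data.frame(seq_id = rep(contigs, n_cells),
                      cell = unlist(lapply(n_cells, seq_len)))
  pick <- sort(sample(nrow(cells), config$n_loci))
  plan <- cells[pick, , drop = FALSE]
  plan$locus_id <- sprintf("L%03d", seq_len(config$n_loci))
  plan$motif_len <- sample(1:6, config$n_loci, replace = TRUE,
                           prob = config$motif_length_mix)
  plan$motif <- vapply(plan$motif_len, random_motif, character(1))
  plan$founder_count <- vapply(plan$motif_len, function(m) {
    r <- config$repeat_count_range[[m]]
    sample(r[1]:r[2], 1L)
  }, integer(1))
  plan$duplicated <- stats::runif(config$n_loci) < config$duplication_rate

  # per-genome allele table (repeat counts; NA = absent)
  genome_ids <- sprintf("G%02d", seq_len(config$n_genomes))
  thresholds <- detection_config()$min_repeats
  alleles <- matrix(rep(plan$founder_count, config$n_genomes),
                    nrow = config$n_loci)
  present <- matrix(TRUE, config$n_loci, config$n_genomes)
  for (g in seq_len(config$n_genomes)[-1]) {
    p_abs <- config$p_absent *
      if (g == config$n_genomes) config$lowcov_absent_mult else 1
    for (i in seq_len(config$n_loci)) {
      if (stats::runif(1) < p_abs) {
        present[i, g] <- FALSE
        next
      }
      if (stats::runif(1) < config$p_length_mut) {
        step <- (stats::rgeom(1, 0.5) + 1L) * sample(c(-1L, 1L), 1L)
        newc <- max(plan$founder_count[i] + step,
                    thresholds[[as.character(plan$motif_len[i])]])
        alleles[i, g] <- newc
      }
    }
  }

  # founder background per contig (tracts spliced in per genome)
  bg <- lapply(contigs, function(sid)
    disrupt_repeats(random_dna(config$contig_lengths[[sid]])))
  names(bg) <- contigs

  # per-genome flank SNPs: realised once per locus x genome on the founder
  # flank windows so the same mutated flank is used consistently
  left_windows <- right_windows <- vector("list", config$n_loci)
  flank_w <- 300L
  for (i in seq_len(config$n_loci)) {
    sid <- plan$seq_id[i]
    cell_start <- edge + (plan$cell[i] - 1L) * cw
    t0 <- cell_start + tract_off              # guardL start (0-based)
    lw0 <- t0 - flank_w + 6L                  # flank includes the guard
    left_bg <- substr(bg[[sid]], lw0 + 1L, t0)
    right_bg <- substr(bg[[sid]], t0 + 1L, t0 + flank_w - 6L)
    left_windows[[i]] <- vapply(seq_len(config$n_genomes), function(g)
      if (g == 1L) left_bg else mutate_snps(left_bg, config$flank_snp_rate),
      character(1))
    right_windows[[i]] <- vapply(seq_len(config$n_genomes), function(g)
      if (g == 1L) right_bg else mutate_snps(right_bg, config$flank_snp_rate),
      character(1))
  }

  # assemble genomes
  genomes <- vector("list", config$n_genomes)
  truth_rows <- vector("list", config$n_genomes)
  spacers <- lapply(seq_len(config$n_loci), function(i)
    if (any(!present[i, ])) neutral_spacer(
      plan$founder_count[i] * plan$motif_len[i]) else NA_character_)
  for (g in seq_len(config$n_genomes)) {
    seqs <- character(length(contigs))
    names(seqs) <- contigs
    t_start <- t_end <- integer(config$n_loci)
    for (sid in contigs) {
      s <- bg[[sid]]
      ids <- which(plan$seq_id == sid)
      # splice loci right-to-left so earlier coordinates stay valid while
      # editing, then recompute per-genome positions left-to-right
      shift <- 0L
      parts <- character(0)
      prev_end <- 0L
      for (i in ids) {
        cell_start <- edge + (plan$cell[i] - 1L) * cw
        t0 <- cell_start + tract_off
        gl <- guard_left(plan$motif[i]); gr <- guard_right(plan$motif[i])
        insert <- if (present[i, g])
          strrep(plan$motif[i], alleles[i, g]) else spacers[[i]]
        lw0 <- t0 - flank_w + 6L
        parts <- c(parts, substr(s, prev_end + 1L, lw0),
                   left_windows[[i]][g], gl, insert, gr,
                   right_windows[[i]][g])
        # start of the tract in this genome's coordinates
        t_start[i] <- lw0 + (flank_w - 6L) + 6L + shift
        t_end[i] <- t_start[i] + nchar(insert)
        shift <- shift + nchar(insert) -
          plan$founder_count[i] * plan$motif_len[i]
        prev_end <- t0 + 6L + plan$founder_count[i] * plan$motif_len[i] +
          6L + (flank_w - 6L)
      }
      parts <- c(parts, substr(s, prev_end + 1L, nchar(s)))
      seqs[[sid]] <- paste(parts, collapse = "")
    }
    genomes[[g]] <- genome_seq(seqs, genome_id = genome_ids[g])
    truth_rows[[g]] <- tibble::tibble(
      locus_id = plan$locus_id, genome_id = genome_ids[g],
      seq_id = plan$seq_id, start = t_start, end = t_end,
      motif = plan$motif, repeat_count = alleles[, g],
      present = present[, g])
  }

  # duplication contig: founder windows (tract +/- flank) with spacers
  dup_ids <- which(plan$duplicated)
  if (length(dup_ids)) {
    dup_parts <- character(0)
    for (i in dup_ids) {
      gl <- guard_left(plan$motif[i]); gr <- guard_right(plan$motif[i])
      win <- paste0(left_windows[[i]][1], gl,
                    strrep(plan$motif[i], plan$founder_count[i]), gr,
                    right_windows[[i]][1])
      dup_parts <- c(dup_parts, neutral_spacer(400L), win)
      if (config$hard_mode)
        dup_parts <- c(dup_parts, neutral_spacer(400L),
                       degrade_identity(win, 0.80))
    }
    dup_contig <- paste(c(dup_parts, neutral_spacer(400L)), collapse = "")
    for (g in seq_len(config$n_genomes))
      genomes[[g]]$seq <- c(genomes[[g]]$seq, chrDup = dup_contig)
  }

  truth <- dplyr::bind_rows(truth_rows)
  loci <- tibble::tibble(
    locus_id = plan$locus_id, seq_id = plan$seq_id,
    ref_start = truth$start[truth$genome_id == genome_ids[1]],
    motif = plan$motif, motif_len = plan$motif_len,
    motif_class = classify_motif(plan$motif),
    motif_group = canonical_motif(plan$motif),
    founder_count = plan$founder_count,
    duplicated = plan$duplicated,
    expected_unique = !plan$duplicated,
    n_present = rowSums(present),
    expected_poly_class = vapply(seq_len(config$n_loci), function(i)
      classify_polymorphism((alleles[i, ] * plan$motif_len[i])[present[i, ]],
                            config$n_genomes), character(1)))

  features <- simulate_gene_models(config)
  structure(list(genomes = stats::setNames(genomes, genome_ids),
                 features = features, truth = truth, loci = loci,
                 config = config),
            class = "ssr_panel_sim")
}

# regular synthetic gene models on founder coordinates (two-exon genes,
# alternating strand), 1-based GFF3 convention
simulate_gene_models <- function(config) {
  spacing <- max(2000L, as.integer(round(10000 / config$gene_model_density)))
  rows <- list()
  for (sid in names(config$contig_lengths)) {
    len <- config$contig_lengths[[sid]]
    starts0 <- seq(2500L, len - 2000L - 1600L, by = spacing)
    for (j in seq_along(starts0)) {
      s <- starts0[j]
      strand <- if (j %% 2L == 1L) "+" else "-"
      gid <- sprintf("%s_gene%03d", sid, j)
      mid <- paste0(gid, ".1")
      # 0-based component layout on the + strand; mirrored labels on "-"
      seg <- list(gene = c(0L, 1600L), mRNA = c(0L, 1600L),
                  exon1 = c(0L, 400L), exon2 = c(900L, 1600L),
                  utr_a = c(0L, 150L), cds1 = c(150L, 400L),
                  cds2 = c(900L, 1400L), utr_b = c(1400L, 1600L))
      lab_a <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
      lab_b <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
      add <- function(type, range, id = NA_character_, parent = NA_character_)
        tibble::tibble(seq_id = sid, source = "ssrmine_sim", type = type,
                       start = s + range[1] + 1L, end = s + range[2],
                       strand = strand, id = id, parent = parent)
      rows[[length(rows) + 1L]] <- dplyr::bind_rows(
        add("gene", seg$gene, id = gid),
        add("mRNA", seg$mRNA, id = mid, parent = gid),
        add("exon", seg$exon1, parent = mid),
        add("exon", seg$exon2, parent = mid),
        add(lab_a, seg$utr_a, parent = mid),
        add("CDS", seg$cds1, parent = mid),
        add("CDS", seg$cds2, parent = mid),
        add(lab_b, seg$utr_b, parent = mid))
    }
  }
  dplyr::bind_rows(rows)
}

#' @export
print.ssr_panel_sim <- function(x, ...) {
  cat("<ssr_panel_sim> ", length(x$genomes), " genomes, ",
      nrow(x$loci), " planted loci, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated panel to disk
#'
#' Emits one FASTA per genome, the shared gene annotation as GFF3, and the
#' truth tables as TSV.
#'
#' @param sim An `ssr_panel_sim` from [simulate_panel()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_panel <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes)
    write_genome_fasta(g, file.path(dir, paste0(g$genome_id, ".fa")))
  write_gff3(sim$features, file.path(dir, "genes.gff3"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(sim$loci, file.path(dir, "truth_loci.tsv"))
  invisible(dir)
}
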