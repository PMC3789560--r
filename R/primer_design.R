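# Unified nearest-neighbor thermodynamic parameters (SantaLucia unified set):
# dH kcal/mol, dS cal/(mol K) per stacked dinucleotide, plus terminal
# initiation terms for A/T and G/C ends.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
NN_INIT <- list(AT = c(dh = 2.3, ds = 4.1), GC = c(dh = 0.1, ds = -2.8))

#' Nearest-neighbor melting temperature
#'
#' Duplex melting temperature of a primer under the unified SantaLucia
#' nearest-neighbor model, with an entropic monovalent-salt correction
#' (`0.368 * (n-1) * ln[Na+]`) and the `C_T/4` concentration term for
#' non-self-complementary duplexes. Conditions default to 50 mM monovalent
#' cation and 50 nM total oligo.
#'
#' @param seq Character vector of DNA sequences (`A,C,G,T` only, length >= 8).
#' @param config A [primer_config()] supplying `mv_conc` (mM) and
#'   `oligo_conc` (nM).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @examples
#' melting_temp("ACTGGTCAGTCAATCGGACT")
#' @export
melting_temp <- function(seq, config = primer_config()) {
  if (any(grepl("[^ACGT]", seq)))
    stop("melting_temp requires sequences over A,C,G,T only")
  if (any(nchar(seq) < 8L))
    stop("melting_temp requires length >= 8")
  vapply(seq, function(s) {
    n <- nchar(s)
    pairs <- substring(s, 1:(n - 1L), 2:n)
    dh <- sum(NN_DH[pairs])
    ds <- sum(NN_DS[pairs])
    for (endbase in c(substr(s, 1, 1), substr(s, n, n))) {
      init <- if (endbase %in% c("A", "T")) NN_INIT$AT else NN_INIT$GC
      dh <- dh + init[["dh"]]
      ds <- ds + init[["ds"]]
    }
    ds <- ds + 0.368 * (n - 1L) * log(config$mv_conc / 1000)
    ct <- config$oligo_conc * 1e-9
    dh * 1000 / (ds + 1.987 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC content of DNA sequences
#'
#' @param seq Character vector of DNA strings.
#' @return Numeric vector of GC percentages (0–100); `N` bases count toward
#'   the length but not the GC tally.
#' @examples
#' gc_content(c("GCGC", "ACGT"))
#' @export
gc_content <- function(seq) {
  gc <- nchar(gsub("[^GCgc]", "", seq))
  100 * gc / nchar(seq)
}

# longest single-base run in each sequence
max_homopolymer <- function(seq) {
  vapply(seq, function(s) {
    r <- rle(seq_chars(s))
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}

# crude self-complementarity screen: TRUE if any 8-mer of the primer is the
# reverse complement of another of its 8-mers (possible self-dimer)
self_dimer_8mer <- function(seq) {
  vapply(seq, function(s) {
    n <- nchar(s)
    if (n < 16L) return(FALSE)
    words <- substring(s, 1:(n - 7L), 8:n)
    any(revcomp(words) %in% words)
  }, logical(1), USE.NAMES = FALSE)
}

# all primer candidates within one flank sequence (coordinates are offsets
# into the flank, 0-based half-open); reverse candidates are taken on the
# reverse complement by the caller. Thermodynamics and GC are evaluated by
# prefix sums over the flank so the full placement grid stays cheap; the
# prefix-sum Tm is algebraically identical to melting_temp().
enumerate_primers <- function(flank, cfg) {
  n <- nchar(flank)
  empty <- tibble::tibble(start = integer(), len = integer(),
                          seq = character(), gc = numeric(), tm = numeric(),
                          penalty = numeric())
  if (n < cfg$len_min) return(empty)
  ch <- seq_chars(flank)
  valid <- ch %in% c("A", "C", "G", "T")
  din <- paste0(ch[-n], ch[-1L])
  dh <- unname(NN_DH[din])            # NA at any N-containing step
  ds <- unname(NN_DS[din])
  # N-containing candidates are excluded via cum_n, so zeros here are safe
  cum_dh <- c(0, cumsum(ifelse(is.na(dh), 0, dh)))
  cum_ds <- c(0, cumsum(ifelse(is.na(ds), 0, ds)))
  cum_gc <- c(0L, cumsum(ch %in% c("G", "C")))
  cum_n <- c(0L, cumsum(!valid))

  grid <- expand.grid(len = cfg$len_min:cfg$len_max,
                      start = 0:(n - cfg$len_min))
  grid <- grid[grid$start + grid$len <= n, , drop = FALSE]
  s0 <- grid$start; L <- grid$len
  keep <- (cum_n[s0 + L + 1L] - cum_n[s0 + 1L]) == 0L
  s0 <- s0[keep]; L <- L[keep]
  if (length(s0) == 0L) return(empty)

  gc <- 100 * (cum_gc[s0 + L + 1L] - cum_gc[s0 + 1L]) / L
  keep <- gc >= cfg$gc_min & gc <= cfg$gc_max
  s0 <- s0[keep]; L <- L[keep]; gc <- gc[keep]
  if (length(s0) == 0L) return(empty)

  # homopolymer screen: a candidate fails if it fully contains a single-base
  # run longer than max_poly_x
  runs <- rle(ch)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  long <- which(runs$lengths > cfg$max_poly_x & runs$values %in%
                  c("A", "C", "G", "T"))
  bad <- rep(FALSE, length(s0))
  for (r in long) {
    ovl <- pmin(run_end[r], s0 + L) - pmax(run_start[r], s0 + 1L) + 1L
    bad <- bad | ovl > cfg$max_poly_x
  }
  s0 <- s0[!bad]; L <- L[!bad]; gc <- gc[!bad]
  if (length(s0) == 0L) return(empty)

  # nearest-neighbor Tm via prefix sums (+ terminal initiation terms)
  dh_sum <- cum_dh[s0 + L] - cum_dh[s0 + 1L]
  ds_sum <- cum_ds[s0 + L] - cum_ds[s0 + 1L]
  init_of <- function(b) ifelse(b %in% c("A", "T"), NN_INIT$AT[["dh"]],
                                NN_INIT$GC[["dh"]])
  init_ds_of <- function(b) ifelse(b %in% c("A", "T"), NN_INIT$AT[["ds"]],
                                   NN_INIT$GC[["ds"]])
  first_b <- ch[s0 + 1L]; last_b <- ch[s0 + L]
  dh_sum <- dh_sum + init_of(first_b) + init_of(last_b)
  ds_sum <- ds_sum + init_ds_of(first_b) + init_ds_of(last_b) +
    0.368 * (L - 1L) * log(cfg$mv_conc / 1000)
  tm <- dh_sum * 1000 / (ds_sum + 1.987 * log(cfg$oligo_conc * 1e-9 / 4)) -
    273.15
  keep <- !is.na(tm) & tm >= cfg$tm_min & tm <= cfg$tm_max
  s0 <- s0[keep]; L <- L[keep]; gc <- gc[keep]; tm <- tm[keep]
  if (length(s0) == 0L) return(empty)

  cand <- tibble::tibble(start = s0, len = L,
                         seq = substr(rep(flank, length(s0)), s0 + 1L, s0 + L),
                         gc = gc, tm = tm)
  cand <- cand[!self_dimer_8mer(cand$seq), , drop = FALSE]
  # rounded so exact ties survive summation-order floating-point noise
  cand$penalty <- round(abs(cand$len - cfg$len_opt) +
    cfg$tm_penalty_weight * abs(cand$tm - cfg$tm_opt), 9)
  cand
}

#' Design one primer pair per unique-flank locus
#'
#' Enumerates every primer placement inside the left flank (forward primer)
#' and right flank (reverse primer, reported 5'->3' on the opposite strand)
#' that satisfies the length, GC, Tm, homopolymer and self-dimer
#' constraints, then returns per locus the pair minimising
#' `|len - len_opt|_fwd + |len - len_opt|_rev + w * (|Tm - tm_opt|_fwd +
#' |Tm - tm_opt|_rev)` subject to the product-size window; the product
#' always spans the full repeat tract. Ties break to the smaller product,
#' then the leftmost forward primer. Loci with no feasible pair are
#' omitted (their ids are kept in the `"failed_loci"` attribute).
#'
#' @param loci A `flanked_loci` tibble; only rows with `unique == TRUE` are
#'   used.
#' @param config A [primer_config()].
#' @return A tibble of class `primer_pairs`: `locus_id, seq_id, fwd_seq,
#'   rev_seq, fwd_start, fwd_end, rev_start, rev_end` (reference
#'   coordinates, 0-based half-open), `product_len, fwd_tm, rev_tm, fwd_gc,
#'   rev_gc, penalty, expected_size`.
#' @export
design_primers <- function(loci, config = primer_config()) {
  use <- loci[!is.na(loci$unique) & loci$unique, , drop = FALSE]
  rows <- vector("list", nrow(use))
  failed <- character(0)
  for (i in seq_len(nrow(use))) {
    res <- design_pair_one(use$left_flank[i], use$right_flank[i],
                           use$end[i] - use$start[i], config)
    if (is.null(res)) {
      failed <- c(failed, use$locus_id[i])
      next
    }
    fl <- nchar(use$left_flank[i])
    rows[[i]] <- tibble::tibble(
      locus_id = use$locus_id[i], genome_id = use$genome_id[i],
      seq_id = use$seq_id[i],
      fwd_seq = res$fwd_seq, rev_seq = res$rev_seq,
      fwd_start = use$start[i] - fl + res$fwd_off,
      fwd_end = use$start[i] - fl + res$fwd_off + nchar(res$fwd_seq),
      rev_start = use$end[i] + res$rev_off_from_tract,
      rev_end = use$end[i] + res$rev_off_from_tract + nchar(res$rev_seq),
      product_len = res$product_len,
      fwd_tm = res$fwd_tm, rev_tm = res$rev_tm,
      fwd_gc = res$fwd_gc, rev_gc = res$rev_gc,
      penalty = res$penalty, expected_size = res$product_len)
  }
  out <- dplyr::bind_rows(rows)
  if (length(failed))
    message(length(failed), " locus/loci with no feasible primer pair")
  attr(out, "failed_loci") <- failed
  class(out) <- c("primer_pairs", class(out))
  out
}

# optimum pair for one locus; offsets are relative to flank starts
design_pair_one <- function(left_flank, right_flank, tract_len, cfg) {
  fl <- nchar(left_flank)
  fr <- nchar(right_flank)
  fwd <- enumerate_primers(left_flank, cfg)
  if (nrow(fwd) == 0L) return(NULL)
  # reverse primers: enumerate on the revcomp of the right flank; a
  # candidate at offset r (0-based, from the 3' end of the right flank)
  # with length L occupies right-flank positions [fr - r - L, fr - r)
  rev <- enumerate_primers(revcomp(right_flank), cfg)
  if (nrow(rev) == 0L) return(NULL)
  # distance from tract end to reverse primer end:
  rev$end_from_tract <- fr - rev$start
  # product length = (fl - fwd_start) + tract_len + end_from_tract
  rev <- rev[order(rev$end_from_tract, rev$penalty), , drop = FALSE]
  # prefix best: for each count of eligible rev (end_from_tract ascending),
  # the minimum penalty so far with its earliest end_from_tract
  best_idx <- integer(nrow(rev))
  cur <- 1L
  for (j in seq_len(nrow(rev))) {
    if (rev$penalty[j] < rev$penalty[cur] ||
        (rev$penalty[j] == rev$penalty[cur] &&
         rev$end_from_tract[j] < rev$end_from_tract[cur])) cur <- j
    best_idx[j] <- cur
  }
  fwd <- fwd[order(fwd$start, fwd$penalty), , drop = FALSE]
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    left_part <- fl - fwd$start[i]
    max_end <- cfg$product_max - tract_len - left_part
    min_end <- cfg$product_min - tract_len - left_part
    hi <- findInterval(max_end, rev$end_from_tract)
    if (hi < 1L) next
    lo_ok <- rev$end_from_tract[seq_len(hi)] >= min_end
    if (!any(lo_ok)) next
    # scan eligible window for min penalty (tie: smaller end_from_tract)
    win <- which(lo_ok)
    if (length(win) == hi && min_end <= rev$end_from_tract[1]) {
      j <- best_idx[hi]
    } else {
      pens <- rev$penalty[win]
      j <- win[which.min(pens)]
    }
    tot <- fwd$penalty[i] + rev$penalty[j]
    prod <- left_part + tract_len + rev$end_from_tract[j]
    cand <- list(pen = tot, prod = prod, fwd_start = fwd$start[i], i = i,
                 j = j)
    if (is.null(best) || tot < best$pen ||
        (tot == best$pen && (prod < best$prod ||
          (prod == best$prod && fwd$start[i] < best$fwd_start))))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  i <- best$i; j <- best$j
  list(fwd_seq = fwd$seq[i], rev_seq = rev$seq[j],
       fwd_off = fwd$start[i],
       rev_off_from_tract = rev$end_from_tract[j] - rev$len[j],
       product_len = best$prod,
       fwd_tm = fwd$tm[i], rev_tm = rev$tm[j],
       fwd_gc = fwd$gc[i], rev_gc = rev$gc[j],
       penalty = best$pen)
}
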