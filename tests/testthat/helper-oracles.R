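# Independent brute-force oracles. These deliberately re-derive results by
# exhaustive scanning, sharing no candidate-generation code with the package.

# minimal-period check written independently of ssrmine:::has_smaller_period
oracle_is_periodic <- function(motif) {
  m <- nchar(motif)
  if (m == 1L) return(FALSE)
  ch <- strsplit(motif, "")[[1]]
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    if (all(ch == ch[((seq_len(m) - 1L) %% d) + 1L])) return(TRUE)
  }
  FALSE
}

# brute-force perfect-SSR scan: tests every (position, motif length) with a
# descending-copies recurrence, then applies the documented resolution
# policy (longest wins, ties to smaller motif length, then leftmost)
oracle_find_ssrs <- function(s, cfg = detection_config()) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  valid <- ch %in% c("A", "C", "G", "T")
  cand <- list()
  for (m in seq_len(cfg$max_motif_len)) {
    thr <- cfg$min_repeats[[as.character(m)]]
    if (n < m * thr) next
    copies <- integer(n)
    for (i in seq(n - m + 1L, 1L)) {
      if (!all(valid[i:(i + m - 1L)])) next
      nxt <- i + m
      if (nxt + m - 1L <= n && all(ch[i:(i + m - 1L)] ==
                                   ch[nxt:(nxt + m - 1L)]))
        copies[i] <- copies[nxt] + 1L
      else copies[i] <- 1L
    }
    for (i in seq_len(n - m + 1L)) {
      if (copies[i] < thr) next
      if (i - m >= 1L && all(valid[(i - m):(i - 1L)]) &&
          all(ch[(i - m):(i - 1L)] == ch[i:(i + m - 1L)])) next
      motif <- paste(ch[i:(i + m - 1L)], collapse = "")
      if (oracle_is_periodic(motif)) next
      cand[[length(cand) + 1L]] <- data.frame(
        start = i - 1L, end = i - 1L + m * copies[i], motif = motif,
        motif_len = m, repeat_count = copies[i])
    }
  }
  if (length(cand) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), motif_len = integer(),
                      repeat_count = integer()))
  cand <- do.call(rbind, cand)
  cand <- cand[order(-(cand$end - cand$start), cand$motif_len, cand$start), ]
  keep <- logical(nrow(cand))
  taken_start <- integer(0); taken_end <- integer(0)
  for (r in seq_len(nrow(cand))) {
    if (all(cand$end[r] <= taken_start | cand$start[r] >= taken_end)) {
      keep[r] <- TRUE
      taken_start <- c(taken_start, cand$start[r])
      taken_end <- c(taken_end, cand$end[r])
    }
  }
  out <- cand[keep, ]
  out[order(out$start), ]
}

# full-scan e-PCR binding-site oracle: tries every seed anchor position on
# both strands with vectorised mismatch counting, then validates the 5'
# remainder with the package's general DP (the implementation itself uses
# the enumeration fast path at these budgets)
oracle_binding_sites <- function(primer, genome, cfg = epcr_config()) {
  w <- cfg$word_size
  rows <- list()
  for (sid in names(genome$seq)) {
    g <- strsplit(genome$seq[[sid]], "")[[1]]
    n <- length(g)
    if (n < w) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") primer else revcomp(primer)
      pch <- strsplit(pat, "")[[1]]
      np <- length(pch)
      seed <- if (strand == "+") pch[(np - w + 1L):np] else pch[1:w]
      term_k <- if (strand == "+") w else 1L
      anchors <- seq_len(n - w + 1L)
      mism <- rep(0L, length(anchors))
      for (k in seq_len(w))
        mism <- mism + (g[anchors + k - 1L] != seed[k] |
                          g[anchors + k - 1L] == "N")
      term_ok <- g[anchors + term_k - 1L] == seed[term_k]
      ok <- which(mism <= cfg$discontig_words & term_ok)
      for (p in ok) {
        p0 <- p - 1L
        rest <- if (strand == "+") substr(pat, 1L, np - w) else
          substr(pat, w + 1L, np)
        if (nchar(rest) == 0L) {
          fit <- list(mm = 0L, ind = 0L, glen = 0L)
        } else if (strand == "+") {
          lo <- max(0L, p0 - nchar(rest) - cfg$max_indels)
          gseg <- substr(genome$seq[[sid]], lo + 1L, p0)
          fit <- ssrmine:::align_tail_dp(
            ssrmine:::reverse_str(rest), ssrmine:::reverse_str(gseg), cfg)
        } else {
          hi <- min(n, p0 + w + nchar(rest) + cfg$max_indels)
          gseg <- substr(genome$seq[[sid]], p0 + w + 1L, hi)
          fit <- ssrmine:::align_tail_dp(rest, gseg, cfg)
        }
        if (is.null(fit)) next
        rows[[length(rows) + 1L]] <- data.frame(
          seq_id = sid,
          start = if (strand == "+") p0 - fit$glen else p0,
          end = if (strand == "+") p0 + w else p0 + w + fit$glen,
          strand = strand,
          mismatches = fit$mm + mism[p], indels = fit$ind)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), indels = integer()))
  out <- unique(do.call(rbind, rows))
  out[order(out$seq_id, out$start), ]
}

# exhaustive primer-pair oracle on small flanks: all placements, all pairs
oracle_best_pair <- function(left_flank, right_flank, tract_len,
                             cfg = primer_config()) {
  all_cands <- function(fseq) {
    out <- list()
    for (L in cfg$len_min:cfg$len_max) {
      if (nchar(fseq) < L) next
      for (s0 in 0:(nchar(fseq) - L)) {
        sq <- substr(fseq, s0 + 1L, s0 + L)
        if (grepl("[^ACGT]", sq)) next
        gc <- 100 * nchar(gsub("[^GC]", "", sq)) / L
        if (gc < cfg$gc_min || gc > cfg$gc_max) next
        if (grepl(sprintf("(A{%d}|C{%d}|G{%d}|T{%d})", cfg$max_poly_x + 1L,
                          cfg$max_poly_x + 1L, cfg$max_poly_x + 1L,
                          cfg$max_poly_x + 1L), sq)) next
        tm <- melting_temp(sq, cfg)
        if (tm < cfg$tm_min || tm > cfg$tm_max) next
        words <- substring(sq, 1:(L - 7L), 8:L)
        if (any(revcomp(words) %in% words)) next
        out[[length(out) + 1L]] <- data.frame(
          start = s0, len = L, seq = sq, tm = tm,
          pen = round(abs(L - cfg$len_opt) +
            cfg$tm_penalty_weight * abs(tm - cfg$tm_opt), 9))
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  fwd <- all_cands(left_flank)
  rev <- all_cands(revcomp(right_flank))
  if (is.null(fwd) || is.null(rev)) return(NULL)
  fl <- nchar(left_flank); fr <- nchar(right_flank)
  best <- NULL
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      prod <- (fl - fwd$start[i]) + tract_len + (fr - rev$start[j])
      if (prod < cfg$product_min || prod > cfg$product_max) next
      pen <- fwd$pen[i] + rev$pen[j]
      cand <- list(pen = pen, prod = prod, fwd_start = fwd$start[i],
                   fwd_seq = fwd$seq[i], rev_seq = rev$seq[j])
      if (is.null(best) || pen < best$pen ||
          (pen == best$pen && (prod < best$prod ||
            (prod == best$prod && fwd$start[i] < best$fwd_start))))
        best <- cand
    }
  }
  best
}
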