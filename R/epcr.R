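#' Find genomic binding sites for a single primer
#'
#' Emulates the hash-based electronic-PCR site search: the primer's
#' 3'-terminal `word_size`-mer must match the genome exactly except for up
#' to `discontig_words` wildcard positions (the 3'-terminal base itself must
#' always match), and the remaining 5' portion must align immediately
#' upstream with at most `max_mismatches` mismatches and `max_indels`
#' indels. Both strands are searched.
#'
#' @param primer Primer sequence, 5'->3', `A,C,G,T` only, longer than the
#'   seed word.
#' @param genome A [genome_seq()].
#' @param config An [epcr_config()].
#' @return A tibble with one row per site: `seq_id, start, end` (0-based
#'   half-open genomic footprint), `strand` (`"+"` if the primer matches the
#'   forward strand), `mismatches, indels`.
#' @export
find_binding_sites <- function(primer, genome, config = epcr_config()) {
  stopifnot(inherits(genome, "genome_seq"))
  if (grepl("[^ACGT]", primer)) stop("primer must be A,C,G,T only")
  w <- config$word_size
  if (nchar(primer) <= w) stop("primer length must exceed word_size")
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    # on "+" the seed word is the rightmost w bases of the pattern; on "-"
    # (pattern = revcomp(primer)) it is the leftmost w bases, and the
    # primer's 3'-terminal base maps to the pattern's first base
    for (sid in names(genome$seq)) {
      subject <- Biostrings::DNAString(genome$seq[[sid]])
      seed <- if (strand == "+") substr(pat, nchar(pat) - w + 1L, nchar(pat))
              else substr(pat, 1L, w)
      m <- Biostrings::matchPattern(seed, subject,
                                    max.mismatch = config$discontig_words)
      if (length(m) == 0L) next
      starts <- BiocGenerics::start(m) - 1L     # 0-based seed start
      sites <- check_candidates(pat, strand, genome$seq[[sid]], starts, w,
                                config)
      if (!is.null(sites) && nrow(sites)) {
        sites$seq_id <- sid
        sites$strand <- strand
        out[[length(out) + 1L]] <- sites
      }
    }
  }
  if (length(out) == 0L)
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer(), indels = integer()))
  res <- dplyr::bind_rows(out)
  tibble::as_tibble(res[order(res$seq_id, res$start),
                        c("seq_id", "start", "end", "strand", "mismatches",
                          "indels")])
}

# validate seed-anchored candidates: wildcard placement in the word, then
# the 5' remainder via a small banded DP with separate mismatch/indel budgets
check_candidates <- function(pat, strand, s, seed_starts, w, cfg) {
  n <- nchar(pat)
  rows <- list()
  for (p0 in seed_starts) {
    word_g <- substr(s, p0 + 1L, p0 + w)
    if (grepl("N", word_g, fixed = TRUE)) next
    word_p <- if (strand == "+") substr(pat, n - w + 1L, n) else
      substr(pat, 1L, w)
    diff <- which(charToRaw(word_g) != charToRaw(word_p))
    # the primer's 3'-terminal base must match exactly
    term_pos <- if (strand == "+") w else 1L
    if (term_pos %in% diff) next
    if (length(diff) > cfg$discontig_words) next
    rest <- if (strand == "+") substr(pat, 1L, n - w) else
      substr(pat, w + 1L, n)
    if (nchar(rest) == 0L) {
      fit <- list(mm = 0L, ind = 0L, glen = 0L)
    } else if (strand == "+") {
      # remainder aligns immediately left of the seed, right-anchored
      lo <- max(0L, p0 - nchar(rest) - cfg$max_indels)
      gseg <- substr(s, lo + 1L, p0)
      fit <- align_tail(reverse_str(rest), reverse_str(gseg), cfg)
    } else {
      # remainder aligns immediately right of the seed, left-anchored
      hi <- min(nchar(s), p0 + w + nchar(rest) + cfg$max_indels)
      gseg <- substr(s, p0 + w + 1L, hi)
      fit <- align_tail(rest, gseg, cfg)
    }
    if (is.null(fit)) next
    if (strand == "+") {
      start <- p0 - fit$glen; end <- p0 + w
    } else {
      start <- p0; end <- p0 + w + fit$glen
    }
    # reported mismatches include wildcard substitutions inside the seed
    # word, but only 5'-portion mismatches count against the budget
    rows[[length(rows) + 1L]] <-
      data.frame(start = start, end = end,
                 mismatches = fit$mm + length(diff),
                 indels = fit$ind)
  }
  if (length(rows)) unique(do.call(rbind, rows)) else NULL
}

reverse_str <- function(x) paste(rev(seq_chars(x)), collapse = "")

# left-anchored alignment of query against a genome segment: the query must
# be consumed entirely, starting at segment position 1, with mismatch and
# indel budgets tracked separately. Returns the minimal (indels, mismatches)
# fit (lexicographic) and the number of genome characters consumed, or NULL.
# For indel budgets <= 1 the single-gap placements are enumerated exactly;
# larger budgets fall back to the banded DP.
align_tail <- function(query, gseg, cfg) {
  if (cfg$max_indels <= 1L) align_tail_enum(query, gseg, cfg)
  else align_tail_dp(query, gseg, cfg)
}

align_tail_enum <- function(query, gseg, cfg) {
  q <- charToRaw(query); g <- charToRaw(gseg)
  rawN <- charToRaw("N")
  nq <- length(q); ng <- length(g)
  mism <- function(qi, gi) {
    if (length(qi) == 0L) return(0L)
    sum(q[qi] != g[gi] | g[gi] == rawN)
  }
  best <- NULL
  consider <- function(mm, ind, glen) {
    if (mm > cfg$max_mismatches) return()
    if (is.null(best) || ind < best$ind ||
        (ind == best$ind && mm < best$mm))
      best <<- list(mm = as.integer(mm), ind = as.integer(ind),
                    glen = as.integer(glen))
  }
  if (ng >= nq) consider(mism(1:nq, 1:nq), 0L, nq)
  if (cfg$max_indels >= 1L) {
    # one query base unpaired (genome consumes nq - 1)
    if (ng >= nq - 1L) {
      for (t in 1:nq) {
        mm <- mism(seq_len(t - 1L), seq_len(t - 1L)) +
          (if (t < nq) mism((t + 1L):nq, t:(nq - 1L)) else 0L)
        consider(mm, 1L, nq - 1L)
      }
    }
    # one genome base unpaired (genome consumes nq + 1)
    if (ng >= nq + 1L) {
      for (t in 1:(nq + 1L)) {
        mm <- mism(seq_len(t - 1L), seq_len(t - 1L)) +
          (if (t <= nq) mism(t:nq, (t + 1L):(nq + 1L)) else 0L)
        consider(mm, 1L, nq + 1L)
      }
    }
  }
  best
}

align_tail_dp <- function(query, gseg, cfg) {
  qc <- seq_chars(query); gc_ <- seq_chars(gseg)
  nq <- length(qc); ng <- length(gc_)
  max_ind <- cfg$max_indels; max_mm <- cfg$max_mismatches
  INF <- 1000L
  # best[i+1, j+1, k+1] = min mismatches aligning first i query chars to
  # first j genome chars with exactly k indels
  best <- array(INF, dim = c(nq + 1L, ng + 1L, max_ind + 1L))
  best[1L, 1L, 1L] <- 0L
  for (i in 0:nq) {
    for (j in 0:ng) {
      for (k in 0:max_ind) {
        cur <- best[i + 1L, j + 1L, k + 1L]
        if (cur >= INF) next
        if (i < nq && j < ng) {
          mm <- cur + (qc[i + 1L] != gc_[j + 1L] | gc_[j + 1L] == "N")
          if (mm < best[i + 2L, j + 2L, k + 1L])
            best[i + 2L, j + 2L, k + 1L] <- mm
        }
        if (k < max_ind) {
          if (i < nq && cur < best[i + 2L, j + 1L, k + 2L])
            best[i + 2L, j + 1L, k + 2L] <- cur   # query base unpaired
          if (j < ng && cur < best[i + 1L, j + 2L, k + 2L])
            best[i + 1L, j + 2L, k + 2L] <- cur   # genome base unpaired
        }
      }
    }
  }
  found <- NULL
  for (k in 0:max_ind) {
    for (j in 0:ng) {
      mm <- best[nq + 1L, j + 1L, k + 1L]
      if (mm <= max_mm) {
        if (is.null(found) || k < found$ind ||
            (k == found$ind && mm < found$mm))
          found <- list(mm = as.integer(mm), ind = k, glen = j)
      }
    }
  }
  found
}

#' Run electronic PCR for one primer pair
#'
#' Finds all binding sites of both primers, pairs every forward-strand site
#' of one primer with every reverse-strand site of the other (in both role
#' assignments) into candidate amplicons of at most `max_product` bp, and
#' classifies the marker: `unique` if exactly one amplicon exists and its
#' size is within `size_deviation` of `expected_size`; `multi_site` if two
#' or more amplicons exist; `no_site` otherwise.
#'
#' @param fwd,rev Primer sequences, 5'->3'.
#' @param genome A [genome_seq()].
#' @param expected_size Expected amplicon size (bp).
#' @param config An [epcr_config()].
#' @return A `specificity_call` list: `status`, and `amplicons` (tibble with
#'   `seq_id, start, end, product_len, fwd_strand, mismatches_fwd,
#'   mismatches_rev, indels_fwd, indels_rev, within_expected_size`).
#' @export
epcr <- function(fwd, rev, genome, expected_size, config = epcr_config()) {
  sites_f <- find_binding_sites(fwd, genome, config)
  sites_r <- find_binding_sites(rev, genome, config)
  amp <- dplyr::bind_rows(
    pair_sites(sites_f, sites_r, "+", config),
    pair_sites(sites_r, sites_f, "-", config))
  if (nrow(amp)) {
    amp <- amp[!duplicated(amp[, c("seq_id", "start", "end")]), ,
               drop = FALSE]
    amp$within_expected_size <- abs(amp$product_len - expected_size) <=
      config$size_deviation
    amp <- amp[order(amp$seq_id, amp$start), , drop = FALSE]
  } else {
    amp$within_expected_size <- logical(0)
  }
  status <- if (nrow(amp) >= 2L) "multi_site"
            else if (nrow(amp) == 1L && amp$within_expected_size) "unique"
            else "no_site"
  structure(list(status = status, amplicons = tibble::as_tibble(amp)),
            class = "specificity_call")
}

# left primer on "+" strand paired with right primer on "-" strand
pair_sites <- function(left_sites, right_sites, fwd_strand, config) {
  lp <- left_sites[left_sites$strand == "+", , drop = FALSE]
  rp <- right_sites[right_sites$strand == "-", , drop = FALSE]
  if (nrow(lp) == 0L || nrow(rp) == 0L)
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), product_len = integer(),
                          fwd_strand = character(),
                          mismatches_fwd = integer(),
                          mismatches_rev = integer(),
                          indels_fwd = integer(), indels_rev = integer()))
  grid <- expand.grid(i = seq_len(nrow(lp)), j = seq_len(nrow(rp)))
  ok <- lp$seq_id[grid$i] == rp$seq_id[grid$j] &
    rp$start[grid$j] >= lp$start[grid$i] &
    rp$end[grid$j] >= lp$end[grid$i] &
    rp$end[grid$j] - lp$start[grid$i] <= config$max_product
  grid <- grid[ok, , drop = FALSE]
  fwd_is_left <- fwd_strand == "+"
  mm_f <- if (fwd_is_left) lp$mismatches[grid$i] else rp$mismatches[grid$j]
  mm_r <- if (fwd_is_left) rp$mismatches[grid$j] else lp$mismatches[grid$i]
  in_f <- if (fwd_is_left) lp$indels[grid$i] else rp$indels[grid$j]
  in_r <- if (fwd_is_left) rp$indels[grid$j] else lp$indels[grid$i]
  tibble::tibble(seq_id = lp$seq_id[grid$i],
                 start = lp$start[grid$i], end = rp$end[grid$j],
                 product_len = rp$end[grid$j] - lp$start[grid$i],
                 fwd_strand = fwd_strand,
                 mismatches_fwd = mm_f, mismatches_rev = mm_r,
                 indels_fwd = in_f, indels_rev = in_r)
}

#' @export
print.specificity_call <- function(x, ...) {
  cat("<specificity_call> status:", x$status, "-", nrow(x$amplicons),
      "amplicon(s)\n")
  invisible(x)
}

#' Electronic PCR over a batch of markers
#'
#' @param pairs Tibble with columns `marker_id` (or `locus_id`), `fwd_seq`,
#'   `rev_seq`, `expected_size`.
#' @param genome A [genome_seq()].
#' @param config An [epcr_config()].
#' @return A tibble of class `specificity_calls`: `marker_id, status,
#'   n_amplicons, product_len` (of the single amplicon when unique), with a
#'   `summary` attribute counting markers by status.
#' @export
epcr_batch <- function(pairs, genome, config = epcr_config()) {
  id_col <- if ("marker_id" %in% names(pairs)) "marker_id" else "locus_id"
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    call <- epcr(pairs$fwd_seq[i], pairs$rev_seq[i], genome,
                 pairs$expected_size[i], config)
    tibble::tibble(marker_id = pairs[[id_col]][i], status = call$status,
                   n_amplicons = nrow(call$amplicons),
                   product_len = if (call$status == "unique")
                     call$amplicons$product_len[1] else NA_integer_)
  })
  out <- dplyr::bind_rows(rows)
  smry <- table(factor(out$status,
                       levels = c("unique", "multi_site", "no_site")))
  attr(out, "summary") <- as.list(smry)
  class(out) <- c("specificity_calls", class(out))
  out
}
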