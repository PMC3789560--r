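#' Construct a genome sequence object
#'
#' A `genome_seq` is a named character vector of uppercase DNA sequences
#' (one per contig/chromosome) plus a genome identifier. All coordinates in
#' this package are 0-based half-open in memory; conversion to 1-based
#' (GFF3) or 0-based half-open (BED) happens only at I/O boundaries.
#'
#' @param seq Named character vector of DNA sequences; characters outside
#'   `A,C,G,T,N` are mapped to `N` (with a message giving the count).
#' @param genome_id Genome identifier string.
#' @return A `genome_seq` object.
#' @export
genome_seq <- function(seq, genome_id = "genome") {
  if (is.null(names(seq)) || anyNA(names(seq)) || any(names(seq) == ""))
    stop("all sequences must be named (seq_id)")
  if (anyDuplicated(names(seq)))
    stop("duplicate seq_id: ", names(seq)[duplicated(names(seq))][1])
  if (any(nchar(seq) == 0L)) stop("empty sequence not allowed")
  seq <- toupper(seq)
  n_bad <- sum(nchar(seq)) - sum(nchar(gsub("[^ACGTN]", "", seq)))
  if (n_bad > 0L) {
    message(n_bad, " non-ACGTN base(s) mapped to N")
    seq <- vapply(seq, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  structure(list(genome_id = genome_id, seq = seq), class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", x$genome_id, ": ", length(x$seq), " sequence(s), ",
      format(sum(nchar(x$seq)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

#' Contig lengths of a genome
#' @param genome A `genome_seq`.
#' @return Named integer vector of sequence lengths (bp).
#' @export
genome_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_seq"))
  vapply(genome$seq, nchar, integer(1))
}

#' Read a genome FASTA file
#'
#' Headers are taken up to the first whitespace as `seq_id`; lowercase bases
#' are uppercased and IUPAC ambiguity codes are mapped to `N`.
#'
#' @param path FASTA file path.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @return A [genome_seq()] object.
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(lines[nonblank[1]], ">"))
    stop("malformed FASTA (first non-blank line ", nonblank[1],
         " does not start with '>'): ", path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  body <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""),
                 character(1))
  # groups are 1..n_headers in order; records with no body stay empty and
  # are rejected by genome_seq()
  filled <- stats::setNames(rep("", length(ids)), as.character(seq_along(ids)))
  filled[names(body)] <- body
  if (anyDuplicated(ids))
    stop("duplicate seq_id in FASTA: ", ids[duplicated(ids)][1])
  genome_seq(stats::setNames(unname(filled), ids),
             genome_id = genome_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a genome FASTA file
#'
#' @param genome A [genome_seq()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_seq"))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome$seq)) {
    s <- genome$seq[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", id), substring(s, starts,
                                            pmin(starts + width - 1L, nchar(s)))),
               con)
  }
  invisible(path)
}

# genome substring on 0-based half-open coordinates
genome_sub <- function(genome, seq_id, start, end) {
  substr(genome$seq[[seq_id]], start + 1L, end)
}
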