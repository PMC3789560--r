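#' Read gene features from a GFF3 file
#'
#' Returns the raw feature table with 1-based inclusive coordinates exactly
#' as read (conversion to the package's internal 0-based half-open
#' convention happens inside [build_region_model()]). `Parent` links are
#' resolved against feature `ID`s; features whose parent is unknown are
#' dropped with a warning.
#'
#' @param path GFF3 file path.
#' @param keep_types Feature types retained; defaults to the types needed
#'   for genomic-region classification.
#' @return A tibble with columns `seq_id, source, type, start, end, strand,
#'   id, parent`.
#' @export
read_gff3 <- function(path,
                      keep_types = c("gene", "mRNA", "exon", "CDS",
                                     "five_prime_UTR", "three_prime_UTR")) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(tibble::tibble(seq_id = character(), source = character(),
                          type = character(), start = integer(),
                          end = integer(), strand = character(),
                          id = character(), parent = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 9L))
    stop("malformed GFF3 line (expected 9 tab-separated fields): line ",
         which(lengths(parts) != 9L)[1])
  m <- do.call(rbind, parts)
  attr_field <- m[, 9]
  get_attr <- function(key) {
    val <- stringr::str_match(attr_field, paste0("(?:^|;)\\s*", key, "=([^;]+)"))[, 2]
    val
  }
  feats <- tibble::tibble(
    seq_id = m[, 1], source = m[, 2], type = m[, 3],
    start = as.integer(m[, 4]), end = as.integer(m[, 5]),
    strand = m[, 7],
    id = get_attr("ID"), parent = get_attr("Parent"))
  if (any(feats$end < feats$start))
    stop("GFF3 feature with end < start: line ",
         which(feats$end < feats$start)[1])
  feats <- feats[feats$type %in% keep_types, , drop = FALSE]
  known <- feats$id[!is.na(feats$id)]
  orphan <- !is.na(feats$parent) & !(feats$parent %in% known)
  if (any(orphan)) {
    warning(sum(orphan), " feature(s) with unknown Parent dropped")
    feats <- feats[!orphan, , drop = FALSE]
  }
  feats
}

#' Write features to a GFF3 file
#'
#' @param features Tibble as returned by [read_gff3()] (1-based inclusive
#'   coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  attrs <- ifelse(is.na(features$id), "",
                  paste0("ID=", features$id)) |>
    paste0(ifelse(is.na(features$parent), "",
                  paste0(ifelse(is.na(features$id), "", ";"),
                         "Parent=", features$parent)))
  lines <- paste(features$seq_id,
                 features$source %||% "ssrmine",
                 features$type, features$start, features$end,
                 ".", features$strand, ".",
                 ifelse(nzchar(attrs), attrs, "."),
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
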