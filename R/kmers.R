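#' Count canonical k-mers
#'
#' Counts every length-`k` window containing only ACGT (case-insensitive),
#' collapsed to its canonical form: the lexicographic minimum of the window
#' and its reverse complement. Windows containing any other symbol are
#' skipped. Counting is exact and in memory; the practical ceiling is around
#' 1e8 distinct k-mers.
#'
#' @param sequences character vector of DNA sequences.
#' @param k k-mer size, 3 <= k <= 26 (odd values recommended so no k-mer is
#'   its own reverse complement).
#' @return a `kmer_table`: list with `k`, sorted numeric `codes` (2-bit
#'   packed canonical k-mers) and integer `counts`.
#' @export
count_kmers <- function(sequences, k) {
  check_scalar(k, "k", min = 1, max = 26, integer = TRUE)
  res <- cpp_count_kmers(as.character(sequences), as.integer(k))
  structure(list(k = as.integer(k), codes = res$codes, counts = res$counts),
            class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf("kmer_table: k=%d, %d distinct canonical k-mers, %.0f total occurrences\n",
              x$k, length(x$codes), sum(as.numeric(x$counts))))
  invisible(x)
}

#' Named k-mer counts from a table
#'
#' Decodes the packed codes into k-mer strings. Intended for small tables
#' (inspection and tests).
#'
#' @param table a `kmer_table`.
#' @return named integer vector, names are canonical k-mer strings.
#' @export
kmer_counts <- function(table) {
  setNames(table$counts, cpp_decode_kmers(table$codes, table$k))
}

#' Occurrence counts of sequences' k-mers in a k-mer table
#'
#' @param table a `kmer_table`.
#' @param sequence a single DNA string.
#' @return integer vector, one entry per k-mer position of `sequence` (NA for
#'   windows containing non-ACGT symbols; 0 when absent from the table).
#' @export
kmer_position_counts <- function(table, sequence) {
  codes <- cpp_kmer_codes(sequence, table$k)
  cpp_lookup_codes(table$codes, table$counts, codes)
}

#' Build the k-mer coverage histogram
#'
#' @param table a `kmer_table`.
#' @return a `kmer_histogram`: list with `k`, integer `depth` (sorted,
#'   distinct) and numeric `count` (number of distinct canonical k-mers seen
#'   at that depth).
#' @export
build_histogram <- function(table) {
  if (length(table$counts) == 0)
    return(kmer_histogram(integer(0), numeric(0), k = table$k))
  tab <- table(table$counts)
  kmer_histogram(as.integer(names(tab)), as.numeric(tab), k = table$k)
}

#' Construct a k-mer histogram from depth/count pairs
#'
#' @param depth integer vector of coverage depths (>= 1).
#' @param count numeric vector of distinct-k-mer counts per depth (>= 0).
#' @param k the k-mer size the histogram was built at (optional metadata).
#' @return a `kmer_histogram`.
#' @export
kmer_histogram <- function(depth, count, k = NA_integer_) {
  if (length(depth) != length(count))
    abort_validation("depth and count must have equal length")
  if (length(depth) > 0) {
    if (any(depth < 1 | depth != round(depth)))
      abort_validation("depths must be integers >= 1")
    if (any(count < 0))
      abort_validation("counts must be >= 0")
    o <- order(depth)
    depth <- as.integer(depth[o]); count <- as.numeric(count[o])
    if (anyDuplicated(depth))
      abort_validation("duplicate depths in histogram")
  }
  structure(list(k = k, depth = as.integer(depth), count = as.numeric(count)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("kmer_histogram: k=%s, %d depth classes, D=%.0f distinct, T=%.0f total\n",
              ifelse(is.na(x$k), "?", x$k), length(x$depth),
              hist_distinct(x), hist_total(x)))
  invisible(x)
}

#' Distinct k-mers in a histogram (D = sum h(c))
#' @param hist a `kmer_histogram`.
#' @return numeric scalar.
#' @export
hist_distinct <- function(hist) sum(hist$count)

#' Total k-mer occurrences in a histogram (T = sum c * h(c))
#' @param hist a `kmer_histogram`.
#' @return numeric scalar.
#' @export
hist_total <- function(hist) sum(as.numeric(hist$depth) * hist$count)
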