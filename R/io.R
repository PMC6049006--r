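#' Read a FASTA file
#'
#' Gzip transparent by extension. Sequence case is preserved; analyses
#' upcase internally.
#'
#' @param path file path (`.gz` accepted).
#' @return named character vector of sequences (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  first <- readLines(path, n = 1)
  if (length(first) == 1 && !startsWith(first, ">"))
    abort_parse("malformed FASTA (line 1): expected '>' header, got '",
                substr(first, 1, 30), "'")
  x <- Biostrings::readBStringSet(path, format = "fasta")
  setNames(as.character(x), names(x))
}

#' Write a FASTA file
#'
#' Sequences are wrapped at 80 columns; a `.gz` extension enables gzip
#' compression.
#'
#' @param sequences named character vector.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 80,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path file path (`.gz` accepted).
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  parsed <- tryCatch({
    x <- Biostrings::readBStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
    ids <- names(x)
    seqs <- as.character(x)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
    bad <- which(nchar(qual, type = "bytes") != nchar(seqs, type = "bytes"))
    if (length(bad) > 0)
      stop("quality/sequence length mismatch for read '", ids[bad[1]], "'")
    list(ids = ids, seqs = seqs, qual = qual)
  }, error = function(e) abort_parse("malformed FASTQ in ", path, ": ",
                                     conditionMessage(e)))
  data.frame(id = parsed$ids, seq = unname(parsed$seqs),
             qual = unname(parsed$qual), stringsAsFactors = FALSE)
}

#' Write a FASTQ file
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output path; `.gz` enables gzip.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  bad <- which(nchar(reads$qual) != nchar(reads$seq))
  if (length(bad) > 0)
    abort_validation("quality/sequence length mismatch for read '",
                     reads$id[bad[1]], "'")
  x <- Biostrings::BStringSet(setNames(reads$seq, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a k-mer coverage histogram
#'
#' Two whitespace-separated integer columns, `depth count`, no header (the
#' common `.histo` layout). Blank lines are ignored; depths need not be
#' contiguous.
#'
#' @param path file path.
#' @param k optional k-mer size to attach as metadata.
#' @return a `kmer_histogram`.
#' @export
read_histogram <- function(path, k = NA_integer_) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) return(kmer_histogram(integer(0), numeric(0), k = k))
  fields <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 2 || !all(grepl("^[0-9]+$", f)))
      abort_parse("malformed histogram (line ", keep[i],
                  "): expected two integer fields, got '", lines[keep[i]], "'")
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 2, byrow = TRUE)
  kmer_histogram(as.integer(m[, 1]), m[, 2], k = k)
}

#' Write a k-mer coverage histogram
#'
#' @param hist a `kmer_histogram`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_histogram <- function(hist, path) {
  writeLines(sprintf("%d %.0f", hist$depth, hist$count), path)
  invisible(path)
}

#' Read a per-contig depth table
#'
#' Tab-separated, `contig_id` followed by one or more depth columns, no
#' header.
#'
#' @param path file path.
#' @return named numeric vector (first depth column) or matrix with rownames
#'   when multiple samples are present.
#' @export
read_depth_table <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    abort_parse("depth table needs at least two columns")
  depths <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(depths) || any(!is.finite(depths)) || any(depths < 0))
    abort_parse("depth columns must be nonnegative numbers")
  rownames(depths) <- tab[, 1]
  if (ncol(depths) == 1) setNames(depths[, 1], tab[, 1]) else depths
}

#' Write a per-contig depth table
#'
#' @param depths named numeric vector or matrix with rownames.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_depth_table <- function(depths, path) {
  if (is.matrix(depths)) {
    tab <- data.frame(id = rownames(depths), depths)
  } else {
    tab <- data.frame(id = names(depths), depth = unname(depths))
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
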