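#' Nx contiguity metric
#'
#' Sort lengths descending; `Nx` is the length at which the cumulative sum
#' first reaches x% of the total, `Lx` the number of sequences up to and
#' including it.
#'
#' @param lengths vector of positive sequence lengths.
#' @param x percent threshold (default 50).
#' @return list with `Nx` and `Lx`.
#' @export
nx_metric <- function(lengths, x = 50) {
  if (length(lengths) == 0)
    abort_validation("lengths must be non-empty")
  if (any(lengths <= 0))
    abort_validation("lengths must all be positive")
  check_scalar(x, "x", min = 0, max = 100)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  i <- which(cumsum(s) >= x / 100 * sum(s))[1]
  list(Nx = s[i], Lx = i)
}

#' NGx contiguity metric against an estimated genome size
#'
#' As [nx_metric()] but the threshold is x% of `genome_size`; `NA` when the
#' assembly total falls short of the threshold.
#'
#' @param lengths vector of positive sequence lengths.
#' @param genome_size estimated genome size in bases.
#' @param x percent threshold (default 50).
#' @return list with `NGx` and `LGx` (both NA when undefined).
#' @export
ngx_metric <- function(lengths, genome_size, x = 50) {
  check_scalar(genome_size, "genome_size", min = 1e-9)
  check_scalar(x, "x", min = 0, max = 100)
  s <- sort(as.numeric(lengths), decreasing = TRUE)
  thr <- x / 100 * genome_size
  cum <- cumsum(s)
  if (length(s) == 0 || cum[length(s)] < thr)
    return(list(NGx = NA_real_, LGx = NA_integer_))
  i <- which(cum >= thr)[1]
  list(NGx = s[i], LGx = i)
}

# uppercase and map every non-ACGT symbol to N
sanitize_dna <- function(x) gsub("[^ACGT]", "N", toupper(x))

#' Assembly metrics for one scaffold set
#'
#' Computes the contiguity, composition, and usefulness parameters for a
#' single assembly: scaffold and contig counts and lengths (contigs obtained
#' by splitting scaffolds at runs of at least `n_split` Ns), N50/L50 and
#' NG50/LG50 at both levels, GC content over non-N bases, N content, contigs
#' over 10 kb, and the percentage of the estimated genome size contained in
#' scaffolds of at least 7 kb (average invertebrate gene) and 25 kb (average
#' vertebrate gene). Non-ACGTN symbols are counted as N.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param genome_size_estimate estimated genome size in bases; when NULL or
#'   non-positive the NG50 and usefulness fields are NA.
#' @param n_split minimum N-run length that separates contigs.
#' @param gene_sizes thresholds (bases) for the usefulness percentages.
#' @return an `assembly_metrics` list.
#' @export
assembly_metrics <- function(scaffolds, genome_size_estimate = NULL,
                             n_split = 10,
                             gene_sizes = c(invertebrate = 7000,
                                            vertebrate = 25000)) {
  if (length(scaffolds) == 0)
    abort_validation("need at least one scaffold")
  check_scalar(n_split, "n_split", min = 1, integer = TRUE)
  seqs <- sanitize_dna(scaffolds)
  scaf_len <- nchar(seqs)
  contig_pieces <- strsplit(seqs, sprintf("N{%d,}", n_split))
  contig_len <- nchar(unlist(contig_pieces, use.names = FALSE))
  contig_len <- contig_len[contig_len > 0]
  base_tab <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seqs),
                                          c("A", "C", "G", "T", "N"))
  totals <- colSums(base_tab)
  acgt <- sum(totals[c("A", "C", "G", "T")])
  n50_s <- nx_metric(scaf_len); n50_c <- nx_metric(contig_len)
  G <- genome_size_estimate
  have_G <- !is.null(G) && is.finite(G) && G > 0
  ng_s <- if (have_G) ngx_metric(scaf_len, G) else list(NGx = NA_real_, LGx = NA_integer_)
  ng_c <- if (have_G) ngx_metric(contig_len, G) else list(NGx = NA_real_, LGx = NA_integer_)
  pct_ge <- function(L) {
    if (!have_G) return(NA_real_)
    100 * sum(as.numeric(scaf_len[scaf_len >= L])) / G
  }
  structure(list(
    n_scaffolds = length(scaf_len),
    n_contigs = length(contig_len),
    total_scaffold_length = sum(as.numeric(scaf_len)),
    total_contig_length = sum(as.numeric(contig_len)),
    longest_scaffold = max(scaf_len),
    longest_contig = max(contig_len),
    N50_scaffold = n50_s$Nx, L50_scaffold = n50_s$Lx,
    N50_contig = n50_c$Nx, L50_contig = n50_c$Lx,
    NG50_scaffold = ng_s$NGx, NG50_contig = ng_c$NGx,
    gc = 100 * sum(totals[c("C", "G")]) / acgt,
    n_content = 100 * totals[["N"]] / sum(totals),
    contigs_over_10kb = sum(contig_len > 10000),
    pct_genome_in_scaffolds_ge_7kb = pct_ge(gene_sizes[["invertebrate"]]),
    pct_genome_in_scaffolds_ge_25kb = pct_ge(gene_sizes[["vertebrate"]]),
    genome_size_estimate = if (have_G) G else NA_real_
  ), class = "assembly_metrics")
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat("assembly_metrics:\n")
  for (nm in names(x))
    cat(sprintf("  %-32s %s\n", nm, format(x[[nm]], big.mark = ",")))
  invisible(x)
}

#' Mean gene length from GFF3 annotations
#'
#' Mean of `end - start + 1` (1-based inclusive coordinates) over features of
#' the requested type.
#'
#' @param annotations path to a GFF3 file, a `GRanges`, or a data.frame with
#'   `type`, `start`, `end` columns.
#' @param feature_type feature type to average (default `"gene"`).
#' @param round_to_kb round the result to the nearest kilobase.
#' @return mean length in bases.
#' @export
mean_gene_length <- function(annotations, feature_type = "gene",
                             round_to_kb = FALSE) {
  if (is.character(annotations) && length(annotations) == 1) {
    gr <- rtracklayer::import(annotations, format = "gff3")
    widths <- BiocGenerics::width(gr)[as.character(gr$type) == feature_type]
  } else if (is.data.frame(annotations)) {
    sub <- annotations[annotations$type == feature_type, , drop = FALSE]
    widths <- sub$end - sub$start + 1
  } else {
    widths <- BiocGenerics::width(annotations)[
      as.character(annotations$type) == feature_type]
  }
  if (length(widths) == 0)
    abort_validation("no feature of type '", feature_type, "' found")
  m <- mean(widths)
  if (round_to_kb) m <- round(m / 1000) * 1000
  m
}

#' Marker recovery: a completeness proxy
#'
#' Scores each marker sequence against the assembly by canonical k-mer
#' containment: a marker is `complete` when a single scaffold contains at
#' least `complete_threshold` of the marker's distinct canonical k-mers,
#' `fragmented` when the union over scaffolds does but no single scaffold,
#' and `missing` otherwise.
#'
#' @param markers named character vector of marker sequences.
#' @param scaffolds named character vector of assembly scaffolds.
#' @param k k-mer size.
#' @param complete_threshold containment fraction required, in (0, 1\].
#' @return a `marker_recovery` list with `n_complete`, `n_fragmented`,
#'   `n_missing`, and a `status` data.frame per marker.
#' @export
marker_recovery <- function(markers, scaffolds, k = 21,
                            complete_threshold = 0.9) {
  if (length(markers) == 0)
    abort_validation("markers must be non-empty")
  check_scalar(complete_threshold, "complete_threshold", min = 1e-12, max = 1)
  scaf_codes <- lapply(scaffolds, function(s) {
    codes <- cpp_kmer_codes(s, as.integer(k))
    sort(unique(codes[!is.na(codes)]))
  })
  status <- vapply(markers, function(m) {
    codes <- cpp_kmer_codes(m, as.integer(k))
    codes <- unique(codes[!is.na(codes)])
    if (length(codes) == 0) return("missing")
    per_scaf_hits <- vapply(scaf_codes, function(sc) {
      sum(cpp_lookup_codes(sc, rep(1L, length(sc)), codes) > 0)
    }, numeric(1))
    n <- length(codes)
    if (any(per_scaf_hits >= complete_threshold * n)) return("complete")
    union_hit <- sum(Reduce(`|`, lapply(scaf_codes, function(sc)
      cpp_lookup_codes(sc, rep(1L, length(sc)), codes) > 0)))
    if (union_hit >= complete_threshold * n) "fragmented" else "missing"
  }, character(1))
  structure(list(
    n_complete = sum(status == "complete"),
    n_fragmented = sum(status == "fragmented"),
    n_missing = sum(status == "missing"),
    status = data.frame(marker = names(markers), status = unname(status),
                        stringsAsFactors = FALSE)
  ), class = "marker_recovery")
}

#' @export
print.marker_recovery <- function(x, ...) {
  cat(sprintf("marker_recovery: %d complete, %d fragmented, %d missing (of %d)\n",
              x$n_complete, x$n_fragmented, x$n_missing, nrow(x$status)))
  invisible(x)
}
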