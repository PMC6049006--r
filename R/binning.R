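# canonical tetranucleotide classes: 136 = (256 - 16)/2 + 16 after
# reverse-complement collapsing (16 palindromes stand alone)
tnf_universe <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      all4 <- do.call(paste0, expand.grid(BASES, BASES, BASES, BASES,
                                          stringsAsFactors = FALSE)[, 4:1])
      codes <- vapply(all4, function(s) cpp_kmer_codes(s, 4L)[1], numeric(1))
      u <- sort(unique(codes))
      cache <<- list(codes = u, labels = cpp_decode_kmers(u, 4L))
    }
    cache
  }
})

#' Canonical tetranucleotide frequency vector
#'
#' Counts every 4-base window (windows containing non-ACGT symbols are
#' skipped), collapses each window with its reverse complement (136 canonical
#' classes), and normalizes to sum 1.
#'
#' @param sequence a DNA string with at least one valid 4-base window.
#' @return named numeric vector of length 136 summing to 1.
#' @export
tnf_vector <- function(sequence) {
  uni <- tnf_universe()
  codes <- cpp_kmer_codes(sequence, 4L)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0)
    abort_validation("sequence too short/ambiguous: no valid tetranucleotide window")
  counts <- tabulate(match(codes, uni$codes), nbins = length(uni$codes))
  setNames(counts / sum(counts), uni$labels)
}

#' Build contig records with composition features
#'
#' @param sequences named character vector of contig sequences; headers may
#'   carry `|genome=` truth labels (see [parse_contig_labels()]).
#' @param truth optional named character vector of truth labels by contig id,
#'   overriding header labels.
#' @return a `contig_set`: list with `id`, `length`, `gc`, `truth`, the
#'   sequences, and a contigs x 136 `tnf` matrix.
#' @export
contig_set <- function(sequences, truth = NULL) {
  if (length(sequences) == 0)
    return(structure(list(id = character(0), sequence = character(0),
                          length = integer(0), gc = numeric(0),
                          truth = character(0),
                          tnf = matrix(0, 0, 136)), class = "contig_set"))
  if (is.null(names(sequences)) || any(names(sequences) == ""))
    abort_validation("contig sequences must be named")
  lab <- parse_contig_labels(names(sequences))
  if (!is.null(truth)) {
    lab$genome_id <- unname(truth[lab$contig_id])
  }
  tnf <- t(vapply(sequences, tnf_vector, numeric(136)))
  rownames(tnf) <- lab$contig_id
  structure(list(
    id = lab$contig_id,
    sequence = unname(sequences),
    length = unname(nchar(sequences)),
    gc = gc_fraction(sequences),
    truth = lab$genome_id,
    tnf = tnf
  ), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, %.0f bases, GC %.1f%%\n",
              length(x$id), sum(as.numeric(x$length)),
              100 * sum(x$gc * x$length) / sum(x$length)))
  invisible(x)
}

#' Per-contig depth from read k-mer counts
#'
#' Alignment-free coverage: the median, over the contig's k-mer positions, of
#' the read-set occurrence count of the canonical k-mer at that position.
#'
#' @param contigs a `contig_set` or named character vector of sequences.
#' @param read_kmers a `kmer_table` built from the read set.
#' @return named numeric vector of depths (0 for contigs absent from reads).
#' @export
contig_depth_from_kmers <- function(contigs, read_kmers) {
  if (inherits(contigs, "contig_set")) {
    seqs <- setNames(contigs$sequence, contigs$id)
  } else seqs <- contigs
  vapply(seqs, function(s) {
    counts <- kmer_position_counts(read_kmers, s)
    counts <- counts[!is.na(counts)]
    if (length(counts) == 0) return(0)
    median(counts)
  }, numeric(1))
}

#' Bin contigs by tetranucleotide composition and abundance
#'
#' Pairwise contig distance
#' `d(i,j) = w * ||tnf_i - tnf_j||_2 +
#'   (1 - w) * |log10(depth_i + 1) - log10(depth_j + 1)| / normalizer`
#' with `normalizer = log10(max depth + 1)`. Contigs with `d <= tau` are
#' linked; connected components form bins (single linkage), and components
#' whose total length falls below `min_bin_size` are left unbinned. The
#' procedure is deterministic given its inputs.
#'
#' @param contigs a `contig_set`.
#' @param depths named numeric vector of mean depths by contig id (first
#'   column of a multi-sample profile is used if a matrix).
#' @param w composition weight in \[0, 1\].
#' @param tau link threshold.
#' @param min_bin_size minimum bin length in bases.
#' @param min_contig_length contigs shorter than this are left unbinned.
#' @return a `binning_result`: list with `bins` (data.frame `bin_id`,
#'   `n_contigs`, `total_length`, `mean_gc`, `mean_depth`), `membership`
#'   (named character, NA = unbinned), `unbinned` ids, and a `params` echo.
#' @export
bin_contigs <- function(contigs, depths, w = 0.7, tau = 0.025,
                        min_bin_size = 20000, min_contig_length = 2000) {
  check_scalar(w, "w", min = 0, max = 1)
  check_scalar(tau, "tau", min = 0)
  check_scalar(min_bin_size, "min_bin_size", min = 0)
  params <- list(w = w, tau = tau, min_bin_size = min_bin_size,
                 min_contig_length = min_contig_length)
  if (length(contigs$id) == 0) {
    return(structure(list(bins = data.frame(), membership = character(0),
                          unbinned = character(0), params = params),
                     class = "binning_result"))
  }
  if (is.matrix(depths)) depths <- depths[, 1]
  d_vec <- depths[contigs$id]
  if (any(is.na(d_vec)))
    abort_validation("every contig needs a depth entry")

  eligible <- contigs$length >= min_contig_length
  membership <- setNames(rep(NA_character_, length(contigs$id)), contigs$id)
  if (any(eligible)) {
    idx <- which(eligible)
    tnf_d <- as.matrix(stats::dist(contigs$tnf[idx, , drop = FALSE]))
    ld <- log10(d_vec[idx] + 1)
    norm <- max(log10(max(d_vec[idx]) + 1), 1e-9)
    dep_d <- abs(outer(ld, ld, "-")) / norm
    d <- w * tnf_d + (1 - w) * dep_d
    adj <- d <= tau
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
    comp_len <- tapply(contigs$length[idx], comp, sum)
    big <- names(comp_len)[comp_len >= min_bin_size]
    # stable bin ids: by decreasing total length, ties by first contig
    big <- big[order(-comp_len[big], as.integer(big))]
    for (bi in seq_along(big)) {
      members <- idx[comp == as.integer(big[bi])]
      membership[members] <- sprintf("bin%03d", bi)
    }
  }
  binned <- !is.na(membership)
  if (any(binned)) {
    sp <- split(which(binned), membership[binned])
    bins <- do.call(rbind, lapply(names(sp), function(b) {
      i <- sp[[b]]
      len <- as.numeric(contigs$length[i])
      data.frame(bin_id = b, n_contigs = length(i), total_length = sum(len),
                 mean_gc = sum(contigs$gc[i] * len) / sum(len),
                 mean_depth = sum(d_vec[i] * len) / sum(len),
                 stringsAsFactors = FALSE)
    }))
    bins <- bins[order(bins$bin_id), , drop = FALSE]
    rownames(bins) <- NULL
  } else bins <- data.frame()
  structure(list(bins = bins, membership = membership,
                 unbinned = names(membership)[!binned], params = params),
            class = "binning_result")
}

#' @export
print.binning_result <- function(x, ...) {
  cat(sprintf("binning_result: %d bins, %d contigs binned, %d unbinned\n",
              nrow(x$bins), sum(!is.na(x$membership)), length(x$unbinned)))
  if (nrow(x$bins) > 0) print(x$bins)
  invisible(x)
}

#' Evaluate bins against truth labels
#'
#' For each bin: the majority truth label by length, precision (fraction of
#' the bin's length carrying the majority label), recall (fraction of that
#' genome's total contig length captured by the bin), and their harmonic mean
#' F1.
#'
#' @param result a `binning_result`.
#' @param contigs the `contig_set` that was binned (its `truth` labels and
#'   lengths are used).
#' @return data.frame with `bin_id`, `majority_label`, `precision`, `recall`,
#'   `f1`.
#' @export
evaluate_bins <- function(result, contigs) {
  if (any(is.na(contigs$truth)))
    abort_validation("every contig needs a truth label")
  genome_len <- tapply(as.numeric(contigs$length), contigs$truth, sum)
  mem <- result$membership[contigs$id]
  rows <- lapply(sort(unique(mem[!is.na(mem)])), function(b) {
    i <- which(!is.na(mem) & mem == b)
    len_by_label <- tapply(as.numeric(contigs$length[i]), contigs$truth[i], sum)
    maj <- names(len_by_label)[which.max(len_by_label)]
    precision <- len_by_label[[maj]] / sum(len_by_label)
    recall <- len_by_label[[maj]] / genome_len[[maj]]
    data.frame(bin_id = b, majority_label = maj, precision = precision,
               recall = recall, f1 = 2 * precision * recall / (precision + recall),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bin_id = character(0), majority_label = character(0),
                      precision = numeric(0), recall = numeric(0),
                      f1 = numeric(0))
  rownames(out) <- NULL
  out
}

#' Select host bins
#'
#' Truth mode returns bins whose majority truth label is the designated
#' host. Heuristic mode returns the largest bin plus every bin whose mean GC
#' lies within `gc_window` percentage points and whose mean depth lies within
#' a factor `depth_factor` of the largest bin's.
#'
#' @param result a `binning_result`.
#' @param mode `"truth"` or `"heuristic"`.
#' @param host_label the host genome id (truth mode).
#' @param evaluation result of [evaluate_bins()] (truth mode).
#' @param gc_window GC tolerance in percentage points (heuristic mode).
#' @param depth_factor maximum depth ratio to the largest bin (heuristic
#'   mode).
#' @return character vector of bin ids (possibly empty).
#' @export
select_host_bins <- function(result, mode = c("truth", "heuristic"),
                             host_label = NULL, evaluation = NULL,
                             gc_window = 3, depth_factor = 2) {
  mode <- match.arg(mode)
  if (nrow(result$bins) == 0) return(character(0))
  if (mode == "truth") {
    if (is.null(evaluation) || is.null(host_label))
      abort_validation("truth mode needs `evaluation` and `host_label`")
    return(evaluation$bin_id[evaluation$majority_label == host_label])
  }
  bins <- result$bins
  top <- bins[which.max(bins$total_length), ]
  keep <- abs(bins$mean_gc - top$mean_gc) * 100 <= gc_window &
    pmax(bins$mean_depth, 1e-9) / pmax(top$mean_depth, 1e-9) <= depth_factor &
    pmax(top$mean_depth, 1e-9) / pmax(bins$mean_depth, 1e-9) <= depth_factor
  sort(unique(c(top$bin_id, bins$bin_id[keep])))
}

#' Recruit reads to host bins by shared k-mers
#'
#' A read is recruited when at least a fraction `theta` of its canonical
#' k-mers occurs in the k-mer set of the host bin sequences. Read pairs
#' (ids ending in `/1` and `/2`) are recruited jointly when either mate
#' qualifies, mirroring mate rescue in read mappers.
#'
#' @param reads data.frame with `id`, `seq` (and optionally `qual`).
#' @param host_sequences character vector of host bin contig sequences.
#' @param k k-mer size for the shared-k-mer test.
#' @param theta shared-k-mer fraction threshold in (0, 1\].
#' @return list with `host` and `other` (subsets of `reads`) and `stats`
#'   (counts and fractions).
#' @export
recruit_reads <- function(reads, host_sequences, k = 21, theta = 0.5) {
  check_scalar(theta, "theta", min = 1e-12, max = 1)
  if (length(host_sequences) == 0 || sum(nchar(host_sequences)) == 0)
    abort_validation("host bin sequence set is empty")
  host_tab <- count_kmers(host_sequences, k)
  frac <- cpp_shared_kmer_fraction(reads$seq, as.integer(k), host_tab$codes)
  hit <- !is.na(frac) & frac >= theta
  pair_key <- sub("/[12]$", "", reads$id)
  hit <- as.logical(ave(hit, pair_key, FUN = any))
  stats <- list(n_reads = nrow(reads), n_host = sum(hit),
                n_other = sum(!hit), host_fraction = mean(hit),
                k = k, theta = theta)
  list(host = reads[hit, , drop = FALSE],
       other = reads[!hit, , drop = FALSE],
       stats = stats)
}
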