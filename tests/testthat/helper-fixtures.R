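# i.i.d. random DNA string
rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# kmer_histogram from a vector of per-k-mer depths
hist_from_depths <- function(depths, k = 21L) {
  depths <- depths[depths > 0]
  tab <- table(depths)
  kmer_histogram(as.integer(names(tab)), as.numeric(tab), k = k)
}

# string reverse complement without Biostrings (independent of the package)
rc_naive <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
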