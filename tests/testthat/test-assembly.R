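brute_nx <- function(lengths, x) {
  s <- unname(sort(lengths, decreasing = TRUE))
  cum <- 0
  for (i in seq_along(s)) {
    cum <- cum + s[i]
    if (cum >= x / 100 * sum(s)) return(list(Nx = s[i], Lx = i))
  }
}

test_that("Nx and NGx match worked examples and a brute-force scan", {
  expect_equal(nx_metric(c(10, 8, 6, 4, 2), 50), list(Nx = 8, Lx = 2))
  expect_equal(nx_metric(42), list(Nx = 42, Lx = 1))
  expect_error(nx_metric(numeric(0)), "non-empty")

  expect_equal(ngx_metric(c(10, 8, 6, 4, 2), 40)$NGx, 6)
  expect_true(is.na(ngx_metric(c(2), 40)$NGx))

  set.seed(71)
  for (i in 1:200) {
    lens <- sample(1:5000, sample(1:60, 1), replace = TRUE)
    x <- sample(c(25, 50, 75, 90), 1)
    expect_equal(nx_metric(lens, x), brute_nx(lens, x))
    # NGx == Nx when the genome size equals the assembly span
    expect_equal(ngx_metric(lens, sum(lens), x)$NGx, nx_metric(lens, x)$Nx)
  }
})

test_that("assembly metrics split at N runs and compute composition", {
  m <- assembly_metrics(c(s1 = strrep("ACGT", 25)), genome_size_estimate = 200)
  expect_equal(m$n_scaffolds, 1)
  expect_equal(m$n_contigs, 1)
  expect_equal(m$gc, 50)
  expect_equal(m$pct_genome_in_scaffolds_ge_7kb, 0)

  scaf <- paste0(rand_dna(5000), strrep("N", 10), rand_dna(3000))
  m2 <- assembly_metrics(c(s = scaf))
  expect_equal(m2$n_contigs, 2)
  expect_equal(m2$longest_contig, 5000)
  # a 9-N run does not split
  scaf9 <- paste0(rand_dna(5000), strrep("N", 9), rand_dna(3000))
  expect_equal(assembly_metrics(c(s = scaf9))$n_contigs, 1)
  # non-ACGTN symbols count as N
  expect_equal(assembly_metrics(c(s = "ACGTRYACGT"))$n_content, 20)

  # field-by-field recount on random fragmented assemblies
  set.seed(72)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    scafs <- vapply(seq_len(n), function(j) {
      pieces <- replicate(sample(1:4, 1), rand_dna(sample(200:2000, 1)))
      paste(pieces, collapse = strrep("N", sample(c(5, 10, 25), 1)))
    }, character(1))
    names(scafs) <- sprintf("s%02d", seq_len(n))
    G <- sum(nchar(scafs))
    m <- assembly_metrics(scafs, genome_size_estimate = G)
    expect_equal(m$n_scaffolds, n)
    contig_lens <- nchar(unlist(strsplit(scafs, "N{10,}")))
    contig_lens <- contig_lens[contig_lens > 0]
    expect_equal(m$n_contigs, length(contig_lens))
    expect_equal(m$total_contig_length, sum(contig_lens))
    expect_equal(m$N50_contig, brute_nx(contig_lens, 50)$Nx)
    expect_equal(m$N50_scaffold, brute_nx(nchar(scafs), 50)$Nx)
    ch <- strsplit(paste(scafs, collapse = ""), "")[[1]]
    expect_equal(m$gc, 100 * sum(ch %in% c("G", "C")) / sum(ch != "N"))
    expect_equal(m$n_content, 100 * mean(ch == "N"))
    expect_equal(m$pct_genome_in_scaffolds_ge_7kb,
                 100 * sum(nchar(scafs)[nchar(scafs) >= 7000]) / G)
  }
})

test_that("usefulness and contiguity decouple for gene-sized scaffolds", {
  # 30 scaffolds of exactly 7 kb: no contig clears 10 kb, yet every base
  # counts toward the >= 7 kb usefulness share
  scafs <- setNames(replicate(30, rand_dna(7000)), sprintf("s%02d", 1:30))
  m <- assembly_metrics(scafs, genome_size_estimate = 30 * 7000)
  expect_equal(m$contigs_over_10kb, 0)
  expect_equal(m$pct_genome_in_scaffolds_ge_7kb, 100)
  expect_equal(m$pct_genome_in_scaffolds_ge_25kb, 0)
})

test_that("mean gene length follows 1-based inclusive coordinates", {
  df <- data.frame(type = c("gene", "gene", "mRNA"),
                   start = c(1, 1001, 1), end = c(5000, 9999 + 1, 200))
  expect_equal(mean_gene_length(df), mean(c(5000, 9000)))
  expect_equal(mean_gene_length(data.frame(type = "gene", start = 100,
                                           end = 199)), 100)
  expect_error(mean_gene_length(df, feature_type = "tRNA"), "no feature")

  # GFF3 round trip through the standard reader
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1\t5000\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t6001\t15000\t.\t-\t.\tID=g2"), gff)
  expect_equal(mean_gene_length(gff), 7000)
  expect_equal(mean_gene_length(gff, round_to_kb = TRUE), 7000)

  # custom usefulness thresholds (e.g., the 25 kb vertebrate average)
  scafs <- c(s1 = rand_dna(30000), s2 = rand_dna(8000))
  m <- assembly_metrics(scafs, genome_size_estimate = 38000,
                        gene_sizes = c(invertebrate = 7000,
                                       vertebrate = 25000))
  expect_equal(m$pct_genome_in_scaffolds_ge_25kb, 100 * 30000 / 38000)
})

test_that("marker recovery classifies complete, fragmented, and missing", {
  genome <- rand_dna(50000)
  scafs <- c(s1 = substr(genome, 1, 30000), s2 = substr(genome, 30001, 50000))
  markers <- c(
    m_complete = substr(genome, 1000, 1600),
    m_fragmented = substr(genome, 29750, 30350),  # spans the s1/s2 junction
    m_missing = rand_dna(600))
  mr <- marker_recovery(markers, scafs, k = 21, complete_threshold = 0.9)
  expect_equal(mr$status$status,
               c("complete", "fragmented", "missing"))

  # assembly missing 10% of the genome loses about 10% of markers
  set.seed(73)
  genome2 <- rand_dna(200000)
  starts <- round(seq(1, 198500, length.out = 200))
  mk <- vapply(starts, function(s) substr(genome2, s, s + 700), character(1))
  names(mk) <- sprintf("m%03d", seq_along(mk))
  assembly <- c(part = substr(genome2, 1, 180000))  # 90% of the genome
  mr2 <- marker_recovery(mk, assembly, k = 21)
  expect_lt(abs(mr2$n_missing / length(mk) - 0.10), 0.05)
})
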