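test_that("tetranucleotide vectors match brute-force enumeration", {
  v <- tnf_vector("AAAA")
  expect_equal(sum(v), 1)
  expect_equal(unname(v["AAAA"]), 1)
  expect_equal(sum(v > 0), 1)

  # ACGTACGT: windows ACGT, CGTA, GTAC, TACG, ACGT; TACG collapses to CGTA
  v2 <- tnf_vector("ACGTACGT")
  expect_equal(unname(v2["ACGT"]), 2 / 5)
  expect_equal(unname(v2["CGTA"]), 2 / 5)
  expect_equal(unname(v2["GTAC"]), 1 / 5)

  # strand symmetry on random sequences, against a brute-force recount
  set.seed(61)
  for (i in 1:20) {
    s <- rand_dna(sample(100:400, 1), gc = runif(1, 0.3, 0.7))
    expect_equal(tnf_vector(s), tnf_vector(rc_naive(s)))
    # brute force: count windows, merging each with its reverse complement
    wins <- substring(s, 1:(nchar(s) - 3), 4:nchar(s))
    canon <- pmin(wins, vapply(wins, rc_naive, character(1)))
    brute <- table(canon) / length(canon)
    v <- tnf_vector(s)
    expect_equal(v[names(brute)], as.numeric(brute)[seq_along(brute)],
                 ignore_attr = TRUE)
    expect_equal(sum(v[setdiff(names(v), names(brute))]), 0)
  }

  expect_error(tnf_vector("NNNNNN"), "too short/ambiguous")
  expect_error(tnf_vector("ACG"), "too short/ambiguous")
})

test_that("k-mer median depth tracks planted coverage", {
  contig <- rand_dna(2000)
  reads30 <- rep(contig, 30)
  tab <- count_kmers(reads30, 21)
  expect_equal(unname(contig_depth_from_kmers(c(c1 = contig), tab)), 30)
  absent <- rand_dna(2000)
  expect_equal(unname(contig_depth_from_kmers(c(c2 = absent), tab)), 0)

  # simulated community: estimated depth within 15% of planted k-mer depth
  g <- rand_dna(100000, gc = 0.45)
  m <- list(list(genome_id = "g", sequences = g, mean_depth = 40))
  rr <- simulate_reads(m, read_length = 250, error_rate = 0, paired = FALSE,
                       seed = 62)
  frag <- fragment_genomes(list(g = g), target_n50 = 8000, min_length = 5000,
                           seed = 63)
  dep <- contig_depth_from_kmers(contig_set(frag$contigs),
                                 count_kmers(rr$reads$seq, 21))
  expect_true(all(abs(dep - 40) / 40 < 0.15))
})

test_that("binning partitions contigs and keeps clean communities apart", {
  # single long contig forms its own bin
  cs1 <- contig_set(c("c1|genome=g" = rand_dna(30000)))
  r1 <- bin_contigs(cs1, c(c1 = 10), min_bin_size = 20000)
  expect_equal(nrow(r1$bins), 1)
  expect_equal(unname(r1$membership["c1"]), "bin001")

  # identical sequences at identical depth share a bin
  s <- rand_dna(25000)
  cs2 <- contig_set(c(a = s, b = s, d = s))
  r2 <- bin_contigs(cs2, c(a = 10, b = 10, d = 10), min_bin_size = 1000)
  expect_equal(length(unique(r2$membership)), 1)

  # empty input
  r0 <- bin_contigs(contig_set(character(0)), numeric(0))
  expect_equal(nrow(r0$bins), 0)

  # partition invariant on a two-genome community
  g1 <- holobinr:::random_markov_dna(150000, 0.35)
  g2 <- holobinr:::random_markov_dna(100000, 0.55)
  frag <- fragment_genomes(list(g1 = g1, g2 = g2), target_n50 = 6000,
                           min_length = 2500, seed = 64)
  cs <- contig_set(frag$contigs)
  depths <- setNames(ifelse(cs$truth == "g1", 70, 20), cs$id)
  res <- bin_contigs(cs, depths, min_bin_size = 20000)
  expect_setequal(c(names(res$membership)[!is.na(res$membership)],
                    res$unbinned), cs$id)
  ev <- evaluate_bins(res, cs)
  expect_true(all(ev$f1 > 0.95))

  # label invariance: renaming ids permutes but preserves structure
  ren <- setNames(cs$sequence, sprintf("x%03d|genome=%s",
                                       seq_along(cs$id), cs$truth))
  cs_ren <- contig_set(ren)
  res_ren <- bin_contigs(cs_ren, setNames(unname(depths), cs_ren$id),
                         min_bin_size = 20000)
  old_part <- split(seq_along(cs$id), res$membership[cs$id])
  new_part <- split(seq_along(cs_ren$id), res_ren$membership[cs_ren$id])
  expect_equal(lapply(old_part, sort), lapply(new_part, sort),
               ignore_attr = TRUE)

  # raising tau never increases the number of connected components
  n_comp <- vapply(c(0.005, 0.02, 0.05, 0.2), function(tau) {
    r <- bin_contigs(cs, depths, tau = tau, min_bin_size = 0,
                     min_contig_length = 0)
    nrow(r$bins)
  }, numeric(1))
  expect_false(is.unsorted(rev(n_comp)))
})

test_that("binning accuracy is non-decreasing in GC separation", {
  set.seed(65)
  f1_at_gap <- vapply(c(5, 10, 20), function(gap) {
    g_host <- holobinr:::random_markov_dna(120000, 0.40)
    g_sym <- holobinr:::random_markov_dna(80000, 0.40 + gap / 100)
    frag <- fragment_genomes(list(host = g_host, sym = g_sym),
                             target_n50 = 6000, min_length = 2500, seed = 66)
    cs <- contig_set(frag$contigs)
    depths <- setNames(ifelse(cs$truth == "host", 70, 20), cs$id)
    res <- bin_contigs(cs, depths, min_bin_size = 20000)
    ev <- evaluate_bins(res, cs)
    hostr <- ev[ev$majority_label == "host", ]
    if (nrow(hostr) == 0) 0 else max(hostr$f1)
  }, numeric(1))
  expect_false(is.unsorted(f1_at_gap - 1e-9))
  expect_gt(f1_at_gap[3], 0.95)
})

test_that("bin evaluation computes length-weighted precision and recall", {
  # perfect bins
  s <- c("a|genome=A" = rand_dna(5000), "b|genome=B" = rand_dna(5000))
  cs <- contig_set(s)
  res <- bin_contigs(cs, c(a = 10, b = 50), tau = 0.001, min_bin_size = 0,
                     min_contig_length = 0)
  ev <- evaluate_bins(res, cs)
  expect_true(all(ev$precision == 1 & ev$recall == 1 & ev$f1 == 1))

  # hand-built 80/20 bin: A has 100 kb total, bin holds 80 kb A + 20 kb B
  cs2 <- contig_set(c("a1|genome=A" = rand_dna(80000),
                      "a2|genome=A" = rand_dna(20000),
                      "b1|genome=B" = rand_dna(20000)))
  fake <- structure(list(
    membership = c(a1 = "bin001", a2 = NA, b1 = "bin001"),
    bins = data.frame(bin_id = "bin001"), unbinned = "a2",
    params = list()), class = "binning_result")
  ev2 <- evaluate_bins(fake, cs2)
  expect_equal(ev2$precision, 0.8)
  expect_equal(ev2$recall, 0.8)
  expect_equal(ev2$f1, 0.8)

  # random assignment of two equal genomes: precision near 0.5
  set.seed(67)
  prec <- replicate(20, {
    cs3 <- contig_set(setNames(
      replicate(60, rand_dna(1000)),
      sprintf("c%02d|genome=%s", 1:60, rep(c("A", "B"), each = 30))))
    fake3 <- structure(list(
      membership = setNames(sample(c("bin001", "bin002"), 60, replace = TRUE),
                            cs3$id),
      bins = data.frame(bin_id = c("bin001", "bin002")),
      unbinned = character(0), params = list()), class = "binning_result")
    mean(evaluate_bins(fake3, cs3)$precision)
  })
  expect_lt(abs(mean(prec) - 0.5), 0.1)
})

test_that("host bin selection works in truth and heuristic modes", {
  s <- c("a|genome=host" = rand_dna(30000))
  cs <- contig_set(s)
  res <- bin_contigs(cs, c(a = 50), min_bin_size = 0, min_contig_length = 0)
  ev <- evaluate_bins(res, cs)
  expect_equal(select_host_bins(res, "truth", host_label = "host",
                                evaluation = ev), "bin001")
  expect_equal(select_host_bins(res, "heuristic"), "bin001")

  # three similar host bins plus one distant symbiont bin
  bins <- data.frame(
    bin_id = c("bin001", "bin002", "bin003", "bin004"),
    n_contigs = c(10, 5, 4, 8),
    total_length = c(300000, 120000, 100000, 150000),
    mean_gc = c(0.40, 0.41, 0.39, 0.62),
    mean_depth = c(70, 65, 80, 20), stringsAsFactors = FALSE)
  fake <- structure(list(bins = bins, membership = character(0),
                         unbinned = character(0), params = list()),
                    class = "binning_result")
  expect_setequal(select_host_bins(fake, "heuristic"),
                  c("bin001", "bin002", "bin003"))

  empty <- structure(list(bins = data.frame(), membership = character(0),
                          unbinned = character(0), params = list()),
                     class = "binning_result")
  expect_length(select_host_bins(empty, "heuristic"), 0)
})

test_that("read recruitment honors theta, pairs, and monotonicity", {
  host <- rand_dna(20000)
  other <- rand_dna(20000)
  reads <- data.frame(
    id = c("h1", "h2", "o1"),
    seq = c(substr(host, 101, 250), substr(host, 5001, 5150),
            substr(other, 101, 250)),
    qual = strrep("I", 150), stringsAsFactors = FALSE)
  rec <- recruit_reads(reads, host, k = 21, theta = 1)
  expect_setequal(rec$host$id, c("h1", "h2"))
  expect_equal(rec$other$id, "o1")
  expect_error(recruit_reads(reads, character(0)), "empty")

  # pair rescue: a garbage mate rides along with its recruited partner
  pr <- data.frame(id = c("p1/1", "p1/2"),
                   seq = c(substr(host, 301, 450), rand_dna(150)),
                   qual = strrep("I", 150), stringsAsFactors = FALSE)
  rec2 <- recruit_reads(pr, host, k = 21, theta = 0.9)
  expect_setequal(rec2$host$id, c("p1/1", "p1/2"))

  # recruited set shrinks weakly as theta rises
  set.seed(68)
  noisy <- vapply(1:40, function(i) {
    s <- substr(host, i * 100, i * 100 + 149)
    holobinr:::substitute_bases(s, sample(150, sample(0:30, 1)))
  }, character(1))
  rds <- data.frame(id = sprintf("r%02d", 1:40), seq = noisy,
                    qual = strrep("I", 150), stringsAsFactors = FALSE)
  sizes <- vapply(c(0.2, 0.5, 0.8, 1), function(th)
    nrow(recruit_reads(rds, host, k = 21, theta = th)$host), numeric(1))
  expect_false(is.unsorted(rev(sizes)))
})
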