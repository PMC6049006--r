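test_that("peak detection resolves diploid and unimodal spectra", {
  set.seed(51)
  # diploid recipe: het component at mean 32, hom at 64, plus an error spike
  depths <- c(rnbinom(1e5, mu = 32, size = 40),
              rnbinom(round(1e5 * 0.55), mu = 64, size = 40))
  cnt <- tabulate(depths)
  cnt[1:10] <- cnt[1:10] + round(3e5 * exp(-(1:10)))
  h <- kmer_histogram(which(cnt > 0), cnt[cnt > 0], k = 21)
  pk <- detect_peaks(h)
  expect_gte(pk$e, 5); expect_lte(pk$e, 15)
  expect_gte(pk$lambda, 30); expect_lte(pk$lambda, 34)
  expect_gte(pk$c_hom, 60); expect_lte(pk$c_hom, 68)
  expect_false(pk$unimodal)

  # single peak: reported as the homozygous depth, lambda at half
  set.seed(52)
  h1 <- hist_from_depths(rnbinom(1e5, mu = 40, size = 30))
  pk1 <- detect_peaks(h1)
  expect_true(pk1$unimodal)
  expect_gte(pk1$c_hom, 38); expect_lte(pk1$c_hom, 42)
  expect_gte(pk1$lambda, 19); expect_lte(pk1$lambda, 21)

  # pure error spectrum
  expect_error(detect_peaks(kmer_histogram(c(1L, 2L), c(1000, 200))),
               "no signal peak")
})

test_that("Lander-Waterman size follows its closed form", {
  expect_equal(waterman_size(kmer_histogram(10L, 100), e = 1, c_hom = 10), 100)
  # error mass below e is excluded
  expect_equal(waterman_size(kmer_histogram(c(1L, 10L), c(500, 100)),
                             e = 3, c_hom = 10), 100)
  expect_error(waterman_size(kmer_histogram(10L, 100), e = 1, c_hom = -1),
               "c_hom")
})

test_that("error and repeat fractions are the stated mass ratios", {
  h <- kmer_histogram(c(1L, 30L), c(1000, 100))
  expect_equal(error_fraction(h, 11), 1000 / 4000)
  expect_equal(error_fraction(h, 1), 0)

  h2 <- kmer_histogram(c(63L, 300L), c(900, 100))
  expect_equal(repeat_fraction(h2, e = 11, rho = 252), 30000 / 86700)
  expect_equal(repeat_cutoff(63), 252)

  # mass conservation: the three shares partition T
  set.seed(53)
  h3 <- hist_from_depths(sample(1:400, 2000, replace = TRUE))
  e <- 11; rho <- 252
  mid <- sum(as.numeric(h3$depth) * h3$count *
               (h3$depth >= e & h3$depth <= rho)) / hist_total(h3)
  filt <- 1 - error_fraction(h3, e)
  expect_equal(error_fraction(h3, e) + mid + repeat_fraction(h3, e, rho) * filt,
               1)
})

test_that("Poisson EM recovers mixture parameters with monotone likelihood", {
  set.seed(54)
  # single-component data: EM pushes all weight onto component 1 at lambda 20
  h <- hist_from_depths(rpois(1e5, 20))
  fit <- fit_poisson_em(h, e = 3, m = 2, init_lambda = 20)
  expect_lt(abs(fit$lambda - 20) / 20, 0.01)
  expect_lt(fit$weights[2], 0.05)
  expect_false(is.unsorted(fit$loglik - 1e-9))

  # three components, weights (0.4, 0.5, 0.1) at lambda 30
  set.seed(55)
  comp <- sample(1:3, 1e5, replace = TRUE, prob = c(0.4, 0.5, 0.1))
  h3 <- hist_from_depths(rpois(1e5, 30 * comp))
  fit3 <- fit_poisson_em(h3, e = 3, m = 3, init_lambda = 30)
  expect_lt(abs(fit3$lambda - 30) / 30, 0.02)
  expect_false(is.unsorted(fit3$loglik - 1e-9))

  # local optimality: converged log-likelihood is at least that of the
  # generating parameters
  ll_true <- sum(h3$count * log(0.4 * dpois(h3$depth, 30) +
                                  0.5 * dpois(h3$depth, 60) +
                                  0.1 * dpois(h3$depth, 90)))
  expect_gte(fit3$loglik[length(fit3$loglik)], ll_true - 1e-6)
})

test_that("NB mixture fit recovers depth, weights, and heterozygosity", {
  set.seed(56)
  n <- 1e5
  comp <- sample(1:2, n, replace = TRUE, prob = c(0.45, 0.55))
  h <- hist_from_depths(rnbinom(n, mu = 32 * comp, size = 40))
  fit <- fit_nb_mixture(h, e = 3, m = 2, init_lambda = 32)
  expect_lt(abs(fit$lambda - 32) / 32, 0.03)
  expect_lt(abs(fit$weights[1] - 0.45), 0.05)

  # closed-form heterozygosity conversions
  hw <- het_from_weights(c(0, 1), k = 21)
  expect_equal(hw$p_het, 0)
  expect_equal(hw$r, 0)
  p <- 0.1
  w1 <- 2 * p / (1 + p)   # weights giving p_het = 0.1
  hw2 <- het_from_weights(c(w1, 1 - w1), k = 21)
  expect_equal(hw2$p_het, 0.1, tolerance = 1e-12)
  expect_equal(hw2$r, 1 - 0.9^(1 / 21), tolerance = 1e-12)
})

test_that("the three estimators agree on error-free haploid simulations", {
  g <- rand_dna(200000, gc = 0.42)
  m <- list(list(genome_id = "g", sequences = g, mean_depth = 50))
  rr <- simulate_reads(m, read_length = 100, error_rate = 0, paired = FALSE,
                       seed = 57)
  h <- build_histogram(count_kmers(rr$reads$seq, 21))
  pk <- detect_peaks(h)
  G <- c(waterman = waterman_size(h, pk$e, pk$c_hom),
         poisson = fit_poisson_em(h, e = pk$e, m = 2,
                                  init_lambda = pk$lambda)$G,
         nb = fit_nb_mixture(h, e = pk$e, m = 2, init_lambda = pk$lambda)$G)
  expect_true(all(abs(G - 200000) / 200000 < 0.05))
  expect_lt(max(G) / min(G) - 1, 0.05)
})

test_that("consensus size is the median with permutation symmetry", {
  cons <- consensus_size(c(419.8, 404.7, 332.8))
  expect_equal(cons$median, 404.7)
  expect_equal(consensus_size(c(332.8, 419.8, 404.7))$median, 404.7)
  one <- consensus_size(42)
  expect_equal(one$median, 42)
  expect_equal(one$sd, 0)
  expect_true(one$single)
  expect_error(consensus_size(numeric(0)), "non-empty")
})

test_that("Kruskal-Wallis matches a brute-force rank implementation", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857143, tolerance = 1e-6)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$H, 0)
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2)))$p, 1)

  brute_H <- function(groups) {
    x <- unlist(groups)
    g <- rep(seq_along(groups), lengths(groups))
    r <- rank(x)
    N <- length(x)
    H <- 12 / (N * (N + 1)) *
      sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (N + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  set.seed(58)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(1:20, sample(3:10, 1), replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    expect_lt(abs(kruskal_wallis(groups)$H - brute_H(groups)), 1e-9)
  }
})

test_that("the feature-estimation wrapper summarizes across k sizes", {
  g <- rand_dna(100000)
  m <- list(list(genome_id = "g", sequences = g, mean_depth = 50))
  rr <- simulate_reads(m, read_length = 100, error_rate = 0, paired = FALSE,
                       seed = 59)
  hists <- lapply(c(17, 21), function(k) build_histogram(count_kmers(rr$reads$seq, k)))
  names(hists) <- c(17, 21)
  est <- estimate_genome_features(hists)
  expect_equal(nrow(est$table), 6)
  expect_equal(est$consensus_median, median(est$table$G))
  expect_true(all(c("by_method", "by_k") %in% names(est$comparison_stats)))
})
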