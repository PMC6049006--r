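#' Detect error valley and coverage peaks in a k-mer spectrum
#'
#' Works on the moving-average smoothed histogram laid out on a contiguous
#' depth grid. The error cutoff `e` is the depth of the minimum between depth
#' 1 and the first significant local maximum. The haploid-depth peak `lambda`
#' and homozygous peak `c_hom` are then assigned from the significant local
#' maxima: the tallest maximum is paired with a second maximum at roughly
#' twice (or half) its depth when one exists; otherwise the spectrum is
#' treated as single-peaked, the peak is reported as `c_hom`, and
#' `lambda = c_hom / 2` with `unimodal = TRUE`.
#'
#' @param hist a `kmer_histogram`.
#' @param smoothing_window odd moving-average window width (in depth units).
#' @param min_rel_height minimum height of a candidate peak, relative to the
#'   tallest smoothed value, for it to count as a real peak (guards against
#'   sparse noise maxima in the repeat tail).
#' @return list with `e`, `lambda`, `c_hom`, `unimodal`, and a `peaks`
#'   data.frame (`depth`, `height`) of significant maxima.
#' @export
detect_peaks <- function(hist, smoothing_window = 5, min_rel_height = 0.05) {
  check_scalar(smoothing_window, "smoothing_window", min = 1, integer = TRUE)
  if (smoothing_window %% 2 == 0)
    abort_validation("smoothing_window must be odd")
  if (length(hist$depth) == 0)
    abort_validation("histogram is empty")
  max_d <- max(hist$depth[hist$count > 0])
  if (max_d < 3)
    stop("no signal peak: all k-mer mass below depth 3 (pure error spectrum)")
  y <- numeric(max_d)
  y[hist$depth] <- hist$count
  # moving average with shrinking windows at the edges
  w <- smoothing_window %/% 2
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(max_d) - w, 1L)
  hi <- pmin(seq_len(max_d) + w, max_d)
  ys <- (cs[hi + 1] - cs[lo]) / (hi - lo + 1)

  is_max <- rep(FALSE, max_d)
  if (max_d >= 3) {
    i <- 2:(max_d - 1)
    is_max[i] <- ys[i] >= ys[i - 1] & ys[i] > ys[i + 1] & ys[i] > 0
  }
  cand <- which(is_max)
  if (length(cand) == 0)
    stop("no signal peak detected in k-mer spectrum")
  # significance is relative to the tallest interior maximum, not to the
  # monotone error spike at the low-depth boundary
  sig <- cand[ys[cand] >= min_rel_height * max(ys[cand])]

  first_peak <- sig[1]
  e <- which.min(ys[1:first_peak])
  sig <- sig[sig >= e]
  if (length(sig) == 0)
    stop("no signal peak at or above the error cutoff")
  p <- sig[which.max(ys[sig])]

  hom_cand <- sig[sig >= 1.6 * p & sig <= 2.4 * p]
  het_cand <- sig[sig >= p / 2.4 & sig <= p / 1.6]
  if (length(hom_cand) > 0) {
    lambda <- as.numeric(p)
    c_hom <- as.numeric(hom_cand[which.max(ys[hom_cand])])
    unimodal <- FALSE
  } else if (length(het_cand) > 0) {
    # the tallest peak is the homozygous one; its half-depth partner is the
    # heterozygous peak
    lambda <- as.numeric(het_cand[which.max(ys[het_cand])])
    c_hom <- as.numeric(p)
    unimodal <- FALSE
  } else {
    c_hom <- as.numeric(p)
    lambda <- c_hom / 2
    unimodal <- TRUE
  }
  list(e = as.integer(e), lambda = lambda, c_hom = c_hom,
       unimodal = unimodal,
       peaks = data.frame(depth = sig, height = ys[sig]))
}

#' Lander-Waterman genome size estimate
#'
#' Haploid genome size from the total k-mer mass above the error cutoff
#' divided by the homozygous peak depth:
#' `G = sum_{c >= e} c h(c) / c_hom`.
#'
#' @param hist a `kmer_histogram`.
#' @param e error cutoff depth (k-mers with depth < e are excluded).
#' @param c_hom homozygous (2-copy) peak depth.
#' @return genome size in bases.
#' @export
waterman_size <- function(hist, e, c_hom) {
  check_scalar(e, "e", min = 1)
  if (!is.numeric(c_hom) || length(c_hom) != 1 || !is.finite(c_hom) || c_hom <= 0)
    abort_validation("c_hom must be a positive number")
  if (c_hom <= e)
    abort_validation("c_hom (", c_hom, ") must exceed the error cutoff e (", e, ")")
  keep <- hist$depth >= e
  sum(as.numeric(hist$depth[keep]) * hist$count[keep]) / c_hom
}

#' Fraction of k-mer occurrences attributed to sequencing errors
#'
#' Share of total occurrences T at depths below the error cutoff:
#' `sum_{c < e} c h(c) / T`.
#'
#' @param hist a `kmer_histogram`.
#' @param e error cutoff depth.
#' @return fraction in \[0, 1\].
#' @export
error_fraction <- function(hist, e) {
  check_scalar(e, "e", min = 1)
  tot <- hist_total(hist)
  if (tot == 0) return(0)
  low <- hist$depth < e
  sum(as.numeric(hist$depth[low]) * hist$count[low]) / tot
}

#' Fraction of filtered k-mer occurrences in the repeat tail
#'
#' `sum_{c > rho} c h(c) / sum_{c >= e} c h(c)`.
#'
#' @param hist a `kmer_histogram`.
#' @param e error cutoff depth.
#' @param rho repeat cutoff depth; defaults to `repeat_cutoff(c_hom)` in the
#'   full fits.
#' @return fraction in \[0, 1\].
#' @export
repeat_fraction <- function(hist, e, rho) {
  check_scalar(e, "e", min = 1)
  check_scalar(rho, "rho")
  if (rho <= e)
    abort_validation("rho (", rho, ") must exceed e (", e, ")")
  keep <- hist$depth >= e
  denom <- sum(as.numeric(hist$depth[keep]) * hist$count[keep])
  if (denom == 0) return(0)
  tail <- hist$depth > rho
  sum(as.numeric(hist$depth[tail]) * hist$count[tail]) / denom
}

#' Default repeat cutoff from the homozygous peak
#'
#' Depths above `factor * c_hom` are treated as repetitive. With the default
#' factor of 4 a homozygous peak at 63x yields a cutoff of 252x.
#'
#' @param c_hom homozygous peak depth.
#' @param factor multiple of `c_hom` marking the repeat tail.
#' @return cutoff depth.
#' @export
repeat_cutoff <- function(c_hom, factor = 4) {
  check_scalar(c_hom, "c_hom", min = 1e-9)
  factor * c_hom
}

#' Heterozygosity from mixture weights
#'
#' Converts distinct-k-mer mixture weights into the heterozygous fraction of
#' k-mer loci and the per-base heterozygosity. A heterozygous locus
#' contributes two distinct k-mers to the haploid-depth component, hence the
#' factor 1/2: `p_het = (w1/2) / (w1/2 + sum_{i>=2} w_i)`, and
#' `r = 1 - (1 - p_het)^(1/k)`.
#'
#' @param w numeric vector of component weights (component 1 = heterozygous).
#' @param k k-mer size.
#' @return list with `p_het` and `r`.
#' @export
het_from_weights <- function(w, k) {
  if (any(w < 0)) abort_validation("weights must be nonnegative")
  w <- w / sum(w)
  p_het <- (w[1] / 2) / (w[1] / 2 + sum(w[-1]))
  r <- 1 - (1 - p_het)^(1 / k)
  list(p_het = unname(p_het), r = unname(r))
}

new_spectrum_fit <- function(method, hist, e, lambda, weights, theta = NA_real_,
                             converged = TRUE, loglik = NULL, resid_norm = NA_real_) {
  c_hom <- 2 * lambda
  rho <- repeat_cutoff(c_hom)
  keep <- hist$depth >= e
  G <- sum(as.numeric(hist$depth[keep]) * hist$count[keep]) / (2 * lambda)
  k <- hist$k
  het <- if (!is.na(k)) het_from_weights(weights, k) else list(p_het = NA_real_, r = NA_real_)
  structure(list(
    method = method, k = k, e = e, lambda = lambda, c_hom = c_hom,
    rho = rho, weights = weights, theta = theta,
    p_het = het$p_het, r = het$r, G = G,
    error_fraction = error_fraction(hist, e),
    repeat_fraction = repeat_fraction(hist, e, rho),
    converged = converged, loglik = loglik, resid_norm = resid_norm
  ), class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("spectrum_fit [%s]: lambda=%.2f c_hom=%.2f e=%d G=%.3g bases\n",
              x$method, x$lambda, x$c_hom, x$e, x$G))
  cat(sprintf("  weights: %s%s\n", paste(sprintf("%.3f", x$weights), collapse = " "),
              ifelse(is.na(x$theta), "", sprintf("  theta=%.1f", x$theta))))
  cat(sprintf("  p_het=%.4f r=%.5f error=%.2f%% repeats=%.2f%%\n",
              x$p_het, x$r, 100 * x$error_fraction, 100 * x$repeat_fraction))
  invisible(x)
}

# starting haploid depth for the mixture fits
init_lambda_from_peaks <- function(hist, e) {
  pk <- tryCatch(detect_peaks(hist), error = function(err) NULL)
  if (!is.null(pk)) return(pk$lambda)
  keep <- hist$depth >= e
  sum(as.numeric(hist$depth[keep]) * hist$count[keep]) / sum(hist$count[keep]) / 2
}

#' Poisson-mixture genome model fitted by EM
#'
#' Fits the distinct-k-mer distribution at depths >= `e` as a mixture
#' `sum_i w_i Poisson(c; i * lambda)` (component 1 heterozygous at haploid
#' depth, component 2 homozygous at twice that, higher components repeats) by
#' expectation-maximization over `(lambda, w)`. The log-likelihood is
#' non-decreasing across iterations; the fit stops when the improvement drops
#' below `tol` or after `max_iter` iterations (returning the best fit so far
#' with `converged = FALSE`). The haploid genome size is
#' `G = sum_{c >= e} c h(c) / (2 lambda)`.
#'
#' @param hist a `kmer_histogram`.
#' @param e error cutoff depth; detected from the spectrum when NULL.
#' @param m number of mixture components (>= 2).
#' @param init_lambda starting haploid depth; peak-derived when NULL.
#' @param max_iter,tol EM stopping controls.
#' @param max_fit_factor the EM is fitted on depths up to
#'   `max_fit_factor * m * lambda0`, so high-copy repeat k-mers far beyond
#'   the mixture's reach cannot drag the coverage estimate; the genome size
#'   numerator still uses all depths >= e.
#' @return a `spectrum_fit` with a `loglik` trace.
#' @export
fit_poisson_em <- function(hist, e = NULL, m = 2, init_lambda = NULL,
                           max_iter = 500, tol = 1e-8, max_fit_factor = 2.4) {
  check_scalar(m, "m", min = 2, integer = TRUE)
  if (is.null(e)) e <- detect_peaks(hist)$e
  check_scalar(e, "e", min = 1)
  lambda <- init_lambda %||% init_lambda_from_peaks(hist, e)
  c_cap <- max(ceiling(max_fit_factor * m * lambda), e + 2 * m)
  keep <- hist$depth >= e & hist$depth <= c_cap
  if (!any(keep & hist$count > 0))
    abort_validation("histogram has no mass at or above e")
  cdep <- as.numeric(hist$depth[keep])
  h <- hist$count[keep]
  w <- rep(1 / m, m)
  comp <- seq_len(m)
  loglik <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # E-step in log space
    lp <- vapply(comp, function(i) dpois(cdep, i * lambda, log = TRUE) + log(w[i]),
                 numeric(length(cdep)))
    if (is.null(dim(lp))) lp <- matrix(lp, nrow = 1)
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(h * lse)
    loglik <- c(loglik, ll)
    if (iter > 1 && abs(ll - loglik[iter - 1]) < tol) { converged <- TRUE; break }
    r <- exp(lp - lse)                       # responsibilities, rows sum to 1
    wh <- r * h
    w <- colSums(wh) / sum(h)
    w <- pmax(w, 1e-12)
    w <- w / sum(w)
    lambda <- sum(wh * cdep) / sum(sweep(wh, 2, comp, "*"))
  }
  if (!converged)
    warning("fit_poisson_em: EM did not converge in ", max_iter,
            " iterations; returning best fit so far")
  new_spectrum_fit("poisson_em", hist, e = as.integer(e), lambda = lambda,
                   weights = w, converged = converged, loglik = loglik)
}

#' Negative-binomial mixture fit of a k-mer spectrum
#'
#' Least-squares fit of the distinct-k-mer histogram at depths >= `e` to
#' `D' sum_i w_i NB(c; mean = i * lambda, size = theta)` with a shared
#' dispersion `theta` across components, via Levenberg-Marquardt on an
#' unconstrained parameterization (log lambda, log theta, softmax weights,
#' log D'). Component 1 is heterozygous, component 2 homozygous, higher
#' components duplicated sequence. Reports `p_het`, per-base heterozygosity
#' `r = 1 - (1 - p_het)^(1/k)`, and `G = sum_{c >= e} c h(c) / (2 lambda)`.
#'
#' @param hist a `kmer_histogram` (its `k` must be set for `r`).
#' @param e error cutoff depth; detected from the spectrum when NULL.
#' @param m number of components, 2 to 4.
#' @param init_lambda starting haploid depth; peak-derived when NULL.
#' @param max_grid_factor the depth grid used for fitting extends to
#'   `max_grid_factor * m * lambda0` (capped at the histogram maximum), so
#'   the distant repeat tail does not dominate the residuals.
#' @return a `spectrum_fit` with `theta` set and `resid_norm` recorded.
#' @export
fit_nb_mixture <- function(hist, e = NULL, m = 3, init_lambda = NULL,
                           max_grid_factor = 4) {
  check_scalar(m, "m", min = 2, max = 4, integer = TRUE)
  if (is.null(e)) e <- detect_peaks(hist)$e
  check_scalar(e, "e", min = 1)
  keep <- hist$depth >= e
  if (!any(keep & hist$count > 0))
    abort_validation("histogram has no mass at or above e")
  lambda0 <- init_lambda %||% init_lambda_from_peaks(hist, e)
  c_max <- min(max(hist$depth), ceiling(max_grid_factor * m * lambda0))
  c_max <- max(c_max, e + 2 * m)
  grid <- seq.int(as.integer(ceiling(e)), as.integer(c_max))
  h_c <- numeric(length(grid))
  idx <- match(hist$depth, grid)
  ok <- !is.na(idx)
  h_c[idx[ok]] <- hist$count[ok]

  comp <- seq_len(m)
  model <- function(par) {
    lambda <- exp(par[1]); theta <- exp(par[2])
    a <- c(0, par[3:(m + 1)])
    w <- exp(a - max(a)); w <- w / sum(w)
    Dp <- exp(par[m + 2])
    mu <- rowSums(vapply(comp, function(i)
      w[i] * dnbinom(grid, mu = i * lambda, size = theta), numeric(length(grid))))
    list(fit = Dp * mu, w = w, lambda = lambda, theta = theta, Dp = Dp)
  }
  resid_fun <- function(par) h_c - model(par)$fit
  par0 <- c(log(lambda0), log(30),
            rep(0, m - 1), log(max(sum(h_c), 1)))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(err) err)
  if (inherits(fit, "error")) {
    rn <- sqrt(sum(resid_fun(par0)^2))
    stop("fit_nb_mixture: optimizer failure (last residual norm ",
         format(rn), "): ", conditionMessage(fit))
  }
  mod <- model(fit$par)
  if (!all(is.finite(c(mod$lambda, mod$theta, mod$w))))
    stop("fit_nb_mixture: optimizer returned non-finite parameters ",
         "(residual norm ", format(sqrt(fit$deviance)), ")")
  new_spectrum_fit("nb_mixture", hist, e = as.integer(e), lambda = mod$lambda,
                   weights = mod$w, theta = mod$theta,
                   converged = fit$info %in% 1:4,
                   resid_norm = sqrt(fit$deviance))
}

#' Consensus genome size across estimates
#'
#' @param estimates numeric vector of genome-size estimates.
#' @return list with `median`, `sd` (sample standard deviation; 0 with
#'   `single = TRUE` when only one estimate is supplied), and `n`.
#' @export
consensus_size <- function(estimates) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0)
    abort_validation("estimates must be non-empty")
  single <- length(estimates) == 1
  list(median = median(estimates),
       sd = if (single) 0 else sd(estimates),
       single = single, n = length(estimates))
}

#' Kruskal-Wallis rank-sum comparison of estimate groups
#'
#' Tie-corrected H statistic with a chi-square p-value on
#' `length(groups) - 1` degrees of freedom (via [stats::kruskal.test()]).
#' When every observation is identical the statistic is 0 and p = 1.
#'
#' @param groups list (>= 2) of non-empty numeric vectors.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    abort_validation("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0))
    abort_validation("each group must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1)
    return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- kruskal.test(values, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Genome-feature estimates across k-mer sizes and methods
#'
#' Runs the Lander-Waterman, Poisson-EM, and NB-mixture estimators on each
#' supplied histogram and summarizes: a (k, method) genome-size table, the
#' consensus median and standard deviation, and Kruskal-Wallis comparisons of
#' the sizes grouped by method (pooling k) and by k (pooling methods).
#'
#' @param histograms named list of `kmer_histogram` objects, one per k-mer
#'   size (names are the k values, informational only).
#' @param e shared error cutoff; detected per histogram when NULL.
#' @param m_poisson,m_nb component counts for the two mixture fits.
#' @return a `genome_feature_estimates` list with `table` (data.frame `k`,
#'   `method`, `G`, `lambda`, `r`), `consensus_median`, `consensus_sd`, and
#'   `comparison_stats`.
#' @export
estimate_genome_features <- function(histograms, e = NULL, m_poisson = 2,
                                     m_nb = 3) {
  if (length(histograms) == 0)
    abort_validation("histograms must be non-empty")
  rows <- list()
  for (nm in names(histograms)) {
    hist <- histograms[[nm]]
    pk <- detect_peaks(hist)
    e_use <- e %||% pk$e
    wat <- waterman_size(hist, e_use, pk$c_hom)
    pois <- fit_poisson_em(hist, e = e_use, m = m_poisson,
                           init_lambda = pk$lambda)
    nb <- fit_nb_mixture(hist, e = e_use, m = m_nb, init_lambda = pk$lambda)
    rows[[nm]] <- data.frame(
      k = rep(hist$k, 3),
      method = c("waterman", "poisson_em", "nb_mixture"),
      G = c(wat, pois$G, nb$G),
      lambda = c(pk$lambda, pois$lambda, nb$lambda),
      r = c(NA_real_, pois$r, nb$r),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cons <- consensus_size(tab$G)
  comparison <- list()
  if (length(unique(tab$method)) >= 2 && nrow(tab) > length(unique(tab$method)))
    comparison$by_method <- c(list(grouping = "method"),
                              kruskal_wallis(split(tab$G, tab$method)))
  if (length(unique(tab$k)) >= 2)
    comparison$by_k <- c(list(grouping = "k"),
                         kruskal_wallis(split(tab$G, tab$k)))
  structure(list(table = tab, consensus_median = cons$median,
                 consensus_sd = cons$sd, comparison_stats = comparison),
            class = "genome_feature_estimates")
}

#' @export
print.genome_feature_estimates <- function(x, ...) {
  print(x$table)
  cat(sprintf("consensus: median %.4g +/- %.3g bases\n",
              x$consensus_median, x$consensus_sd))
  invisible(x)
}

#' Plot a k-mer spectrum with annotated peaks
#'
#' @param hist a `kmer_histogram`.
#' @param peaks optional result of [detect_peaks()]; computed when NULL.
#' @param xmax right edge of the depth axis (default 4x the homozygous peak).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the peak list used.
#' @export
plot_spectrum <- function(hist, peaks = NULL, xmax = NULL, ...) {
  peaks <- peaks %||% detect_peaks(hist)
  xmax <- xmax %||% ceiling(4 * peaks$c_hom)
  keep <- hist$depth <= xmax
  graphics::plot(hist$depth[keep], hist$count[keep], type = "h",
                 xlab = "k-mer depth", ylab = "distinct k-mers", ...)
  graphics::abline(v = c(peaks$e, peaks$lambda, peaks$c_hom),
                   col = c("grey40", "red", "blue"), lty = 2)
  graphics::legend("topright", bty = "n", lty = 2,
                   col = c("grey40", "red", "blue"),
                   legend = sprintf(c("e = %d", "lambda = %.1f", "c_hom = %.1f"),
                                    c(peaks$e, peaks$lambda, peaks$c_hom)))
  invisible(peaks)
}
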