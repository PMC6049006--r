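BASES <- c("A", "C", "G", "T")

abort_validation <- function(...) {
  stop(structure(class = c("holobinr_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

abort_parse <- function(...) {
  stop(structure(class = c("holobinr_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_scalar <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    abort_validation(name, " must be a single finite number")
  if (x < min || x > max)
    abort_validation(name, " must be in [", min, ", ", max, "], got ", x)
  if (integer && x != round(x))
    abort_validation(name, " must be an integer, got ", x)
  invisible(x)
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences (ACGTN and IUPAC codes accepted).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of sequences
#'
#' Non-ACGT symbols are ignored in both numerator and denominator.
#'
#' @param x character vector of sequences.
#' @return numeric vector of GC fractions.
#' @export
gc_fraction <- function(x) {
  vapply(x, function(s) {
    r <- charToRaw(toupper(s))
    gc <- sum(r == charToRaw("G") | r == charToRaw("C"))
    at <- sum(r == charToRaw("A") | r == charToRaw("T"))
    if (gc + at == 0) return(NA_real_)
    gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

# Random DNA with i.i.d. bases at the given GC content.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  idx <- sample.int(4L, n, replace = TRUE, prob = p)
  rawToChar(as.raw(c(65L, 67L, 71L, 84L)[idx]))
}

# Random DNA from an order-2 Markov chain whose context-specific emission
# probabilities are genome-specific perturbations of a GC-targeted base
# composition. Realized GC is repaired to within `tol` of the target by
# uniform-position swaps so compositional signatures differ between genomes
# while GC stays on target.
random_markov_dna <- function(n, gc = 0.5, tol = 0.015, concentration = 8) {
  if (n <= 0) return("")
  base_p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  # 16 contexts (previous two bases) x 4 emission probs
  trans <- matrix(0, 16, 4)
  for (ctx in 1:16) {
    pert <- rgamma(4, shape = concentration * base_p * 4, rate = 1)
    trans[ctx, ] <- pert / sum(pert)
  }
  # renormalize each context toward the target GC so the chain's marginal
  # composition does not drift
  for (ctx in 1:16) {
    p <- trans[ctx, ]
    gc_now <- p[2] + p[3]
    p[c(2, 3)] <- p[c(2, 3)] * gc / gc_now
    p[c(1, 4)] <- p[c(1, 4)] * (1 - gc) / (p[1] + p[4])
    trans[ctx, ] <- p / sum(p)
  }
  s1 <- sample.int(4L, 1L, prob = base_p)
  s2 <- if (n >= 2) sample.int(4L, 1L, prob = base_p) else 1L
  cum <- t(apply(trans, 1, cumsum))
  out <- cpp_markov_walk(n, cum, runif(n), s1, s2)
  seq_raw <- as.raw(c(65L, 67L, 71L, 84L))[out]
  # GC repair: swap uniformly chosen positions until within tolerance
  gc_now <- sum(seq_raw == as.raw(67L) | seq_raw == as.raw(71L)) / n
  excess <- round((gc_now - gc) * n)
  if (abs(excess) > tol * n) {
    if (excess > 0) {
      at_idx <- which(seq_raw == as.raw(67L) | seq_raw == as.raw(71L))
      pick <- sample(at_idx, excess)
      seq_raw[pick] <- as.raw(c(65L, 84L))[sample.int(2L, excess, replace = TRUE)]
    } else {
      gc_idx <- which(seq_raw == as.raw(65L) | seq_raw == as.raw(84L))
      pick <- sample(gc_idx, -excess)
      seq_raw[pick] <- as.raw(c(67L, 71L))[sample.int(2L, -excess, replace = TRUE)]
    }
  }
  rawToChar(seq_raw)
}

# Substitute bases at given 1-based positions with a uniformly chosen
# different base. Operates on a single sequence string.
substitute_bases <- function(seq, positions) {
  if (length(positions) == 0) return(seq)
  r <- charToRaw(seq)
  cur <- r[positions]
  codes <- as.raw(c(65L, 67L, 71L, 84L))
  # map current base to an index, pick one of the other three
  cur_idx <- match(cur, codes)
  offset <- sample.int(3L, length(positions), replace = TRUE)
  new_idx <- ((cur_idx - 1L + offset) %% 4L) + 1L
  r[positions] <- codes[new_idx]
  rawToChar(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
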