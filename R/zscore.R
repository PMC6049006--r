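#' Direction-signed z-score table
#'
#' Standardizes each parameter row across assemblies:
#' `z[p, a] = direction_p * (x[p, a] - mean_p) / sd_p` with the sample (n-1)
#' standard deviation. Rows with zero spread yield all-zero z-scores. A
#' robust variant uses the median and the (normal-consistent) MAD instead; in
#' that case rows need not sum to zero.
#'
#' @param values parameters x assemblies numeric matrix (rownames =
#'   parameters, colnames = assemblies).
#' @param directions named numeric vector of +1 (higher is better) or -1
#'   (lower is better) per parameter; unnamed values recycle in row order.
#' @param robust use median/MAD standardization.
#' @return z matrix with the same dimnames as `values`.
#' @export
zscore_table <- function(values, directions, robust = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) < 2)
    abort_validation("need at least 2 assemblies")
  if (!all(is.finite(values)))
    abort_validation("values must all be finite")
  if (!is.null(names(directions)) && !is.null(rownames(values)))
    directions <- directions[rownames(values)]
  directions <- rep_len(as.numeric(directions), nrow(values))
  if (!all(directions %in% c(-1, 1)))
    abort_validation("directions must be +1 or -1")
  z <- t(apply(values, 1, function(x) {
    ctr <- if (robust) median(x) else mean(x)
    scl <- if (robust) mad(x) else sd(x)
    if (!is.finite(scl) || scl == 0) return(rep(0, length(x)))
    (x - ctr) / scl
  }))
  dimnames(z) <- dimnames(values)
  z * directions
}

#' Cumulative criterion scores
#'
#' Sums z-score rows within each operational criterion.
#'
#' @param z z matrix from [zscore_table()].
#' @param criteria named character vector mapping parameter name to criterion
#'   name; parameters absent from the map go to `"other"`.
#' @return criteria x assemblies matrix of summed scores, with an `overall`
#'   row.
#' @export
cumulative_scores <- function(z, criteria = NULL) {
  if (is.null(criteria)) {
    out <- matrix(colSums(z), nrow = 1,
                  dimnames = list("overall", colnames(z)))
    return(out)
  }
  crit <- unname(criteria[rownames(z)])
  crit[is.na(crit)] <- "other"
  out <- rowsum(z, crit)
  rbind(out, overall = colSums(z))
}

#' Classify assemblies from cumulative scores
#'
#' Labels follow the standard-deviation-from-the-median rule: `good` when a
#' score is at least one sample SD above the median of the scores, `poor`
#' when at least one SD below, `average` otherwise.
#'
#' @param scores numeric vector of per-assembly cumulative scores (>= 2).
#' @return character vector of labels in `{good, average, poor}`, named like
#'   `scores`.
#' @export
classify_assemblies <- function(scores) {
  if (length(scores) < 2)
    abort_validation("need at least 2 scores")
  med <- median(scores)
  s <- sd(scores)
  labels <- rep("average", length(scores))
  if (is.finite(s) && s > 0) {
    labels[scores >= med + s] <- "good"
    labels[scores <= med - s] <- "poor"
  }
  setNames(labels, names(scores))
}

# default parameter -> (direction, criterion) scheme; config-driven so the
# parameter list can be swapped
default_parameter_scheme <- function() {
  data.frame(
    parameter = c("markers_complete", "markers_fragmented", "markers_missing",
                  "N50_scaffold", "N50_contig", "NG50_scaffold", "NG50_contig",
                  "longest_scaffold", "contigs_over_10kb", "n_content",
                  "pct_genome_in_scaffolds_ge_7kb",
                  "pct_genome_in_scaffolds_ge_25kb"),
    direction = c(1, -1, -1,
                  1, 1, 1, 1,
                  1, 1, -1,
                  1, 1),
    criterion = c("completeness", "completeness", "completeness",
                  "contiguity", "contiguity", "contiguity", "contiguity",
                  "contiguity", "contiguity", "contiguity",
                  "usefulness", "usefulness"),
    stringsAsFactors = FALSE
  )
}

#' Multi-assembly comparison with the modified z-score framework
#'
#' Assembles a parameters x assemblies value matrix from per-assembly
#' metrics (and optional marker-recovery counts), computes direction-signed
#' z-scores, sums them per operational criterion (completeness, contiguity,
#' usefulness), and assigns good/average/poor labels per criterion and
#' overall. Parameters with any missing value across assemblies are dropped
#' (with a message), since z-scores are undefined there.
#'
#' @param metrics named list of `assembly_metrics`, one per assembly.
#' @param markers optional named list of `marker_recovery`, one per assembly.
#' @param scheme data.frame with `parameter`, `direction`, `criterion`
#'   columns; defaults to the built-in scheme.
#' @param robust passed to [zscore_table()].
#' @return a `zscore_report`: list with `values`, `z`, `scores` (criteria x
#'   assemblies), and `labels` (criteria x assemblies character matrix).
#' @export
compare_assemblies <- function(metrics, markers = NULL, scheme = NULL,
                               robust = FALSE) {
  if (length(metrics) < 2)
    abort_validation("need at least 2 assemblies")
  scheme <- scheme %||% default_parameter_scheme()
  asm <- names(metrics)
  val_list <- lapply(asm, function(a) {
    m <- metrics[[a]]
    v <- vapply(scheme$parameter, function(p) {
      if (p %in% names(m)) as.numeric(m[[p]])
      else if (p == "markers_complete" && !is.null(markers)) as.numeric(markers[[a]]$n_complete)
      else if (p == "markers_fragmented" && !is.null(markers)) as.numeric(markers[[a]]$n_fragmented)
      else if (p == "markers_missing" && !is.null(markers)) as.numeric(markers[[a]]$n_missing)
      else NA_real_
    }, numeric(1))
    v
  })
  values <- do.call(cbind, val_list)
  dimnames(values) <- list(scheme$parameter, asm)
  keep <- apply(values, 1, function(x) all(is.finite(x)))
  if (!all(keep))
    message("dropping parameters with missing values: ",
            paste(rownames(values)[!keep], collapse = ", "))
  values <- values[keep, , drop = FALSE]
  scheme <- scheme[keep, , drop = FALSE]
  z <- zscore_table(values, setNames(scheme$direction, scheme$parameter),
                    robust = robust)
  scores <- cumulative_scores(z, setNames(scheme$criterion, scheme$parameter))
  labels <- t(apply(scores, 1, classify_assemblies))
  dimnames(labels) <- dimnames(scores)
  structure(list(values = values, z = z, scores = scores, labels = labels,
                 scheme = scheme, robust = robust),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat("zscore_report\n\ncumulative scores:\n")
  print(round(x$scores, 3))
  cat("\nlabels:\n")
  print(x$labels, quote = FALSE)
  invisible(x)
}
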