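#' Default pipeline configuration
#'
#' Two bundled scale profiles: `"smoke"` (500 kb host, two symbionts, 40x
#' host depth) runs end to end in seconds and is the test-scale default;
#' `"bench"` (2 Mb host, five symbionts, 60x) matches the package's
#' recovery-benchmark conditions. Every stage's parameters are materialized
#' here so the run report can echo exactly what was used.
#'
#' @param profile profile name.
#' @return nested configuration list.
#' @export
default_config <- function(profile = c("smoke", "bench")) {
  profile <- match.arg(profile)
  base <- list(
    profile = profile,
    seed = 1L,
    out_dir = "holobinr_run",
    simulate = list(
      host_length = 5e5, host_het = 0.005, host_repeat_fraction = 0.10,
      repeat_unit_length = 500, host_gc = 0.39, host_depth = 40,
      n_symbionts = 2, symbiont_lengths = c(2e5, 1e5),
      symbiont_gc = c(0.55, 0.30), symbiont_depths = c(20, 15),
      read_length = 150, error_rate = 0.002, paired = TRUE,
      insert_size = 400, target_n50 = 5000, min_contig_length = 2500
    ),
    spectrum = list(k = 21, smoothing_window = 5, error_cutoff = NULL,
                    repeat_cutoff = NULL, m_poisson = 2, m_nb = 3),
    bin = list(w = 0.7, tau = 0.025, min_bin_size = 20000,
               min_contig_length = 2000, k = 21),
    recruit = list(k = 21, theta = 0.5),
    assess = list(n_split = 10)
  )
  if (profile == "bench") {
    base$simulate <- modifyList(base$simulate, list(
      host_length = 2e6, host_het = 0.005, host_repeat_fraction = 0.15,
      host_depth = 60, error_rate = 0.005,
      n_symbionts = 5, symbiont_lengths = c(3e5, 2.5e5, 2e5, 1.5e5, 1e5),
      symbiont_gc = c(0.30, 0.45, 0.50, 0.58, 0.65),
      symbiont_depths = c(40, 30, 25, 15, 10),
      read_length = 250, insert_size = 600, min_contig_length = 2500
    ))
    base$bin$min_bin_size <- 50000
  }
  base
}

# reject keys that the default template does not know, recursively
validate_config_keys <- function(config, template = default_config(), path = "") {
  for (nm in names(config)) {
    if (!nm %in% names(template))
      abort_validation("unknown config key: ", path, nm)
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(config[[nm]]))
      validate_config_keys(config[[nm]], template[[nm]], paste0(path, nm, "."))
  }
  invisible(config)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; keys not present fall back to the selected profile's
#' defaults, unknown keys are rejected before any stage runs.
#'
#' @param path YAML file path.
#' @return merged configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  profile <- user$profile %||% "smoke"
  template <- default_config(profile)
  validate_config_keys(user, template)
  modifyList(template, user)
}

stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, spectrum = 211L, bin = 307L, recruit = 401L,
            assess = 503L)
  (as.integer(seed) + offs[[stage]]) %% .Machine$integer.max
}

#' Run the holobiont analysis pipeline
#'
#' Executes simulate -> k-mer spectrum -> bin -> recruit -> assess in order,
#' writing every intermediate in its standard on-disk format (FASTA, FASTQ,
#' histogram TSV, depth TSV, summary TSVs) plus a JSON run report with the
#' parameters, per-stage seeds, and headline estimates. Rerunning with the
#' same configuration reproduces all outputs byte-identically. A stage
#' failure aborts with the failing stage named; outputs of earlier stages
#' are retained.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()] (or a path to a YAML file).
#' @param stages subset of stages to run (in pipeline order).
#' @return the run report, invisibly also written to
#'   `<out_dir>/run_report.json`.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "spectrum", "bin",
                                    "recruit", "assess")) {
  if (is.character(config) && length(config) == 1) config <- read_config(config)
  validate_config_keys(config, default_config(config$profile %||% "smoke"))
  stages <- match.arg(stages, several.ok = TRUE)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(package_version = as.character(utils::packageVersion("holobinr")),
                 config = config, stages_run = stages)
  st <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  run_stage("simulate", function() {
    p <- config$simulate
    set.seed(stage_seed(config$seed, "simulate"))
    host <- simulate_host_genome(p$host_length, p$host_het,
                                 p$host_repeat_fraction,
                                 p$repeat_unit_length, gc = p$host_gc)
    syms <- if (p$n_symbionts > 0)
      simulate_symbiont_genomes(p$n_symbionts, p$symbiont_lengths,
                                p$symbiont_gc)
    else list()
    members <- c(list(list(genome_id = "host",
                           sequences = c(host$haplotype_a, host$haplotype_b),
                           mean_depth = p$host_depth)),
                 lapply(names(syms), function(id)
                   list(genome_id = id, sequences = syms[[id]],
                        mean_depth = p$symbiont_depths[[match(id, names(syms))]])))
    sim <- simulate_reads(members, read_length = p$read_length,
                          error_rate = p$error_rate, paired = p$paired,
                          insert_size = p$insert_size)
    genomes <- c(list(host = host$haplotype_a), syms)
    depths <- setNames(c(p$host_depth, unlist(p$symbiont_depths)[seq_along(syms)]),
                       c("host", names(syms)))
    frag <- fragment_genomes(genomes, target_n50 = p$target_n50,
                             min_length = p$min_contig_length,
                             depths = depths)
    write_fastq(sim$reads, file.path(out_dir, "reads.fastq.gz"))
    write_fasta(frag$contigs, file.path(out_dir, "contigs.fasta"))
    write.table(sim$truth$read_origins,
                file.path(out_dir, "read_origins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    write.table(frag$truth, file.path(out_dir, "contig_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    st$host <- host; st$reads <- sim$reads; st$read_truth <- sim$truth
    st$contigs <- frag$contigs; st$contig_truth <- frag$truth
    report$simulate <<- list(seed = stage_seed(config$seed, "simulate"),
                             n_reads = nrow(sim$reads),
                             n_contigs = length(frag$contigs),
                             host_length = p$host_length)
  })

  run_stage("spectrum", function() {
    p <- config$spectrum
    reads <- st$reads %||% read_fastq(file.path(out_dir, "reads.fastq.gz"))
    tab <- count_kmers(reads$seq, p$k)
    hist <- build_histogram(tab)
    write_histogram(hist, file.path(out_dir, sprintf("k%d.histo", p$k)))
    pk <- detect_peaks(hist, smoothing_window = p$smoothing_window)
    e <- p$error_cutoff %||% pk$e
    wat <- waterman_size(hist, e, pk$c_hom)
    pois <- fit_poisson_em(hist, e = e, m = p$m_poisson,
                           init_lambda = pk$lambda)
    nb <- fit_nb_mixture(hist, e = e, m = p$m_nb, init_lambda = pk$lambda)
    rho <- p$repeat_cutoff %||% repeat_cutoff(pk$c_hom)
    cons <- consensus_size(c(wat, pois$G, nb$G))
    st$kmer_table <- tab
    st$spectrum <- list(
      k = p$k, e = e, lambda = pk$lambda, c_hom = pk$c_hom,
      unimodal = pk$unimodal, rho = rho,
      G_waterman = wat, G_poisson_em = pois$G, G_nb_mixture = nb$G,
      G_median = cons$median, G_sd = cons$sd,
      p_het = nb$p_het, r = nb$r, theta = nb$theta,
      error_fraction = error_fraction(hist, e),
      repeat_fraction = repeat_fraction(hist, e, rho))
    report$spectrum <<- st$spectrum
  })

  run_stage("bin", function() {
    p <- config$bin
    contigs_raw <- st$contigs %||% read_fasta(file.path(out_dir, "contigs.fasta"))
    cs <- contig_set(contigs_raw)
    tab <- if (!is.null(st$kmer_table) && st$kmer_table$k == p$k) st$kmer_table
    else {
      reads <- st$reads %||% read_fastq(file.path(out_dir, "reads.fastq.gz"))
      count_kmers(reads$seq, p$k)
    }
    depths <- contig_depth_from_kmers(cs, tab)
    write_depth_table(depths, file.path(out_dir, "depths.tsv"))
    res <- bin_contigs(cs, depths, w = p$w, tau = p$tau,
                       min_bin_size = p$min_bin_size,
                       min_contig_length = p$min_contig_length)
    ev <- if (!any(is.na(cs$truth))) evaluate_bins(res, cs) else NULL
    summary_tab <- res$bins
    if (!is.null(ev)) summary_tab <- merge(summary_tab, ev, by = "bin_id")
    write.table(summary_tab, file.path(out_dir, "bins.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (b in res$bins$bin_id) {
      members <- names(res$membership)[!is.na(res$membership) &
                                         res$membership == b]
      write_fasta(setNames(cs$sequence[match(members, cs$id)], members),
                  file.path(out_dir, sprintf("%s.fasta", b)))
    }
    st$contig_set <- cs; st$binning <- res; st$bin_eval <- ev
    host_rows <- if (!is.null(ev)) ev[ev$majority_label == "host", ] else NULL
    report$bin <<- list(n_bins = nrow(res$bins),
                        n_unbinned = length(res$unbinned),
                        host_bin_f1 = if (!is.null(host_rows) && nrow(host_rows) > 0)
                          host_rows$f1[which.max(host_rows$recall)] else NA)
  })

  run_stage("recruit", function() {
    p <- config$recruit
    res <- st$binning
    cs <- st$contig_set
    if (is.null(res)) stop("binning results not available in this run")
    sel <- if (!is.null(st$bin_eval))
      select_host_bins(res, "truth", host_label = "host",
                       evaluation = st$bin_eval)
    else select_host_bins(res, "heuristic")
    host_seqs <- cs$sequence[!is.na(res$membership[cs$id]) &
                               res$membership[cs$id] %in% sel]
    reads <- st$reads %||% read_fastq(file.path(out_dir, "reads.fastq.gz"))
    rec <- recruit_reads(reads, host_seqs, k = p$k, theta = p$theta)
    write_fastq(rec$host, file.path(out_dir, "host_reads.fastq.gz"))
    write_fastq(rec$other, file.path(out_dir, "other_reads.fastq.gz"))
    stats <- rec$stats
    if (!is.null(st$read_truth)) {
      origin <- setNames(st$read_truth$read_origins$genome_id,
                         st$read_truth$read_origins$read_id)
      truth_host <- origin[reads$id] == "host"
      called_host <- reads$id %in% rec$host$id
      stats$precision <- sum(called_host & truth_host) / max(sum(called_host), 1)
      stats$recall <- sum(called_host & truth_host) / max(sum(truth_host), 1)
    }
    jsonlite::write_json(stats, file.path(out_dir, "recruit_stats.json"),
                         auto_unbox = TRUE, digits = NA)
    st$recruited <- rec
    report$recruit <<- stats
    # genome features from the recruited host reads (the whole point of
    # binning: symbiont k-mer mass no longer inflates the estimate)
    ps <- config$spectrum
    host_hist <- build_histogram(count_kmers(rec$host$seq, ps$k))
    pk <- detect_peaks(host_hist, smoothing_window = ps$smoothing_window)
    e <- ps$error_cutoff %||% pk$e
    wat <- waterman_size(host_hist, e, pk$c_hom)
    pois <- fit_poisson_em(host_hist, e = e, m = ps$m_poisson,
                           init_lambda = pk$lambda)
    nb <- fit_nb_mixture(host_hist, e = e, m = ps$m_nb, init_lambda = pk$lambda)
    cons <- consensus_size(c(wat, pois$G, nb$G))
    st$host_spectrum <- list(
      k = ps$k, e = e, lambda = pk$lambda, c_hom = pk$c_hom,
      G_waterman = wat, G_poisson_em = pois$G, G_nb_mixture = nb$G,
      G_median = cons$median, G_sd = cons$sd, p_het = nb$p_het, r = nb$r)
    report$host_spectrum <<- st$host_spectrum
  })

  run_stage("assess", function() {
    p <- config$assess
    res <- st$binning; cs <- st$contig_set
    if (is.null(res)) stop("binning results not available in this run")
    sel <- if (!is.null(st$bin_eval))
      select_host_bins(res, "truth", host_label = "host",
                       evaluation = st$bin_eval)
    else select_host_bins(res, "heuristic")
    host_seqs <- setNames(
      cs$sequence[!is.na(res$membership[cs$id]) & res$membership[cs$id] %in% sel],
      cs$id[!is.na(res$membership[cs$id]) & res$membership[cs$id] %in% sel])
    G <- (st$host_spectrum %||% st$spectrum)$G_median %||% NULL
    m <- assembly_metrics(host_seqs, genome_size_estimate = G,
                          n_split = p$n_split)
    report$assess <<- unclass(m)
  })

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(report)
}
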