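#' Simulate a diploid host genome with heterozygosity and repeats
#'
#' Builds a pair of haplotypes for a diploid host. Haplotype A is assembled
#' from random background sequence plus dispersed copies of randomly drawn
#' repeat units; haplotype B is derived from A by substituting bases
#' independently at `het_rate` per site (never replacing a base with itself).
#' Repeat families each contribute `copies_per_family` dispersed copies of a
#' unit drawn once per family, with the final copy truncated so that planted
#' repeat bases hit `repeat_fraction * haploid_length` exactly.
#'
#' @param haploid_length haploid genome length in bases.
#' @param het_rate per-base substitution rate between haplotypes, in \[0, 1).
#' @param repeat_fraction fraction of the haploid length covered by planted
#'   repeat copies, in \[0, 0.9\].
#' @param repeat_unit_length length of each repeat unit in bases.
#' @param gc target GC content of the genome (default 0.39, a typical
#'   anthozoan value).
#' @param copies_per_family dispersed copies per repeat family.
#' @param seed integer seed; identical seeds reproduce identical output.
#' @return a list with elements `haplotype_a`, `haplotype_b` (character
#'   scalars) and `truth`, a `host_genome_truth` list recording the planted
#'   parameters, the 0-based heterozygous positions, and repeat bookkeeping.
#' @export
simulate_host_genome <- function(haploid_length, het_rate = 0,
                                 repeat_fraction = 0,
                                 repeat_unit_length = 500, gc = 0.39,
                                 copies_per_family = 10, seed = NULL) {
  check_scalar(haploid_length, "haploid_length", min = 10, integer = TRUE)
  check_scalar(het_rate, "het_rate", min = 0, max = 1 - 1e-12)
  check_scalar(repeat_fraction, "repeat_fraction", min = 0, max = 0.9)
  check_scalar(repeat_unit_length, "repeat_unit_length", min = 1,
               max = haploid_length - 1, integer = TRUE)
  check_scalar(gc, "gc", min = 0.05, max = 0.95)
  if (!is.null(seed)) set.seed(seed)

  target_repeat_bases <- round(repeat_fraction * haploid_length)
  n_families <- 0L
  copy_lengths <- integer(0)
  units <- character(0)
  if (target_repeat_bases > 0) {
    n_full <- target_repeat_bases %/% repeat_unit_length
    rem <- target_repeat_bases %% repeat_unit_length
    n_copies <- n_full + (rem > 0)
    n_families <- as.integer(ceiling(n_copies / copies_per_family))
    units <- vapply(seq_len(n_families),
                    function(i) random_dna(repeat_unit_length, gc),
                    character(1))
    family_of_copy <- rep(seq_len(n_families), length.out = n_copies)
    copy_lengths <- rep(repeat_unit_length, n_copies)
    if (rem > 0) copy_lengths[n_copies] <- rem
    copies <- substr(units[family_of_copy], 1L, copy_lengths)
  } else {
    copies <- character(0)
  }
  planted <- sum(nchar(copies))
  background_len <- haploid_length - planted

  background <- random_markov_dna(background_len, gc)
  n_copies <- length(copies)
  if (n_copies > 0) {
    # disperse: cut the background into n_copies + 1 chunks and interleave
    cuts <- sort(sample.int(background_len + 1L, n_copies, replace = TRUE)) - 1L
    bounds <- c(0L, cuts, background_len)
    chunks <- substring(background, head(bounds, -1) + 1L, bounds[-1])
    copies <- copies[sample.int(n_copies)]
    pieces <- character(2 * n_copies + 1)
    pieces[seq(1, 2 * n_copies + 1, by = 2)] <- chunks
    pieces[seq(2, 2 * n_copies, by = 2)] <- copies
    hap_a <- paste(pieces, collapse = "")
  } else {
    hap_a <- background
  }
  stopifnot(nchar(hap_a) == haploid_length)

  het_positions <- if (het_rate > 0) {
    which(runif(haploid_length) < het_rate)
  } else integer(0)
  hap_b <- substitute_bases(hap_a, het_positions)

  truth <- structure(list(
    haploid_length = haploid_length,
    het_rate = het_rate,
    repeat_fraction = repeat_fraction,
    repeat_unit_length = repeat_unit_length,
    het_positions = het_positions - 1L,   # 0-based
    n_repeat_families = n_families,
    planted_repeat_bases = planted,
    has_repeats = planted > 0,
    gc = gc,
    seed = seed
  ), class = "host_genome_truth")

  list(haplotype_a = hap_a, haplotype_b = hap_b, truth = truth)
}

#' Simulate symbiont genomes of distinct base composition
#'
#' Each genome is drawn from its own order-2 Markov chain targeted at the
#' requested GC content, so tetranucleotide profiles differ between genomes
#' while realized GC stays within about 1.5 percentage points of target.
#'
#' @param n number of genomes.
#' @param lengths integer vector of genome lengths (length `n`).
#' @param gc_targets numeric vector of GC targets in (0, 1) (length `n`).
#' @param ids optional genome identifiers; default `sym1..symN`.
#' @param seed integer seed.
#' @return named list of sequences (names are genome ids).
#' @export
simulate_symbiont_genomes <- function(n, lengths, gc_targets, ids = NULL,
                                      seed = NULL) {
  check_scalar(n, "n", min = 1, integer = TRUE)
  if (length(lengths) != n || length(gc_targets) != n)
    abort_validation("lengths and gc_targets must each have ", n, " entries")
  for (g in gc_targets) check_scalar(g, "gc_target", min = 1e-9, max = 1 - 1e-9)
  if (!is.null(seed)) set.seed(seed)
  ids <- ids %||% paste0("sym", seq_len(n))
  out <- lapply(seq_len(n), function(i) random_markov_dna(lengths[i], gc_targets[i]))
  names(out) <- ids
  out
}

#' Simulate uniform-coverage shotgun reads from a community
#'
#' Draws reads uniformly along each member genome at the member's nominal
#' depth, with a flat per-base substitution error rate and constant base
#' qualities (Q40, 'I'). Diploid members are sampled evenly across their two
#' haplotypes, so each haplotype receives half the member depth. Read counts
#' follow `round(mean_depth * haploid_length / read_length)` per member
#' (rounded down to an even number in paired mode).
#'
#' @param members list of community members; each a list with `genome_id`,
#'   `sequences` (character vector of 1 or 2 haplotypes) and `mean_depth`.
#' @param read_length read length in bases.
#' @param error_rate per-base substitution error rate in \[0, 0.1\].
#' @param paired emit read pairs from fixed-size inserts.
#' @param insert_size outer insert size in bases (paired mode).
#' @param seed integer seed.
#' @return list with `reads` (data.frame: `id`, `seq`, `qual`), and `truth`,
#'   a `community_truth` list with the member table and `read_origins`
#'   (data.frame `read_id`, `genome_id`).
#' @export
simulate_reads <- function(members, read_length = 250, error_rate = 0,
                           paired = TRUE, insert_size = 600, seed = NULL) {
  check_scalar(read_length, "read_length", min = 1, integer = TRUE)
  check_scalar(error_rate, "error_rate", min = 0, max = 0.1)
  if (paired) {
    check_scalar(insert_size, "insert_size", integer = TRUE)
    if (insert_size < read_length)
      abort_validation("insert_size (", insert_size,
                       ") must be >= read_length (", read_length, ")")
  }
  if (!is.null(seed)) set.seed(seed)

  member_tab <- data.frame(
    genome_id = vapply(members, function(m) m$genome_id, character(1)),
    ploidy = vapply(members, function(m) length(m$sequences), integer(1)),
    haploid_length = vapply(members, function(m) nchar(m$sequences[[1]]), integer(1)),
    mean_depth = vapply(members, function(m) as.numeric(m$mean_depth), numeric(1)),
    stringsAsFactors = FALSE
  )
  if (any(member_tab$mean_depth <= 0))
    abort_validation("member depths must be strictly positive")
  min_hap <- min(vapply(members, function(m) min(nchar(m$sequences)), integer(1)))
  if (read_length > min_hap)
    abort_validation("read_length exceeds the shortest genome")

  all_seq <- character(0); all_id <- character(0); all_origin <- character(0)
  for (m in members) {
    haps <- m$sequences
    L <- nchar(haps[[1]])
    n_reads <- round(m$mean_depth * L / read_length)
    if (paired) n_reads <- 2L * (n_reads %/% 2L)
    if (n_reads == 0) next
    # split evenly across haplotypes (each haplotype gets depth/ploidy)
    per_hap <- diff(round(seq(0, n_reads, length.out = length(haps) + 1)))
    for (h in seq_along(haps)) {
      n_h <- per_hap[h]
      if (n_h == 0) next
      hap <- haps[[h]]
      Lh <- nchar(hap)
      if (paired) {
        n_pairs <- n_h %/% 2L
        span <- min(insert_size, Lh)
        s <- sample.int(Lh - span + 1L, n_pairs, replace = TRUE)
        r1 <- substring(hap, s, s + read_length - 1L)
        r2 <- revcomp(substring(hap, s + span - read_length, s + span - 1L))
        base_id <- sprintf("%s_h%d_p%06d", m$genome_id, h, seq_len(n_pairs))
        ids <- as.vector(rbind(paste0(base_id, "/1"), paste0(base_id, "/2")))
        seqs <- as.vector(rbind(r1, r2))
      } else {
        s <- sample.int(Lh - read_length + 1L, n_h, replace = TRUE)
        seqs <- substring(hap, s, s + read_length - 1L)
        ids <- sprintf("%s_h%d_r%06d", m$genome_id, h, seq_len(n_h))
      }
      all_seq <- c(all_seq, seqs)
      all_id <- c(all_id, ids)
      all_origin <- c(all_origin, rep(m$genome_id, length(ids)))
    }
  }

  if (error_rate > 0 && length(all_seq) > 0) {
    big <- paste(all_seq, collapse = "")
    n_bases <- nchar(big)
    n_err <- rbinom(1L, n_bases, error_rate)
    if (n_err > 0) {
      pos <- sample.int(n_bases, n_err)
      big <- substitute_bases(big, pos)
    }
    offs <- c(0L, cumsum(nchar(all_seq)))
    all_seq <- substring(big, head(offs, -1) + 1L, offs[-1])
  }

  reads <- data.frame(id = all_id, seq = all_seq,
                      qual = strrep("I", nchar(all_seq)),
                      stringsAsFactors = FALSE)
  truth <- structure(list(
    members = member_tab,
    read_origins = data.frame(read_id = all_id, genome_id = all_origin,
                              stringsAsFactors = FALSE)
  ), class = "community_truth")
  list(reads = reads, truth = truth)
}

#' Fragment genomes into truth-labelled contigs
#'
#' Cuts each genome into non-overlapping, gap-free contigs whose lengths are
#' drawn from an exponential distribution tuned so the realized N50
#' approximates `target_n50` (the length-biased median of an exponential with
#' mean m is about 1.68 m). Contigs shorter than `min_length` are merged into
#' their left neighbour. Contig headers carry truth labels as
#' `id|genome=<genome_id>`.
#'
#' @param genomes named list/vector of genome sequences.
#' @param target_n50 target contig N50 in bases.
#' @param min_length minimum contig length (>= 4 so tetranucleotide profiles
#'   exist).
#' @param depths optional named vector of true depths per genome for the
#'   sidecar depth table.
#' @param seed integer seed.
#' @return list with `contigs` (named character; names are labelled headers)
#'   and `truth` (data.frame: `contig_id`, `genome_id`, `true_depth`).
#' @export
fragment_genomes <- function(genomes, target_n50, min_length = 500,
                             depths = NULL, seed = NULL) {
  check_scalar(target_n50, "target_n50", min = 4, integer = TRUE)
  check_scalar(min_length, "min_length", min = 4, integer = TRUE)
  if (target_n50 < min_length)
    abort_validation("target_n50 (", target_n50,
                     ") must be >= min_length (", min_length, ")")
  if (!is.null(seed)) set.seed(seed)
  genomes <- as.list(genomes)
  if (is.null(names(genomes)) || any(names(genomes) == ""))
    abort_validation("genomes must be named")

  contig_seqs <- character(0); contig_ids <- character(0)
  contig_genome <- character(0); contig_depth <- numeric(0)
  for (gid in names(genomes)) {
    g <- genomes[[gid]]
    L <- nchar(g)
    if (L <= target_n50) {
      lens <- L
    } else {
      mean_len <- max(min_length, target_n50 / 1.678)
      draws <- pmax(min_length, round(rexp(ceiling(3 * L / mean_len), 1 / mean_len)))
      cum <- cumsum(draws)
      n_take <- which(cum >= L)[1]
      lens <- draws[seq_len(n_take)]
      lens[n_take] <- lens[n_take] - (cum[n_take] - L)
      if (length(lens) > 1 && lens[n_take] < min_length) {
        lens[n_take - 1] <- lens[n_take - 1] + lens[n_take]
        lens <- lens[-n_take]
      }
    }
    bounds <- c(0, cumsum(lens))
    seqs <- substring(g, head(bounds, -1) + 1, bounds[-1])
    ids <- sprintf("%s_c%05d", gid, seq_along(seqs))
    contig_seqs <- c(contig_seqs, seqs)
    contig_ids <- c(contig_ids, ids)
    contig_genome <- c(contig_genome, rep(gid, length(seqs)))
    d <- if (!is.null(depths)) unname(depths[gid]) else NA_real_
    contig_depth <- c(contig_depth, rep(d, length(seqs)))
  }
  names(contig_seqs) <- sprintf("%s|genome=%s", contig_ids, contig_genome)
  truth <- data.frame(contig_id = contig_ids, genome_id = contig_genome,
                      true_depth = contig_depth, stringsAsFactors = FALSE)
  list(contigs = contig_seqs, truth = truth)
}

#' Strip truth labels from contig headers
#'
#' @param headers character vector of `id|genome=<genome_id>` headers.
#' @return data.frame with `contig_id` and `genome_id` (NA when unlabelled).
#' @export
parse_contig_labels <- function(headers) {
  has <- grepl("\\|genome=", headers)
  data.frame(
    contig_id = sub("\\|genome=.*$", "", headers),
    genome_id = ifelse(has, sub("^.*\\|genome=", "", headers), NA_character_),
    stringsAsFactors = FALSE
  )
}
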