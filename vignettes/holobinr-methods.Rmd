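---
title: "Methods: host genome recovery from holobiont sequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: host genome recovery from holobiont sequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Many hosts — reef-building corals are the canonical case — live as
*holobionts*: the animal plus photosynthetic dinoflagellates, bacteria,
archaea, fungi and viruses, all physically inseparable at sampling time.
Shotgun sequencing of such a sample yields a *hologenome*: a mixture of the
diploid host genome and many smaller genomes of very different base
composition and abundance. `holobinr` implements the in-silico route from
such a mixed read set to a host draft genome and its evaluation:

1. **k-mer spectrum analysis** — genome size, heterozygosity, error and
   repeat content, estimated without an assembly;
2. **binning** — separating host from symbiont contigs by tetranucleotide
   composition plus coverage, and recruiting the host's reads;
3. **assembly assessment** — contiguity, completeness-proxy, and
   "usefulness" metrics, compared across assemblies with a direction-signed
   z-score framework.

A synthetic holobiont generator with known ground truth replaces raw
sequencing data, so every stage has a parameter-recovery test surface.

# The synthetic holobiont generator

`simulate_host_genome()` builds a diploid host: haplotype A is random
background sequence (order-2 Markov chain at a target GC, default 0.39 — a
typical anthozoan value) with dispersed repeat families planted into it;
haplotype B substitutes bases independently at the heterozygosity rate
`het_rate`, never replacing a base with itself and drawing uniformly from the
three alternatives. Repeat families each contribute 10 dispersed copies of a
unit drawn once per family (default unit 500 bp); the last copy is truncated
so planted repeat bases hit `repeat_fraction * haploid_length` exactly. Ten
copies per family put repeat k-mers at roughly ten times the homozygous
depth, producing the high-coverage shoulder a repeat-rich spectrum shows.

`simulate_symbiont_genomes()` draws each genome from its own perturbed
order-2 Markov chain targeted at the requested GC, then repairs realized GC
by uniform-position swaps. This gives every genome a distinct
tetranucleotide signature — the signal composition-based binning exploits —
while holding GC on target to within about 1.5 percentage points.

`simulate_reads()` samples uniform-coverage reads (optionally paired with a
fixed insert) with a flat per-base substitution error rate and constant Q40
qualities. The flat error model is a deliberate stand-in: no quality-aware
stage exists downstream, and the real error profile of the sequencing
instrument is not modeled. Diploid members are split evenly across
haplotypes, so a member at 60x gives each haplotype 30x.
`fragment_genomes()` cuts genomes into gap-free, non-overlapping contigs
with exponential lengths tuned so the realized N50 approximates the target
(the length-biased median of an exponential with mean $m$ is $\approx 1.68m$),
carrying truth labels in the FASTA headers.

**What the generator does not emulate:** indels and structural variation,
GC-biased coverage, quality-score error profiles, chimeric inserts, and
within-genome composition heterogeneity (horizontal transfer, mobile
elements). Passing recovery tests on this generator therefore demonstrates
correctness of the estimators under their stated models, not robustness to
every artifact of real libraries.

# The k-mer spectrum model

All k-mer work uses canonical k-mers (the lexicographic minimum of a window
and its reverse complement), counted exactly in memory; k is capped at 26 so
packed 2-bit codes remain exact in doubles, and the intended scale is up to
roughly $10^8$ distinct k-mers. The default k grid is {17, 19, 21, 23, 25}
with 21 as the headline size.

For a diploid genome sequenced at total depth $2\lambda$, distinct k-mers
fall into a *heterozygous* component at the haploid depth $\lambda$ (k-mers
overlapping a variant exist on one haplotype only) and a *homozygous*
component at $2\lambda$; higher components are duplicated sequence, a
low-depth spike is sequencing error, and a far tail is high-copy repeat.

`detect_peaks()` smooths the histogram with a moving average (window 5
depth units) and reports: the error cutoff `e` (the valley between depth 1
and the first significant peak), $\lambda$, and $c_{hom}$. Peak
significance is measured relative to the tallest *interior* maximum — not
the monotone error spike at the boundary — with a 5% relative-height floor
that keeps sparse noise maxima in the repeat tail from counting as peaks.
Peak pairing handles both height orders: if a second maximum sits near twice
the tallest peak the tallest is $\lambda$; if one sits near half, the
tallest is $c_{hom}$. A genuinely single-peaked spectrum is reported as
$c_{hom}$ with $\lambda = c_{hom}/2$ and a `unimodal` flag — the right
reading both for haploid samples and for diploids with negligible
heterozygosity, where essentially all k-mer mass is homozygous.

Three estimators then report haploid genome size on the same scale,
$G = \sum_{c \ge e} c\,h(c) / (2\lambda)$ (equivalently the filtered total
mass over the homozygous depth):

* **Lander–Waterman** (`waterman_size()`): the closed-form ratio with
  $c_{hom}$ from peak detection. Dividing by the homozygous peak rather
  than the tallest peak keeps all three methods on a haploid scale.
* **Poisson mixture EM** (`fit_poisson_em()`): the distinct-k-mer
  distribution at depths $\ge e$ is fitted as
  $\sum_i w_i\,\mathrm{Poisson}(c;\, i\lambda)$ by EM. The log-likelihood is
  non-decreasing by construction and iteration stops below $10^{-8}$
  improvement (cap 500 iterations, returning the best fit with a warning if
  hit). The fit is restricted to depths $\le 2.4\,m\lambda_0$: high-copy
  repeat k-mers sit many multiples of $\lambda$ beyond the mixture's reach,
  and without the cap their responsibilities drag $\lambda$ upward. The
  genome-size numerator still uses all filtered depths, so repeat mass
  counts toward $G$.
* **Negative-binomial mixture** (`fit_nb_mixture()`): least-squares fit of
  $h(c) \approx D' \sum_i w_i\,\mathrm{NB}(c;\, \mu = i\lambda,\,
  \mathrm{size} = \theta)$ by Levenberg–Marquardt on an unconstrained
  parameterization (log $\lambda$, log $\theta$, softmax weights, log $D'$).
  A single dispersion $\theta$ is shared across components to keep the fit
  identifiable on small histograms; on uniform-coverage simulations
  $\theta$ runs to the Poisson limit, which is expected and harmless. The
  fitting grid extends to $4m\lambda_0$ so the distant repeat tail does not
  dominate the residuals.

Heterozygosity comes from the mixture weights: a heterozygous locus
contributes *two* distinct k-mers to the $\lambda$ component, so the
heterozygous fraction of k-mer loci is
$p_{het} = (w_1/2) / (w_1/2 + \sum_{i\ge2} w_i)$ and the per-base rate is
$r = 1 - (1 - p_{het})^{1/k}$.

Error and repeat shares are mass ratios: the error fraction is the share of
total occurrences below `e`; the repeat fraction is the share of *filtered*
occurrences above the repeat cutoff $\rho$, default $\rho = 4\,c_{hom}$
(e.g., a 63x homozygous peak gives $\rho = 252$). Both cutoffs are
data-driven with manual overrides, since the valley and the tail onset are
properties of each dataset, not constants.

`consensus_size()` takes the median (and sample SD) across estimates, and
`kruskal_wallis()` (a thin wrapper over the tie-corrected rank test)
compares estimate groups across k sizes or methods.

# Binning and read recruitment

Contigs are featurized by canonical tetranucleotide frequency (136 classes
after reverse-complement collapsing) and by an alignment-free coverage: the
median, along the contig, of the read-set count of the canonical k-mer at
each position. Using a k-mer median instead of read mapping removes a
mapper dependency; it reads about 8% below nominal read depth (edge losses
of $(k-1)$ windows per read plus error attrition), which is immaterial for
binning because the scale cancels in depth *ratios*.

The pairwise contig distance is

$$d(i,j) = w\,\lVert \mathrm{tnf}_i - \mathrm{tnf}_j \rVert_2 +
(1-w)\,\frac{|\log_{10}(d_i+1) - \log_{10}(d_j+1)|}{\log_{10}(d_{max}+1)}$$

with composition weight $w = 0.7$. Contigs with $d \le \tau$ are linked and
connected components become bins (single linkage) — a deliberately simple,
deterministic reading of composition-plus-abundance binning, not a clone of
any production binner's iterated medoid machinery. Components below
`min_bin_size` (200 kb at survey scale, 20–50 kb in the bundled test
profiles) stay unbinned, as do contigs under 2 kb, whose tetranucleotide
vectors are too noisy.

The default $\tau = 0.025$ comes from the measured distance structure on
communities of ~5 kb contigs: the largest single-linkage MST edge *within*
a genome is about 0.018, while the smallest *between*-genome distance is
about 0.039 even at a 5-point GC gap, so 0.025 sits between the two with
margin on both sides. Shorter contigs or very close compositions will
require a larger $w$-adjusted threshold or more depth samples.

Host bins are selected either by truth labels (simulation mode) or by a
heuristic: the largest bin plus every bin within 3 GC percentage points and
a 2x depth factor of it. Reads are recruited to the host when at least a
fraction $\theta$ (default 0.5) of a read's canonical k-mers occur in the
host-bin k-mer set; mates are recruited jointly when either qualifies,
mirroring mate rescue in mappers.

# Assembly assessment

`assembly_metrics()` computes the standard contiguity statistics (N50/L50
at scaffold and contig level, contigs from splitting at runs of $\ge 10$
Ns, QUAST-like), NG50 against an estimated genome size, GC over non-N bases
(non-ACGTN symbols count as N), N content, contigs over 10 kb, and the
*usefulness* criterion: the percentage of the estimated genome contained in
scaffolds at least as long as an average gene — 7 kb for invertebrates (the
value `mean_gene_length()` reproduces from annotation sets), 25 kb for
vertebrates. NG50 uses each assembly's own size estimate.

`marker_recovery()` is a completeness proxy replacing external single-copy
ortholog pipelines: a marker is *complete* when one scaffold contains at
least 90% of its distinct canonical k-mers, *fragmented* when only the
union of scaffolds does, *missing* otherwise.

`compare_assemblies()` builds a parameters-by-assemblies matrix, computes
direction-signed z-scores per parameter ($z = \pm(x - \bar x)/s$, sample
SD; zero-spread rows give zero), sums them per operational criterion
(completeness, contiguity, usefulness — membership is config-driven so the
parameter list can be swapped), and labels each assembly per criterion:
*good* at $\ge$ median + 1 SD of the cumulative scores, *poor* at $\le$
median − 1 SD, *average* otherwise. Two readings of "modified z-score"
exist in the assembly-evaluation literature; the mean/SD, direction-signed
reading is the default and a median/MAD variant is available behind
`robust = TRUE` (whose rows need not sum to zero). The SD-from-median
classification is applied to the cumulative criterion scores.

# Numerical and design notes

* Alphabet is uppercase ACGT (analyses upcase internally; ambiguity codes
  are never generated and non-ACGT windows are skipped in k-mer work).
* All randomness flows through explicit `seed` arguments; the pipeline
  driver derives per-stage seeds from one root seed, and reruns are
  byte-identical including gzipped outputs.
* EM ties are broken by initialization: both mixture fits start from the
  detected peaks (overridable), which anchors component 1 to the haploid
  depth and keeps the single-peak case labeled homozygous.
* Degenerate inputs: empty k-mer tables yield empty histograms; a spectrum
  with all mass below depth 3 raises a "no signal peak" error; a
  single-value consensus reports SD 0 with a flag; zero-spread z-score rows
  are all-zero; an assembly with no genome-size estimate reports NG50 and
  usefulness as NA.
* Validation errors, parse errors, and stage failures carry distinct
  condition classes, which the command-line wrapper maps to exit codes 2, 3
  and 4.

# Scale of the bundled benchmarks

The recovery benchmarks run at desk scale, chosen to exercise every code
path while keeping the default test suite fast: a 2 Mb diploid host at 60x
(0.5% error, 15% repeats, heterozygosity 0–1%) for the spectrum estimators,
and a 2 Mb six-member community (host 1 Mb at 70x; symbionts 100–300 kb,
GC 30–65%, 10–40x; ~5 kb contigs) for binning and recruitment. On these
conditions the estimators land within a few percent of planted genome size,
heterozygosity within a third of a point, repeat share within ~2 points,
binning F1 and recruitment precision/recall near 1. Field-scale datasets
(hundreds of millions of reads) are outside the exact in-memory counter's
intended range; the counting stage is the piece to swap for a disk-backed
counter if that scale is needed, since every downstream stage consumes only
the histogram or code tables.

# Known limitations

* The binner is single-sample by default; multiple depth columns are
  accepted but only the first drives the distance (differential-coverage
  binning across many samples is out of scope).
* The NB fit's shared dispersion underfits spectra whose heterozygous and
  homozygous components have very different overdispersion.
* Marker recovery counts k-mer containment, not orthology: paralogs and
  repeats inflate "complete" calls on real data.
* The heuristic host-bin selector assumes host bins dominate total length
  and share GC/depth; symbiont-dominated samples need truth labels or
  manual inspection.
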