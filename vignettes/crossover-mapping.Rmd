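---
title: "Haplotype maps and fine-scale crossover localization with xomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype maps and fine-scale crossover localization with xomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xomap)
```

# The problem

A one-way pseudo-testcross crosses a heterozygous parent to a (near-)inbred
parent.  Every marker that is heterozygous in the first parent segregates
1:1 in the F1, and each F1 individual inherits one recombinant haplotype
from the heterozygous parent.  Tracking which parental haplotype each
individual carries along every chromosome therefore reveals the positions
of meiotic crossovers, and pooling hundreds of crossovers over a population
yields a fine-scale recombination landscape that can be interrogated for
associations with genes, chromatin and transposable elements.

The difficulty is that whole-genome re-sequencing of large populations is
economical only at low coverage (~2x per individual).  At that depth, hard
genotype calls are noisy in a very structured way: at a truly heterozygous
site the probability that only the reference allele is sampled is
`2^-depth`, so heterozygotes are frequently miscalled as homozygous
reference ("allele dropout"), and sequencing errors occasionally produce
impossible homozygous-alternative calls.  `xomap` implements a pipeline
that is robust to this noise:

1. **variants** — an SNV filtering cascade;
2. **phasing** — sliding-window LD phasing of the heterozygous parent;
3. **window calling** — a binomial/Bayes caller that turns noisy per-SNV
   haplotype labels into confident per-window calls;
4. **skeleton bins** — merging identically segregating windows;
5. **crossover localization** — logistic-regression breakpoint intervals;
6. **recombination maps** — Marey maps and spline-interpolated cM/Mb
   tracks;
7. **enrichment** — interval statistics around crossovers (Monte-Carlo
   shuffle tests, matched cold regions, transposon-family Fisher tests,
   aggregate profiles, binned correlations, Poisson goodness-of-fit and a
   crossover-count GLM).

A meiosis + sequencing simulator with full ground truth
(`simulate_parents()`, `simulate_meiosis()`, `simulate_population()`,
`simulate_annotation()`) is a first-class component: every stage of the
pipeline is validated end-to-end against simulations whose assumptions are
stated below.

# The filtering cascade

Filters are applied in a fixed order; each sees the previous stage's
output (`filter_variants()` wires them together):

* **Repeat masking** (`mask_repeats()`): sites whose 1-bp position
  intersects a repeat interval are removed.
* **Segregation distortion** (`filter_segregation()`): per site, hom-ref
  vs het counts are tested by a chi-square goodness of fit with
  Benjamini–Hochberg control at FDR 0.05.  The Mendelian expectation is
  1:1, but with hard calls at low coverage *every* site's observed ratio
  shifts toward hom-ref by the dropout probability `E[2^-d]`.  Testing
  against a strict 1:1 at realistic population sizes would therefore
  reject most honest sites.  The cascade's default is the *empirical*
  expectation — the genome-wide mean hom-ref:het ratio — which targets
  relative distortion (the biologically meaningful signal, e.g. a
  distorted chromosome arm) and stays calibrated at any coverage.  The
  strict `c(1, 1)` expectation remains available and is the default of the
  standalone `filter_segregation()`.
* **Linkage disequilibrium** (`filter_ld()`): markers in a bi-parental
  population must be tightly linked to their neighborhood.  For each site
  up to 25 partners are sampled uniformly from a physical distance band
  and r² is the squared Pearson correlation of genotype codes over
  pair-wise complete individuals (minimum 10 shared observations); sites
  with median r² below 0.2 are removed.  The distance band is a
  genome-scale parameter: its default (1–10,000 kb) suits chromosomes of
  tens of Mb at ~1 cM/Mb.  On the short, recombination-dense chromosomes
  of the bundled simulations (5 Mb at ~20 cM/Mb) the same *genetic* reach
  corresponds to roughly 1–100 kb, which is what the test suite uses;
  users should scale the band so that its upper end spans no more than a
  few cM.
* **Depth-aware missingness** (`apply_depth_missing()`): hom-ref calls
  with depth below 2 (or 5 for higher-coverage populations) are set
  missing — they are the calls allele dropout contaminates.
* **Per-site missingness** (`filter_missingness()`): sites with more than
  40% (large low-coverage population) or 5% (small high-coverage
  population) missing calls are removed.
* **Hom-alt conversion** (`convert_homalt()`): homozygous-alternative
  calls are impossible in a testcross without error; they are recoded het
  and their fraction among non-missing calls is the empirical genotyping
  error rate `E_T` consumed by the window caller.

# Phasing and the Bayes window caller

`phase_snvs()` phases the heterozygous parent chromosome-by-chromosome:
the first SNV sets the phase arbitrarily (haplotype labels are only
defined up to a global flip, and all downstream results are invariant
under it), and each subsequent SNV is oriented against the already-phased
anchor with the highest r² among the trailing 99 markers, by majority
concordance of the two genotype columns over shared individuals.  Exact
concordance ties fall back to the anchor's orientation, deterministically,
and are logged.

`genotype_to_haplotype()` then labels every individual at every SNV with
the parental haplotype carrying its observed allele.  These labels carry
the dropout noise of the genotypes, which is what the window caller
absorbs.  Within a 50-SNV window shifted 5 SNVs at a time, for an
individual with `n` non-missing labels of which `k` disagree with
haplotype 1, the two hypotheses are compared through binomial likelihoods:

$$P(k \mid hap1) = \binom{n}{k} E_T^k (1 - E_T)^{n-k}, \qquad
  P(k \mid hap2) = \binom{n}{n-k} E_T^{n-k} (1 - E_T)^{k},$$

with a flat prior `P(hap1) = P(hap2) = 0.5` and the call taken at the
maximum posterior.  (The second likelihood substitutes `n - k`: `k`
discordances with haplotype 1 are `n - k` discordances with haplotype 2;
this is the only reading under which the posterior is informative.)
Windows with fewer than 5 non-missing labels, or with exactly symmetric
evidence `k = n/2`, are missing — symmetric evidence carries no
information, and the posterior then equals the prior exactly, a property
the test suite checks against brute-force enumeration at 1e-12.

`build_skeleton()` merges maximal runs of windows with identical
cross-individual call vectors into skeleton bins.  Missing window calls
are bridged per individual by carrying the nearest confident call, so
low-coverage gaps do not fragment bins; bridged spans are flagged.

# Crossover localization

`find_transitions()` emits one candidate per individual per adjacent bin
pair with differing calls, discarding candidates whose flanking bins do
not physically overlap or abut (a guard against misassembled scaffolds).
`localize_crossover()` fits a logistic regression of the binary haplotype
label on SNV position across the two flanking bins.  The probability of a
crossover between two adjacent SNVs is the absolute difference of their
fitted probabilities; the interval is seeded at the maximal pair and grown
one SNV at a time toward whichever side most increases the endpoint-pair
difference, stopping beyond 0.95.

Two numerical choices matter here.  Positions are centered and scaled by
the *median marker gap*, which makes the attainable steepness independent
of marker density; and the slope carries a small L2 penalty (1e-4), so the
fit stays finite under perfect separation while a clean switch across one
typical gap still attains a crossover probability of about 0.96 — i.e. on
error-free data the returned interval is exactly the two SNVs flanking the
switch, which the tests verify against a direct scan.  If the threshold is
never reached the widest interval is returned flagged `low_confidence`.
`merge_fine()` pools populations and keeps intervals with resolution
strictly below 5 kb ("fine-resolution").

# Recombination maps

`genetic_positions()` treats every called window as a genetic marker at
its physical midpoint.  The recombination fraction between adjacent
markers is the fraction of individuals whose calls differ among those
informative at both, accumulated through Haldane's map function by default
(no interference, matching the Poisson simulator; Kosambi is available).
Missing calls are bridged as in skeleton construction — otherwise a
haplotype switch across a low-coverage gap contributes no map distance and
the total map shrinks by 15–20% in our simulations.

`interpolate_rate()` fits a cubic smoothing spline of cM against bp
(smoothing chosen by generalized cross-validation unless `spar` is given)
and differences it on a fixed 100-kb grid.  The fitted curve is clamped to
the observed cM range and monotonized with a running maximum before
differencing: negative spline wiggles become zero-rate windows (counted
and logged) while the windowed rates still integrate to the chromosome map
length — the tests require conservation within 1%.

# Enrichment statistics

All interval statistics use 1-bp minimum overlap, and a query counts
toward every feature class it touches (per-class rates therefore need not
sum to 1).  Empirical p-values from permutations use the add-one estimator
`(1 + r)/(1 + n_perm)`, which is floored at `1/(n_perm + 1)` and uniform
under the null — the suite checks uniformity by a KS test on a null
construction.

* `shuffle_mc()` places length-matched intervals uniformly at random,
  preserving each interval's chromosome by default (a genome-wide mode is
  available); permutations are materialized in blocks so one overlap query
  serves many permutations.
* `sample_cold_regions()` rejection-samples, for each crossover, a control
  region with (i) GC within 10% (relative), (ii) 10–1000 kb from any
  crossover, (iii) identical length, (iv) SNV density within 10%
  (relative), (v) on the same chromosome.  The 10% bands are read as
  relative: an absolute 10-percentage-point band on SNV density would be
  nearly unconstraining.  Failures are reported per region with the
  criterion that failed most; `validate_cold_regions()` independently
  re-checks every emitted region.
* `te_family_fisher()` runs per-family two-sided Fisher tests of
  element-containing interval counts, crossovers vs cold regions, with
  Bonferroni correction across families.
* `aggregate_profile()` computes metagene-style profiles: bodies split
  into 50 windows normalized per nucleotide, flanks in fixed 10-bp (or
  25-bp) bins up to 5 kb, strand-aware, with an optional ±2 SD band from
  100 permutations.
* `binned_stats()` bins signal tracks at 100 kb or 1 Mb and reports
  Spearman correlations (ties mid-ranked) genome-wide and per chromosome;
  `normalize_snv_track()` provides the coverage-adjusted SNV density
  normalizer.
* `poisson_fit_counts()` fits a Poisson by the mean crossover count per
  chromosome and tests observed 0/1/2/≥3 category counts by a multinomial
  chi-square with tail pooling.
* `glm_crossovers()` fits a log-link Poisson GLM of windowed crossover
  counts on genomic/chromatin covariates, reports the sequential deviance
  table, drops rank-deficient covariates with a warning, logs an
  overdispersion check and offers a quasi-Poisson fallback.
* `promoter_quartile_analysis()` compares Stowaway counts between
  promoters over the top and bottom recombination-rate quartiles (Wilcoxon
  rank-sum) and the mean window-scaled rate of element-bearing promoters
  against a Monte-Carlo null of nearby (≤ 500 kb) element-free promoters.

# What the simulator does and does not emulate

`simulate_population()` draws, per individual, a gamete with
per-chromosome crossover counts `~ Poisson(λ)` (no interference; an
obligate crossover is *not* enforced) and positions i.i.d. from a
discretized density on `[0, 1]` — by default a symmetric U-shape that
concentrates crossovers distally, as in large plant chromosomes.  A
crossover pair landing in the same inter-SNV gap cancels and is invisible
to any marker-based method, so the recorded truth keeps exactly the
breakpoints present in the gamete (the haplotype-switch invariant is
exact).  Sequencing is depth `~ Poisson(coverage)` with per-read error;
a hom-alt call arises only at truly hom-ref sites when all reads are
errors, which gives the `E_T` estimator a closed-form target the tests
verify.  Missingness beyond zero-depth is i.i.d. per call.

Real data differ in ways the simulator deliberately omits: mapping
artifacts and repeat-driven error clustering, depth correlation along the
genome and between individuals, reference bias, indel miscalls, crossover
interference, and segregation distortion with a biological cause.  Passing
tests therefore demonstrate the statistical machinery is correct under its
stated model, not that every real-data pathology is handled.

The validation conditions used by the test suite are 90 individuals,
12 chromosomes × 5 Mb at 1000 SNVs/Mb, λ = 1 crossover per chromosome,
2x coverage, 1% base error and a 40% missingness cap.  Under these
conditions the pipeline recovers ~95% of true crossovers, every returned
interval is checked for containing its true breakpoint (≥ 95% required),
and the total map length lands within 10% of the expected
`100·λ·12 = 1200 cM`.  Larger simulations behave the same but are kept out
of the default suite to keep it fast.

# Known limitations

* Double crossovers within a single window span cancel and are undetected
  by construction; with λ = 1 per chromosome this loses a few percent of
  events, concentrated where the crossover density is highest.
* Crossovers inside the first or last half-window of a chromosome have no
  flanking bin on one side and are missed.
* The interval resolution under heavy allele dropout is limited by the
  label noise, not by marker spacing: the logistic transition width grows
  with the discordance rate.  Resolution improves directly with coverage.
* The LD filter's distance band and the spline smoothing parameter are
  genome-scale parameters; defaults suit large chromosomes and the
  documentation states how to scale them.
* `E_T` measures the spurious hom-alt rate, which underestimates the
  haplotype-label discordance caused by allele dropout.  The window
  caller is insensitive to this (the argmax posterior is a majority vote
  for any `E_T < 0.5`), but the attained `P_max` values should not be
  read as calibrated probabilities at low coverage.
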