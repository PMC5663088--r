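## Shared in-code fixtures.  Expensive simulations are built once per suite
## run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

## Clean, essentially error-free population: deep coverage, no base error.
## Truth recovery should be exact (up to the global haplotype flip).
clean_sim <- function() cached("clean_sim", {
  layout <- genome_layout(c("chr1", "chr2"), c(1e6, 1e6))
  parents <- simulate_parents(layout, snv_density = 300, seed = 71)
  sim <- simulate_population(parents, n_individuals = 40, lambda_co = 0.8,
                             density_profile = co_density_uniform(),
                             coverage = 30, base_error = 0,
                             seed = 72)
  list(layout = layout, parents = parents, sim = sim)
})

## Labels derived from the clean population through the public path.
clean_labels <- function() cached("clean_labels", {
  cs <- clean_sim()
  conv <- convert_homalt(cs$sim$matrix)
  ph <- phase_snvs(conv$matrix)
  list(matrix = conv$matrix, phased = ph,
       labels = genotype_to_haplotype(conv$matrix, ph),
       E_T = conv$error_rate)
})

## Noisy low-coverage population mirroring the study conditions at reduced
## scale (2 chromosomes instead of 12).
noisy_sim <- function() cached("noisy_sim", {
  layout <- genome_layout(c("chr1", "chr2"), c(5e6, 5e6))
  parents <- simulate_parents(layout, snv_density = 1000, seed = 81)
  sim <- simulate_population(parents, n_individuals = 90, lambda_co = 1,
                             coverage = 2, base_error = 0.01, seed = 82)
  list(layout = layout, parents = parents, sim = sim)
})

## Full pipeline run on the noisy population (shared by the crossover and
## map tests).
noisy_pipeline <- function() cached("noisy_pipeline", {
  ns <- noisy_sim()
  filt <- filter_variants(ns$sim$matrix, ld_dist_range = c(1e3, 1e5),
                          seed = 53)
  ph <- phase_snvs(filt$matrix)
  lab <- genotype_to_haplotype(filt$matrix, ph)
  wc <- call_windows(lab, E_T = filt$error_rate)
  sk <- build_skeleton(wc)
  co <- call_crossovers(sk, lab)
  list(filt = filt, lab = lab, wc = wc, sk = sk, co = co)
})

## Truth orientation (alt_on_hap1) aligned to the site set of a matrix.
truth_orientation <- function(parents, m) {
  key_p <- paste(parents$sites$chrom, parents$sites$pos)
  key_m <- paste(m$sites$chrom, m$sites$pos)
  parents$sites$alt_on_hap1[match(key_m, key_p)]
}

## Fraction of crossover intervals containing a matching true breakpoint.
containment_rate <- function(co, truth) {
  if (!nrow(co)) return(NA_real_)
  hit <- logical(nrow(co))
  for (r in seq_len(nrow(co))) {
    t2 <- truth[truth$individual == co$individual[r] &
                  truth$chrom == co$chrom[r], ]
    hit[r] <- nrow(t2) > 0 &&
      any(t2$pos >= co$left[r] & t2$pos <= co$right[r])
  }
  mean(hit)
}

## Build a minimal hap_labels object directly from a designed label matrix
## (individuals x sites), positions and chromosome vector.
make_labels <- function(L, pos, chrom = "chr1") {
  sites <- data.frame(chrom = rep(chrom, length.out = length(pos)), pos = pos,
                      ref = "A", alt = "T")
  structure(list(sites = sites,
                 labels = matrix(as.integer(L), nrow(L), ncol(L),
                                 dimnames = list(rownames(L), NULL)),
                 alt_on_hap1 = rep(TRUE, length(pos)),
                 individuals = rownames(L) %||%
                   paste0("ind", seq_len(nrow(L)))),
            class = "hap_labels")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Toy snv_matrix with specified genotype codes (individuals x sites).
make_matrix <- function(geno, pos = NULL, chrom = "chr1", depth = NULL) {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq_len(ncol(geno)) * 1000
  if (is.null(depth)) depth <- matrix(10L, nrow(geno), ncol(geno))
  snv_matrix(data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T"),
             geno, depth)
}
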