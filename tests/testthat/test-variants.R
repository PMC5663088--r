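test_that("VCF genotypes load with the documented code mapping", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "s1", "s2", "s3", sep = "\t"),
    paste("chr1", "100", ".", "A", "T", ".", "PASS", ".", "GT:DP",
          "0/0:4", "0/1:2", "1/1:3", sep = "\t"),
    paste("chr1", "200", ".", "G", "C", ".", "PASS", ".", "GT:DP",
          "./.:0", "1|0:5", "0/0:1", sep = "\t")), vcf)
  m <- load_genotypes(vcf)
  expect_identical(dim(m$geno), c(3L, 2L))
  expect_identical(unname(m$geno[, 1]), c(0L, 1L, 2L))
  expect_identical(unname(m$geno[, 2]), c(NA_integer_, 1L, 0L))
  expect_identical(unname(m$depth[, 2]), c(0L, 5L, 1L))
  ## duplicate positions are named in the error
  dup <- sub("200", "100", readLines(vcf))
  vcf2 <- tempfile(fileext = ".vcf"); writeLines(dup, vcf2)
  expect_error(load_genotypes(vcf2), "chr1 100")
})

test_that("VCF write/read round trip is the identity", {
  cs <- clean_sim()
  m <- cs$sim$matrix
  path <- tempfile(fileext = ".vcf")
  write_snv_vcf(m, path, cs$layout)
  m2 <- load_genotypes(paste0(path, ".gz"))
  expect_identical(unname(m2$geno), unname(m$geno))
  expect_identical(unname(m2$depth), unname(m$depth))
  expect_identical(m2$sites[c("chrom", "pos", "ref", "alt")],
                   m$sites[c("chrom", "pos", "ref", "alt")])
})

test_that("repeat masking removes sites by 1-bp intersection", {
  m <- make_matrix(matrix(1L, 2, 5), pos = c(5, 11, 15, 20, 21))
  ## empty set: identity
  expect_identical(mask_repeats(m, GenomicRanges::GRanges()), m)
  ## BED half-open convention: chr1 10-20 covers 1-based 11..20
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20", bed)
  out <- mask_repeats(m, bed)
  expect_identical(out$sites$pos, c(5, 20 + 1))
  ## full cover empties the matrix with a warning
  all_bed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100))
  expect_warning(out2 <- mask_repeats(m, all_bed), "empty")
  expect_identical(ncol(out2$geno), 0L)
})

test_that("segregation distortion test matches chi-square and BH oracles", {
  ## 45:45 -> statistic 0, retained
  g <- rbind(matrix(0L, 45, 1), matrix(1L, 45, 1))
  r <- filter_segregation(make_matrix(g))
  expect_equal(r$stats$p, 1)
  expect_false(r$stats$removed)
  ## 90:0 -> removed at any reasonable FDR
  r2 <- filter_segregation(make_matrix(matrix(0L, 90, 1)))
  expect_true(r2$stats$removed)
  expect_lt(r2$stats$p, 1e-10)
  ## BH step-up on a 5-site toy equals the brute-force procedure
  counts <- list(c(30, 30), c(45, 15), c(40, 20), c(25, 35), c(55, 5))
  g5 <- do.call(cbind, lapply(counts, function(cc)
    c(rep(0L, cc[1]), rep(1L, cc[2]))))
  r5 <- filter_segregation(make_matrix(g5), fdr = 0.05)
  p <- r5$stats$p
  o <- order(p, decreasing = TRUE)
  manual <- numeric(5); prev <- 1
  for (i in seq_along(o)) {
    v <- min(prev, p[o[i]] * 5 / (5 - i + 1))
    manual[o[i]] <- v; prev <- v
  }
  expect_equal(r5$stats$p_adj, manual)
  ## all-missing site is retained with NA p
  gna <- cbind(g5[, 1], NA_integer_)
  rna <- filter_segregation(make_matrix(gna))
  expect_true(is.na(rna$stats$p[2]))
  expect_identical(ncol(rna$matrix$geno), 2L)
  ## empirical expectation recenters the test under uniform undercalling
  skew <- matrix(rbinom(90 * 40, 1, 0.3), 90, 40)
  rskew <- filter_segregation(make_matrix(skew), expected = "empirical")
  expect_lt(sum(rskew$stats$removed), 3)
})

test_that("LD filter keeps linked and drops unlinked sites", {
  set.seed(31)
  ## duplicated site column has r^2 = 1 with its duplicate
  x <- rbinom(60, 1, 0.5)
  m <- make_matrix(cbind(x, x, x), pos = c(1000, 3000, 5000))
  r <- filter_ld(m, dist_range = c(1e3, 1e5), seed = 1)
  expect_equal(r$stats$median_r2, rep(1, 3))
  expect_false(any(r$stats$removed))
  ## independent random genotypes: median r^2 near 0, removed
  G <- matrix(rbinom(90 * 40, 1, 0.5), 90, 40)
  m2 <- make_matrix(G, pos = seq_len(40) * 2000)
  r2 <- filter_ld(m2, dist_range = c(1e3, 1e5), seed = 2)
  expect_gt(mean(r2$stats$removed), 0.9)
  ## error-free testcross chromosome: perfect linkage, all retained
  cl <- clean_labels()
  sub <- cl$matrix
  keep <- sub$sites$chrom == "chr1"
  sub <- xomap:::subset_sites(sub, keep)
  r3 <- filter_ld(sub, dist_range = c(1e3, 1e5), seed = 3)
  expect_false(any(r3$stats$removed))
  ## site with no partner in band is retained and flagged
  m4 <- make_matrix(cbind(x, x), pos = c(1000, 2e6))
  r4 <- filter_ld(m4, dist_range = c(1e3, 1e5), seed = 4)
  expect_true(all(r4$stats$no_partner))
  expect_identical(ncol(r4$matrix$geno), 2L)
})

test_that("depth and missingness filters follow their thresholds", {
  g <- rbind(c(0L, 1L, 0L), c(0L, 1L, NA))
  d <- rbind(c(1L, 1L, 5L), c(2L, 0L, 0L))
  m <- make_matrix(g, depth = d)
  ## min_depth 0: identity
  expect_identical(apply_depth_missing(m, 0)$geno, m$geno)
  ## hom-ref at depth 1 becomes missing under the "< 2" threshold;
  ## het at depth 1 is untouched
  out <- apply_depth_missing(m, 2)
  expect_true(is.na(out$geno[1, 1]))
  expect_identical(unname(out$geno[1, 2]), 1L)
  expect_identical(unname(out$geno[2, 1]), 0L)
  ## missingness: strictly-above-threshold sites are removed
  gm <- rbind(c(0L, NA, 0L), c(NA, NA, 0L))  # 50%, 100%, 0% missing
  mm <- make_matrix(gm)
  expect_identical(ncol(filter_missingness(mm, 1)$geno), 3L)
  out2 <- filter_missingness(mm, 0.4)
  expect_identical(out2$sites$pos, 3000)
  ## manual tally on a 10-site toy
  g10 <- matrix(0L, 10, 10)
  for (j in 1:10) g10[seq_len(j - 1), j] <- NA
  kept <- filter_missingness(make_matrix(g10), 0.4)
  expect_identical(ncol(kept$geno), sum((0:9) / 10 <= 0.4))
})

test_that("hom-alt conversion yields E_T and removes all hom-alt codes", {
  g <- matrix(1L, 10, 30)
  expect_equal(convert_homalt(make_matrix(g))$error_rate$E_T, 0)
  g[1, 1:3] <- 2L
  conv <- convert_homalt(make_matrix(g))
  expect_equal(conv$error_rate$E_T, 0.01)
  expect_equal(conv$error_rate$numerator, 3L)
  expect_false(any(conv$matrix$geno == 2L, na.rm = TRUE))
  expect_error(convert_homalt(make_matrix(matrix(NA_integer_, 2, 2))),
               "non-missing")
})

test_that("estimated E_T converges to the analytic spurious hom-alt rate", {
  layout <- genome_layout("chr1", 3e6)
  p <- simulate_parents(layout, snv_density = 1000, seed = 32)
  cvg <- 3; e <- 0.03
  s <- simulate_population(p, n_individuals = 50, coverage = cvg,
                           base_error = e, seed = 33)
  er <- convert_homalt(s$matrix)$error_rate
  a <- p$sites$alt_on_hap1
  het <- sweep(s$truth$hap == 0L, 2, a, "&") |
    sweep(s$truth$hap == 1L, 2, !a, "&")
  expe <- mean(!het) * (exp(-cvg * (1 - e)) - exp(-cvg)) / (1 - exp(-cvg))
  se <- sqrt(expe * (1 - expe) / er$denominator)
  expect_lt(abs(er$E_T - expe), 3 * se)
})

test_that("the filter cascade equals its step-by-step application", {
  ns <- noisy_sim()
  m <- ns$sim$matrix
  keep <- m$sites$chrom == "chr1" & m$sites$pos < 2e6
  m <- xomap:::subset_sites(m, keep)
  casc <- filter_variants(m, fdr = 0.05, ld_dist_range = c(1e3, 1e5),
                          min_depth = 2, max_missing = 0.4, seed = 9)
  step <- filter_segregation(m, fdr = 0.05, expected = "empirical")$matrix
  step <- filter_ld(step, dist_range = c(1e3, 1e5), seed = 9)$matrix
  step <- apply_depth_missing(step, 2)
  step <- filter_missingness(step, 0.4)
  step <- convert_homalt(step)
  expect_identical(casc$matrix$geno, step$matrix$geno)
  expect_identical(casc$matrix$sites, step$matrix$sites)
  expect_equal(casc$error_rate$E_T, step$error_rate$E_T)
})
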