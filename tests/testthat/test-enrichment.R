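gr <- function(chrom, start, end, ...) {
  g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
  g
}

test_that("overlap counting agrees with a brute-force all-pairs oracle", {
  set.seed(91)
  for (rep in 1:3) {
    q <- gr("chr1", s <- sample.int(1e6, 100), s + sample(50:500, 100, TRUE))
    fs <- sample.int(1e6, 80)
    f <- gr("chr1", fs, fs + sample(100:2000, 80, TRUE),
            class = sample(c("a", "b"), 80, TRUE))
    oc <- overlap_counts(q, f)
    for (cl in c("a", "b")) {
      fc <- f[f$class == cl]
      brute <- sum(vapply(seq_along(q), function(i)
        any(GenomicRanges::start(q)[i] <= GenomicRanges::end(fc) &
              GenomicRanges::end(q)[i] >= GenomicRanges::start(fc)),
        TRUE))
      expect_identical(oc$count[oc$class == cl], as.integer(brute))
    }
  }
  ## disjoint sets give zero
  oc0 <- overlap_counts(gr("chr1", 1, 10), gr("chr1", 100, 200, class = "a"))
  expect_identical(oc0$count, 0L)
  ## a query touching two classes counts toward both
  q2 <- gr("chr1", 100, 200)
  f2 <- gr("chr1", c(150, 180), c(160, 190), class = c("a", "b"))
  expect_identical(overlap_counts(q2, f2)$rate, c(1, 1))
})

test_that("shuffle test reports add-one empirical p-values", {
  layout <- genome_layout("chr1", 1e5)
  ## queries sitting exactly on the features: enrichment above every
  ## permutation gives the floor p = 1/(n_perm + 1)
  q <- gr("chr1", seq(1000, 91000, by = 10000), seq(1000, 91000, by = 10000) + 49)
  f <- gr("chr1", seq(1000, 91000, by = 10000), seq(1000, 91000, by = 10000) + 49,
          class = "hit")
  res <- shuffle_mc(q, layout, f, n_perm = 200, seed = 1)
  expect_equal(res$p_enrich, 1 / 201)
  expect_identical(res$rate, 1)
  expect_true(res$null_mean < 0.5)
  expect_error(shuffle_mc(q, layout, f, n_perm = 0), "positive")
  ## an interval longer than its chromosome cannot be shuffled
  expect_error(shuffle_mc(gr("chr1", 1, 2e5), layout, f, n_perm = 10),
               "longer")
  ## determinism under a fixed seed
  res2 <- shuffle_mc(q, layout, f, n_perm = 200, seed = 1)
  expect_identical(res, res2)
})

test_that("cold regions satisfy all matching criteria", {
  layout <- genome_layout("chr1", 5e6)
  set.seed(92)
  ## smooth GC track and homogeneous SNV field make matching feasible
  gc <- layout_bins(layout, 1e4)
  gc$score <- 0.40 + rnorm(length(gc), 0, 0.005)
  snvs <- gr("chr1", s <- sort(sample.int(5e6, 6000)), s)
  xo <- gr("chr1", seq(1.2e6, 3.8e6, length.out = 25),
           seq(1.2e6, 3.8e6, length.out = 25) + 4999)
  cold <- sample_cold_regions(xo, layout, gc, snvs, seed = 93)
  expect_identical(length(cold), length(xo))
  v <- validate_cold_regions(cold, xo, gc, snvs)
  expect_true(all(v))
  ## a crossover at the chromosome end with no room is unsatisfiable
  tiny <- genome_layout("chr1", 3e4)
  xo2 <- gr("chr1", 100, 1099)
  gc2 <- layout_bins(tiny, 1e4); gc2$score <- 0.4
  expect_error(sample_cold_regions(xo2, tiny, gc2, snvs, max_tries = 50,
                                   seed = 94), "bounds")
})

test_that("family Fisher test equals hypergeometric enumeration", {
  ## identical composition gives p = 1
  xo <- gr("chr1", (1:50) * 1000, (1:50) * 1000 + 100)
  te <- gr("chr1", (1:25) * 1000, (1:25) * 1000 + 50, family = "MITE")
  res <- te_family_fisher(xo, xo, te)
  expect_equal(res$p, 1)
  ## toy 30/70 vs 10/90 against an exhaustive tail-sum oracle
  xo2 <- gr("chr1", (1:100) * 1e4, (1:100) * 1e4 + 100)
  cold2 <- gr("chr2", (1:100) * 1e4, (1:100) * 1e4 + 100)
  te2 <- suppressWarnings(
    c(gr("chr1", (1:30) * 1e4, (1:30) * 1e4 + 10, family = "fam"),
      gr("chr2", (1:10) * 1e4, (1:10) * 1e4 + 10, family = "fam")))
  res2 <- te_family_fisher(xo2, cold2, te2)
  ## two-sided Fisher p: sum of hypergeometric probabilities <= P(observed)
  probs <- dhyper(0:40, 40, 160, 100)
  pobs <- dhyper(30, 40, 160, 100)
  oracle <- sum(probs[probs <= pobs * (1 + 1e-7)])
  expect_equal(res2$p, oracle, tolerance = 1e-9)
  ## Bonferroni across families
  te3 <- c(te2, gr("chr1", 1e4, 1e4 + 5, family = "rare"))
  res3 <- te_family_fisher(xo2, cold2, te3)
  expect_equal(res3$p_bonferroni, pmin(1, res3$p * 2))
  expect_error(te_family_fisher(xo2, cold2[1:5], te2), "equal size")
})

test_that("aggregate profile equals a naive per-base oracle", {
  layout <- genome_layout("chr1", 1e5)
  set.seed(95)
  sig <- layout_bins(layout, 100)
  sig$score <- rpois(length(sig), 5)
  anc <- gr("chr1", st <- sample(20000:70000, 10), st + sample(500:999, 10, TRUE))
  GenomicRanges::strand(anc) <- sample(c("+", "-"), 10, TRUE)
  prof <- aggregate_profile(anc, sig, body_bins = 10, flank = 1000,
                            flank_bin = 10)
  ## naive oracle: expand the track to per-base values and average bins
  base_val <- rep(sig$score, each = 100)
  naive <- matrix(NA_real_, 10, 2 * 100 + 10)
  for (i in 1:10) {
    s <- GenomicRanges::start(anc)[i]; e <- GenomicRanges::end(anc)[i]
    up <- vapply(1:100, function(b) mean(
      base_val[(s - 1000 + (b - 1) * 10):(s - 1000 + b * 10 - 1)]), 0)
    edges <- round(seq(s - 1, e, length.out = 11))
    body <- vapply(1:10, function(b)
      mean(base_val[(edges[b] + 1):edges[b + 1]]), 0)
    dn <- vapply(1:100, function(b) mean(
      base_val[(e + (b - 1) * 10 + 1):(e + b * 10)]), 0)
    row <- c(up, body, dn)
    if (as.character(GenomicRanges::strand(anc))[i] == "-") row <- rev(row)
    naive[i, ] <- row
  }
  expect_equal(prof$matrix, naive, tolerance = 1e-10)
  ## constant signal gives a flat profile at its value
  sig2 <- layout_bins(layout, 1e5); sig2$score <- 1
  prof2 <- aggregate_profile(anc, sig2, body_bins = 10, flank = 1000,
                             flank_bin = 10)
  expect_equal(unname(prof2$profile), rep(1, 210), tolerance = 1e-12)
  ## anchors shorter than the bin count are skipped
  short <- c(anc, gr("chr1", 5000, 5004))
  expect_message(p3 <- aggregate_profile(short, sig, body_bins = 10,
                                         flank = 100, flank_bin = 10),
                 "skipped")
  expect_identical(p3$n_skipped, 1L)
})

test_that("signal Monte-Carlo behaves at the null and at a constructed peak", {
  layout <- genome_layout("chr1", 2e6)
  sig <- layout_bins(layout, 1000)
  sig$score <- 10  # identical signal everywhere
  q <- gr("chr1", seq(2e5, 1.8e6, length.out = 10),
          seq(2e5, 1.8e6, length.out = 10) + 999)
  res <- signal_mc(q, sig, layout, band = c(1e4, 1e5), n_perm = 100, seed = 3)
  expect_gt(res$p_enrich, 0.3); expect_gt(res$p_deplete, 0.3)
  ## queries placed on simulated peaks reach the floor p
  sig2 <- sig
  hit <- GenomicRanges::countOverlaps(sig2, q) > 0
  sig2$score[hit] <- 1000
  res2 <- signal_mc(q, sig2, layout, band = c(1e4, 1e5), n_perm = 100,
                    seed = 4)
  expect_equal(res2$p_enrich, 1 / 101)
  ## reproducible under a fixed seed
  res3 <- signal_mc(q, sig2, layout, band = c(1e4, 1e5), n_perm = 100,
                    seed = 4)
  expect_identical(res2, res3)
})

test_that("binned correlations respect rank invariance and match a rank oracle", {
  layout <- genome_layout("chr1", 2e6)
  set.seed(96)
  ## bins match the track granularity so the per-bin values undergo an
  ## exact monotone transform
  t1 <- layout_bins(layout, 1e5); t1$score <- rpois(length(t1), 20)
  t2 <- t1; t2$score <- t1$score^2 + 1
  bs <- binned_stats(list(a = t1, b = t2), layout, binsize = 1e5)
  expect_equal(bs$rho["a", "a"], 1)
  expect_equal(bs$rho["a", "b"], 1)
  ## 20-bin toy against the brute-force rank formula (mid-ranked ties)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4)
  y <- rev(x) + seq(0.1, 2, by = 0.1)
  V <- cbind(x = x, y = y)
  bs2 <- binned_stats(V, layout = NULL, binsize = 1e5)
  rx <- rank(x); ry <- rank(y)
  oracle <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(bs2$rho["x", "y"], oracle, tolerance = 1e-12)
  ## constant track flagged with NA
  Vc <- cbind(x = x, const = rep(1, 20))
  expect_warning(bs3 <- binned_stats(Vc, layout = NULL), "constant")
  expect_true(is.na(bs3$rho["x", "const"]))
  ## SNV normalizer
  expect_equal(normalize_snv_track(c(10, 20), c(0.5, 1), c(100, 0)),
               c(0.05, 0))
})

test_that("Poisson goodness-of-fit is calibrated and handles edge cases", {
  set.seed(97)
  rejected <- 0L
  for (s in 1:100) {
    cnt <- rpois(90, 1)
    p <- suppressWarnings(poisson_fit_counts(cnt)$p_value)
    if (p < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 5)  # >= 95% of seeds not rejected at alpha = 0.01
  ## degenerate all-zero counts
  z <- suppressWarnings(poisson_fit_counts(rep(0L, 30)))
  expect_identical(z$lambda, 0)
  expect_identical(z$p_value, 1)
  ## expected frequencies sum to n
  f <- suppressWarnings(poisson_fit_counts(rpois(50, 0.8)))
  expect_equal(sum(f$table$expected), 50)
  expect_warning(poisson_fit_counts(rpois(10, 1)), "low validity")
  expect_error(poisson_fit_counts(c(-1, 2)), "non-negative")
})

test_that("crossover-count GLM recovers known effects", {
  set.seed(98)
  n <- 300
  x <- rnorm(n)
  mu <- exp(0.5 + 1 * x)
  d <- data.frame(crossovers = rpois(n, mu), x = x)
  fit <- glm_crossovers(d)
  ci <- suppressMessages(confint.default(fit$model))["x", ]
  expect_gt(1, ci[1]); expect_lt(1, ci[2])
  ## intercept-only model reproduces the mean count
  fit0 <- glm_crossovers(d[, "crossovers", drop = FALSE])
  expect_equal(unname(exp(coef(fit0$model)[1])), mean(d$crossovers),
               tolerance = 1e-8)
  ## rank-deficient covariates are dropped with a warning
  d2 <- d; d2$x2 <- 2 * d$x
  expect_warning(fit2 <- glm_crossovers(d2), "rank-deficient")
  expect_false("x2" %in% names(coef(fit2$model)))
  ## null covariates give roughly uniform term p-values
  pv <- replicate(60, {
    dn <- data.frame(crossovers = rpois(100, 1), z = rnorm(100))
    glm_crossovers(dn)$anova["z", "Pr(>Chi)"]
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
})

test_that("promoter quartile analyses detect constructed Stowaway effects", {
  layout <- genome_layout("chr1", 1e7)
  ## recombination track: high rate on the left half, low on the right
  tk <- layout_bins(layout, 1e5)
  tk$score <- rep(c(8, 0.5), each = 50)
  set.seed(99)
  prom_hi <- gr("chr1", s <- sort(sample.int(4.5e6, 60)) , s + 999)
  prom_lo <- gr("chr1", s2 <- 5e6 + sort(sample.int(4.5e6, 60)), s2 + 999)
  proms <- c(prom_hi, prom_lo)
  ## twice as many elements in high-recombination promoters
  pick_hi <- rep(seq_along(prom_hi), 2)
  pick_lo <- seq_along(prom_lo)
  tes <- c(GenomicRanges::shift(GenomicRanges::resize(prom_hi[pick_hi], 200,
                                                      fix = "center"), 10),
           GenomicRanges::resize(prom_lo[pick_lo], 200, fix = "center"))
  res <- suppressWarnings(
    promoter_quartile_analysis(proms, tes, tk, n_perm = 200, seed = 5))
  expect_lt(res$wilcox_p, 0.01)
  ## element-bearing promoters just inside the fast half, matched
  ## element-free promoters within 500 kb on the slow side
  tk2 <- layout_bins(layout, 1e5)
  tk2$score <- ifelse(GenomicRanges::start(tk2) < 4.5e6, 8, 0.5)
  with_p <- gr("chr1", s3 <- sort(round(runif(60, 4.0e6, 4.4e6))), s3 + 999)
  without_p <- gr("chr1", s4 <- sort(round(runif(60, 4.6e6, 4.85e6))), s4 + 999)
  tes2 <- GenomicRanges::resize(with_p, 200, fix = "center")
  res2 <- suppressWarnings(promoter_quartile_analysis(
    c(with_p, without_p), tes2, tk2, n_perm = 200, seed = 6))
  expect_lt(res2$mc_p, 0.05)
  expect_gte(res2$mc_p, 1 / 201)
  ## identical count distributions in both quartile groups: rank-sum test
  ## finds nothing (and with no element-free promoter the MC arm is
  ## skipped with a warning)
  tes_same <- GenomicRanges::resize(proms, 200, fix = "center")
  extra <- GenomicRanges::shift(tes_same[seq(1, length(proms), by = 2)], 300)
  expect_warning(res3 <- promoter_quartile_analysis(proms,
                                                    c(tes_same, extra), tk,
                                                    n_perm = 50, seed = 7),
                 "empty promoter group")
  expect_gt(res3$wilcox_p, 0.5)
  expect_true(is.na(res3$mc_p))
})
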