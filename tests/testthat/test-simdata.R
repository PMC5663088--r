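test_that("simulated parents have balanced, sorted, reproducible sites", {
  layout <- genome_layout("chr1", 1e6)
  p <- simulate_parents(layout, snv_density = 1000, seed = 1)
  expect_gt(nrow(p$sites), 800)
  expect_lt(nrow(p$sites), 1200)
  expect_false(is.unsorted(p$sites$pos, strictly = TRUE))
  expect_true(all(p$sites$ref != p$sites$alt))
  ## determinism contract
  p2 <- simulate_parents(layout, snv_density = 1000, seed = 1)
  expect_identical(p, p2)
  ## ALT placement is a fair coin: binomial CI oracle at n ~ 10,000
  big <- simulate_parents(genome_layout("chr1", 1e7), 1000, seed = 2)
  n <- nrow(big$sites)
  frac <- mean(big$sites$alt_on_hap1)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
  expect_error(genome_layout("chr1", 0), "positive")
  expect_error(simulate_parents(layout, snv_density = 0), "> 0")
})

test_that("meiosis obeys the Poisson crossover model", {
  layout <- genome_layout("chr1", 1e6)
  p <- simulate_parents(layout, snv_density = 100, seed = 3)
  ## lambda = 0: gamete is a single parental haplotype
  g0 <- simulate_meiosis(p, lambda_co = 0, seed = 4)
  expect_equal(nrow(g0$crossovers), 0)
  expect_length(unique(g0$hap), 1)
  ## Poisson moment oracle over many gametes (counts include only
  ## marker-visible crossovers, so compare to lambda with generous SE)
  set.seed(5)
  counts <- replicate(4000, nrow(simulate_meiosis(p, lambda_co = 1)$crossovers))
  se <- sqrt(1 / length(counts))
  expect_lt(abs(mean(counts) - 1), 4 * se + 0.05)
})

test_that("U-shaped density depletes crossovers in the chromosome middle", {
  layout <- genome_layout("chr1", 1e6)
  p <- simulate_parents(layout, snv_density = 500, seed = 6)
  set.seed(7)
  pos <- unlist(replicate(800, simulate_meiosis(
    p, lambda_co = 2, density_profile = co_density_ushape())$crossovers$pos))
  rel <- pos / 1e6
  ## analytic mass of the default U-shape in [0.4, 0.6] is ~6%; uniform = 20%
  expect_lt(mean(rel > 0.4 & rel < 0.6), 0.12)
})

test_that("haplotype switch count equals recorded crossover count", {
  layout <- genome_layout(c("chr1", "chr2"), c(5e5, 5e5))
  p <- simulate_parents(layout, snv_density = 200, seed = 8)
  for (s in 1:20) {
    g <- simulate_meiosis(p, lambda_co = 2, seed = 100 + s)
    switches <- sum(vapply(unique(p$sites$chrom), function(ch) {
      h <- g$hap[p$sites$chrom == ch]
      sum(diff(h) != 0L)
    }, integer(1)))
    expect_identical(switches, nrow(g$crossovers))
    expect_true(all(tapply(g$crossovers$pos, g$crossovers$chrom,
                           function(x) !is.unsorted(x, strictly = TRUE))))
  }
})

test_that("sequencing model produces the expected calls", {
  layout <- genome_layout("chr1", 2e5)
  p <- simulate_parents(layout, snv_density = 500, seed = 9)
  ## deep error-free sequencing recovers genotypes exactly
  s <- simulate_population(p, n_individuals = 10, coverage = 30,
                           base_error = 0, seed = 10)
  a <- p$sites$alt_on_hap1
  het <- sweep(s$truth$hap == 0L, 2, a, "&") |
    sweep(s$truth$hap == 1L, 2, !a, "&")
  expect_true(all(s$matrix$geno[het] == 1L, na.rm = TRUE))
  expect_true(all(s$matrix$geno[!het] == 0L, na.rm = TRUE))
  expect_lt(mean(is.na(s$matrix$geno)), 1e-4)
  ## shape and determinism
  expect_identical(dim(s$matrix$geno), c(10L, nrow(p$sites)))
  s2 <- simulate_population(p, n_individuals = 10, coverage = 30,
                            base_error = 0, seed = 10)
  expect_identical(s$matrix$geno, s2$matrix$geno)
  expect_identical(s$truth$crossovers, s2$truth$crossovers)
  expect_error(simulate_population(p, n_individuals = 1), ">= 2")
})

test_that("spurious hom-alt rate matches its closed form", {
  ## under the read model, a hom-alt call arises only at truly hom-ref
  ## sites when all d >= 1 reads are errors:
  ##   P(hom-alt | call) = f_homref * E[e^d | d >= 1]
  ## with depth d ~ Poisson(c), so E[e^d | d>=1] =
  ##   (exp(-c(1-e)) - exp(-c)) / (1 - exp(-c)).
  layout <- genome_layout("chr1", 2e6)
  p <- simulate_parents(layout, snv_density = 1000, seed = 11)
  cvg <- 2; e <- 0.02
  s <- simulate_population(p, n_individuals = 60, coverage = cvg,
                           base_error = e, seed = 12)
  a <- p$sites$alt_on_hap1
  het <- sweep(s$truth$hap == 0L, 2, a, "&") |
    sweep(s$truth$hap == 1L, 2, !a, "&")
  f_hr <- mean(!het)
  expe <- f_hr * (exp(-cvg * (1 - e)) - exp(-cvg)) / (1 - exp(-cvg))
  n_calls <- sum(!is.na(s$matrix$geno))
  obs <- sum(s$matrix$geno == 2L, na.rm = TRUE) / n_calls
  se <- sqrt(expe * (1 - expe) / n_calls)
  expect_lt(abs(obs - expe), 3 * se)
})

test_that("simulated annotation is structurally sound", {
  layout <- genome_layout("chr1", 2e6)
  ann <- simulate_annotation(layout, n_genes = 40, stowaway_tss_bias = 1,
                             seed = 13)
  te <- ann$features[ann$features$class == "TE:Stowaway"]
  prom <- ann$features[ann$features$class == "promoter"]
  ## full bias: every element inside a promoter
  within <- GenomicRanges::countOverlaps(te, prom, type = "within",
                                         ignore.strand = TRUE)
  expect_true(all(within > 0))
  ## gene features partition each gene body exactly
  body_cls <- c("five_prime_UTR", "exon", "intron", "three_prime_UTR")
  parts <- ann$features[ann$features$class %in% body_cls]
  for (gid in ann$genes$gene_id) {
    gp <- parts[!is.na(parts$gene_id) & parts$gene_id == gid]
    gp <- GenomicRanges::sort(gp, ignore.strand = TRUE)
    g <- ann$genes[ann$genes$gene_id == gid]
    expect_identical(GenomicRanges::start(gp)[1], GenomicRanges::start(g))
    expect_identical(GenomicRanges::end(gp)[length(gp)],
                     GenomicRanges::end(g))
    if (length(gp) > 1)
      expect_true(all(GenomicRanges::start(gp)[-1] ==
                        head(GenomicRanges::end(gp), -1) + 1))
  }
  ## no positional preference without bias: KS against uniform
  ann0 <- simulate_annotation(layout, n_genes = 40, stowaway_tss_bias = 0,
                              n_stowaway = 300, seed = 14)
  te0 <- ann0$features[ann0$features$class == "TE:Stowaway"]
  rel <- GenomicRanges::start(te0) / 2e6
  expect_gt(suppressWarnings(ks.test(rel, "punif")$p.value), 0.01)
  ## density too high to place -> informative rejection
  expect_error(simulate_annotation(genome_layout("chr1", 5e4), n_genes = 20,
                                   seed = 15), "density")
})

test_that("simulation artifacts export to standard formats", {
  cs <- clean_sim()
  td <- withr::local_tempdir()
  bed <- file.path(td, "truth.bed")
  write_truth_bed(cs$sim$truth, bed)
  back <- rtracklayer::import(bed, format = "BED")
  expect_equal(length(back), nrow(cs$sim$truth$crossovers))
  expect_equal(GenomicRanges::start(back), cs$sim$truth$crossovers$left_pos)
  ann <- simulate_annotation(cs$layout, n_genes = 20, seed = 16)
  gff <- file.path(td, "ann.gff3")
  write_annotation_gff3(ann, gff)
  expect_gt(length(rtracklayer::import(gff, format = "GFF3")), 0)
  tr <- simulate_signal_track(cs$layout, binsize = 10000, seed = 17)
  bg <- file.path(td, "sig.bedgraph")
  write_signal_bedgraph(tr, bg)
  back2 <- rtracklayer::import(bg, format = "bedGraph")
  expect_equal(sum(back2$score), sum(tr$score))
})
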