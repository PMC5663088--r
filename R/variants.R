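## SNV filtering cascade for a pseudo-testcross: repeat masking ->
## segregation distortion -> sampled-r2 LD -> depth-aware missingness ->
## per-site missingness -> hom-alt conversion (which yields the empirical
## genotyping error rate E_T used by the Bayesian window caller).

#' Load a genotype matrix from VCF
#'
#' Reads per-sample `GT` (and `DP` when present) fields into an
#' [snv_matrix()].  `0/0` maps to hom-ref, `0/1`/`1/0` to het, `1/1` to
#' hom-alt, `./.` to missing; phased separators are accepted.
#'
#' @param vcf Path to a VCF (optionally gzipped).
#' @return An [snv_matrix()].
#' @export
load_genotypes <- function(vcf) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  key <- paste(sites$chrom, sites$pos)
  if (anyDuplicated(key))
    stopf("duplicate site in VCF: %s", key[which(duplicated(key))[1]])
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[ord, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% "0/0"] <- GT_HOM_REF
  code[gt %in% c("0/1", "1/0")] <- GT_HET
  code[gt %in% "1/1"] <- GT_HOM_ALT
  fmt <- v@gt[, "FORMAT"]
  has_dp <- any(grepl("DP", fmt, fixed = TRUE))
  if (has_dp) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    dp <- dp[ord, , drop = FALSE]
    dp[is.na(dp)] <- 0
  } else {
    warnf("VCF has no DP field; recording depth 0 for all calls")
    dp <- matrix(0, nrow(gt), ncol(gt))
  }
  snv_matrix(sites, t(code), t(dp))
}

#' Remove SNVs overlapping repeat intervals
#'
#' Sites whose single-bp position intersects any repeat interval are
#' dropped, matching the convention of masking variants called inside
#' RepeatMasker annotations.
#'
#' @param m An [snv_matrix()].
#' @param repeats Repeat intervals: a `GRanges`, or a path to a BED file
#'   (0-based half-open, converted on import).
#' @return The filtered [snv_matrix()].
#' @export
mask_repeats <- function(m, repeats) {
  if (is.character(repeats))
    repeats <- rtracklayer::import(repeats, format = "BED")
  if (length(repeats) == 0) return(m)
  hit <- GenomicRanges::countOverlaps(sites_granges(m), repeats,
                                      ignore.strand = TRUE) > 0
  if (all(hit)) warnf("all %d sites fall in repeats; empty matrix", ncol(m$geno))
  subset_sites(m, !hit)
}

#' Remove SNVs with distorted segregation
#'
#' Per site, the hom-ref : het genotype counts are tested against the
#' expected segregation ratio by a chi-square goodness of fit; sites with
#' Benjamini-Hochberg adjusted p below `fdr` are removed.  Hom-alt calls
#' (pre-conversion errors) are excluded from the test.  The Mendelian
#' expectation of a pseudo-testcross is 1:1, but with hard genotype calls
#' at low coverage heterozygotes are systematically undercalled (a het
#' site shows no ALT read with probability `2^-depth`), shifting every
#' site's expectation toward hom-ref; `expected = "empirical"` therefore
#' tests each site against the genome-wide mean ratio, targeting
#' *relative* distortion.
#'
#' @param m An [snv_matrix()].
#' @param fdr BH false discovery rate threshold (default 0.05).
#' @param expected Expected hom-ref:het ratio: a numeric length-2 vector
#'   (default `c(1, 1)`) or `"empirical"` for the genome-wide mean ratio.
#' @return List: `matrix` (filtered), `stats` (data.frame with per-site
#'   `chrom`, `pos`, `n_hom_ref`, `n_het`, `p`, `p_adj`, `removed`);
#'   sites with fewer than 2 testable calls get `p = NA` and are retained.
#' @export
filter_segregation <- function(m, fdr = 0.05, expected = c(1, 1)) {
  n0 <- colSums(m$geno == GT_HOM_REF, na.rm = TRUE)
  n1 <- colSums(m$geno == GT_HET, na.rm = TRUE)
  tot <- n0 + n1
  if (identical(expected, "empirical")) {
    p0 <- sum(n0) / max(sum(tot), 1)
  } else {
    if (!is.numeric(expected) || length(expected) != 2 || any(expected <= 0))
      stopf("expected must be a positive length-2 ratio or \"empirical\"")
    p0 <- expected[1] / sum(expected)
  }
  p <- rep(NA_real_, length(tot))
  ok <- tot >= 2
  e0 <- tot[ok] * p0; e1 <- tot[ok] * (1 - p0)
  stat <- (n0[ok] - e0)^2 / e0 + (n1[ok] - e1)^2 / e1
  p[ok] <- pchisq(stat, df = 1, lower.tail = FALSE)
  p_adj <- rep(NA_real_, length(p))
  p_adj[ok] <- p.adjust(p[ok], method = "BH")
  removed <- !is.na(p_adj) & p_adj < fdr
  stats <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                      n_hom_ref = n0, n_het = n1, p = p, p_adj = p_adj,
                      removed = removed)
  list(matrix = subset_sites(m, !removed), stats = stats)
}

#' Remove SNVs in weak linkage disequilibrium with their neighborhood
#'
#' In a bi-parental population every true marker is tightly linked to
#' nearby markers.  For each site, up to `n_sample` partner sites are drawn
#' uniformly (without replacement) from the same chromosome at a distance
#' within `dist_range`; r-squared is the squared Pearson correlation of
#' genotype codes over individuals non-missing at both sites (pairs with
#' fewer than `min_shared` shared observations are skipped).  Sites whose
#' median r-squared falls below `min_median_r2` are removed.
#'
#' @param m An [snv_matrix()].
#' @param n_sample Partners sampled per site (default 25).
#' @param dist_range Numeric length-2: allowed |distance| band in bp
#'   (default `c(1e3, 1e7)`, i.e. 1 kb to 10,000 kb).
#' @param min_median_r2 Removal threshold on the median r-squared
#'   (default 0.2).
#' @param min_shared Minimum individuals shared by a pair (default 10).
#' @param seed Optional integer seed for partner sampling.
#' @return List: `matrix` (filtered), `stats` (per-site `median_r2`,
#'   `n_partners`, `no_partner` flag, `removed`).  Sites with no partner in
#'   the band are retained and flagged.
#' @export
filter_ld <- function(m, n_sample = 25, dist_range = c(1e3, 1e7),
                      min_median_r2 = 0.2, min_shared = 10, seed = NULL) {
  with_seed(seed, {
    ns <- ncol(m$geno)
    G <- m$geno; storage.mode(G) <- "double"
    med <- rep(NA_real_, ns); npart <- integer(ns)
    chroms <- m$sites$chrom; pos <- m$sites$pos
    dmin <- dist_range[1]; dmax <- dist_range[2]
    for (ch in unique(chroms)) {
      idx <- which(chroms == ch)
      p <- pos[idx]
      ## band edges by binary search on the sorted position vector
      loL <- findInterval(p - dmax - 1, p) + 1L
      hiL <- findInterval(p - dmin, p)
      loR <- findInterval(p + dmin - 1, p) + 1L
      hiR <- findInterval(p + dmax, p)
      for (j in seq_along(idx)) {
        cand <- c(if (loL[j] <= hiL[j]) loL[j]:hiL[j],
                  if (loR[j] <= hiR[j]) loR[j]:hiR[j])
        if (!length(cand)) next
        take <- if (length(cand) > n_sample)
          cand[sample.int(length(cand), n_sample)] else cand
        x <- G[, idx[j]]
        Y <- G[, idx[take], drop = FALSE]
        shared <- colSums(!is.na(Y) & !is.na(x))
        Y <- Y[, shared >= min_shared, drop = FALSE]
        if (!ncol(Y)) next
        r <- suppressWarnings(
          cor(x, Y, use = "pairwise.complete.obs"))
        r2 <- as.numeric(r)^2
        r2 <- r2[!is.na(r2)]
        if (!length(r2)) next
        med[idx[j]] <- median(r2)
        npart[idx[j]] <- length(r2)
      }
    }
    no_partner <- is.na(med)
    if (any(no_partner))
      xo_log(sum(no_partner), " site(s) had no informative LD partner; retained")
    removed <- !no_partner & med < min_median_r2
    stats <- data.frame(chrom = chroms, pos = pos, median_r2 = med,
                        n_partners = npart, no_partner = no_partner,
                        removed = removed)
    list(matrix = subset_sites(m, !removed), stats = stats)
  })
}

#' Set low-depth hom-ref calls to missing
#'
#' At low coverage a het genotype is frequently observed as hom-ref because
#' only one allele was sampled; hom-ref calls with depth below `min_depth`
#' are therefore unreliable and set missing.  Het and hom-alt calls carry
#' direct evidence of the ALT allele and are untouched.
#'
#' @param m An [snv_matrix()].
#' @param min_depth Depth threshold (calls with depth `< min_depth` become
#'   missing); 2 for a ~2x population, 5 for higher coverage.
#' @return The modified [snv_matrix()].
#' @export
apply_depth_missing <- function(m, min_depth = 2) {
  if (min_depth < 0) stopf("min_depth must be >= 0")
  drop <- !is.na(m$geno) & m$geno == GT_HOM_REF & m$depth < min_depth
  m$geno[drop] <- NA_integer_
  m
}

#' Remove SNVs with too many missing calls
#'
#' @param m An [snv_matrix()].
#' @param max_missing Maximum tolerated fraction of missing calls per site
#'   (sites strictly above are removed); 0.40 for a large low-coverage
#'   population, 0.05 for a small high-coverage one.
#' @return The filtered [snv_matrix()].
#' @export
filter_missingness <- function(m, max_missing = 0.4) {
  if (max_missing < 0 || max_missing > 1) stopf("max_missing must be in [0, 1]")
  frac <- colMeans(is.na(m$geno))
  subset_sites(m, frac <= max_missing)
}

#' Convert hom-alt calls to het and estimate the genotyping error rate
#'
#' In a one-way pseudo-testcross a hom-alt genotype is impossible without
#' error, so every hom-alt call is recoded het and the fraction of hom-alt
#' calls among all non-missing calls is taken as the empirical genotyping
#' error rate E_T consumed by the Bayesian window caller.
#'
#' @param m An [snv_matrix()].
#' @return List: `matrix` (no hom-alt codes remain), `error_rate` (class
#'   `error_rate`: `E_T`, `numerator`, `denominator`).
#' @export
convert_homalt <- function(m) {
  denom <- sum(!is.na(m$geno))
  if (denom == 0) stopf("matrix has no non-missing calls")
  num <- sum(m$geno == GT_HOM_ALT, na.rm = TRUE)
  m$geno[!is.na(m$geno) & m$geno == GT_HOM_ALT] <- GT_HET
  er <- structure(list(E_T = num / denom, numerator = num,
                       denominator = denom), class = "error_rate")
  list(matrix = m, error_rate = er)
}

#' @export
print.error_rate <- function(x, ...) {
  cat(sprintf("E_T = %.4g (%d hom-alt of %d calls)\n",
              x$E_T, x$numerator, x$denominator))
  invisible(x)
}

#' Run the full SNV filtering cascade
#'
#' Applies, in order: repeat masking, segregation-distortion removal,
#' sampled-r2 LD filtering, depth-aware missingness of hom-ref calls,
#' per-site missingness filtering, and hom-alt conversion with E_T
#' estimation.  The order is fixed; each step sees the previous step's
#' output.
#'
#' @param m An [snv_matrix()].
#' @param repeats Optional repeat intervals (see [mask_repeats()]).
#' @param fdr Segregation-distortion BH threshold.
#' @param seg_expected Expected hom-ref:het ratio for the distortion test;
#'   the default `"empirical"` (genome-wide mean ratio) stays calibrated
#'   under low-coverage het undercalling (see [filter_segregation()]);
#'   pass `c(1, 1)` for the strict Mendelian expectation.
#' @param ld_n_sample,ld_dist_range,min_median_r2 LD filter settings
#'   (see [filter_ld()]).
#' @param min_depth Hom-ref depth floor (see [apply_depth_missing()]).
#' @param max_missing Per-site missingness cap.
#' @param seed Seed for LD partner sampling.
#' @return List: `matrix` (filtered, het-recoded), `error_rate`,
#'   `segregation` and `ld` per-site stat tables, `n_sites` named vector of
#'   site counts after each stage.
#' @export
filter_variants <- function(m, repeats = NULL, fdr = 0.05,
                            seg_expected = "empirical",
                            ld_n_sample = 25, ld_dist_range = c(1e3, 1e7),
                            min_median_r2 = 0.2, min_depth = 2,
                            max_missing = 0.4, seed = NULL) {
  n <- c(input = ncol(m$geno))
  if (!is.null(repeats)) m <- mask_repeats(m, repeats)
  n <- c(n, repeats = ncol(m$geno))
  seg <- filter_segregation(m, fdr = fdr, expected = seg_expected)
  m <- seg$matrix
  n <- c(n, segregation = ncol(m$geno))
  ld <- filter_ld(m, n_sample = ld_n_sample, dist_range = ld_dist_range,
                  min_median_r2 = min_median_r2, seed = seed)
  m <- ld$matrix
  n <- c(n, ld = ncol(m$geno))
  m <- apply_depth_missing(m, min_depth = min_depth)
  m <- filter_missingness(m, max_missing = max_missing)
  n <- c(n, missingness = ncol(m$geno))
  conv <- convert_homalt(m)
  list(matrix = conv$matrix, error_rate = conv$error_rate,
       segregation = seg$stats, ld = ld$stats, n_sites = n)
}

#' Write per-site filter statistics as TSV
#'
#' @param filtered A [filter_variants()] result.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_filter_stats <- function(filtered, path) {
  seg <- filtered$segregation[c("chrom", "pos", "p", "p_adj")]
  names(seg)[3:4] <- c("p_distortion", "p_distortion_adj")
  ld <- filtered$ld[c("chrom", "pos", "median_r2")]
  out <- merge(seg, ld, by = c("chrom", "pos"), all = TRUE, sort = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
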