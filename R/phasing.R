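## Sliding-window LD phasing.  In a pseudo-testcross the progeny genotype at
## a marker is het when the inherited parental haplotype carries the ALT
## allele and hom-ref otherwise, so two markers whose ALT alleles sit on the
## same parental haplotype have concordant genotype columns and markers on
## opposite haplotypes have complementary columns.  Phasing therefore
## reduces to orienting each marker against an already-phased anchor chosen
## by maximal r-squared inside a trailing window.

#' Phase SNVs along each chromosome by sliding-window LD
#'
#' The first SNV of each chromosome anchors the phase arbitrarily
#' (haplotype labels are only defined up to a global flip).  Each
#' subsequent SNV is oriented against the already-phased SNV with the
#' highest r-squared among the trailing `window - 1` markers: if the two
#' genotype columns agree in the majority of shared individuals the ALT
#' alleles are placed on the same haplotype, otherwise on opposite
#' haplotypes.  Because the window advances one SNV at a time, orientation
#' propagates chromosome-wide.
#'
#' @param m An [snv_matrix()] after filtering (codes 0/1).
#' @param window Sliding window size in SNVs (default 100; the trailing
#'   `window - 1` markers are anchor candidates).
#' @param shift Window shift in SNVs; only 1 is supported.
#' @return Object of class `phased_snvs`: list with `sites`, logical
#'   `alt_on_hap1` per site (`NA` when no informative partner existed), and
#'   `n_uninformative`.
#' @export
phase_snvs <- function(m, window = 100, shift = 1) {
  if (shift != 1) stopf("only a 1-SNV shift is supported")
  if (window < 2) stopf("window must be >= 2")
  G <- m$geno; storage.mode(G) <- "double"
  chroms <- m$sites$chrom
  orient <- rep(NA, ncol(G))
  ties <- 0L
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    if (length(idx) < 2) {
      warnf("chromosome %s has < 2 SNVs; left unphased", ch)
      next
    }
    o <- phase_chromosome_(G[, idx, drop = FALSE], window)
    orient[idx] <- o$orient
    ties <- ties + o$ties
  }
  if (ties > 0) xo_log(ties, " orientation tie(s) broken deterministically")
  n_un <- sum(is.na(orient))
  if (n_un > 0) xo_log(n_un, " SNV(s) had no informative partner; unphased")
  structure(list(sites = m$sites, alt_on_hap1 = orient,
                 n_uninformative = n_un),
            class = "phased_snvs")
}

## One chromosome: G is individuals x sites (codes 0/1, NA missing).
phase_chromosome_ <- function(G, window) {
  n <- ncol(G)
  orient <- rep(NA, n)
  orient[1] <- TRUE
  ties <- 0L
  for (i in 2:n) {
    lo <- max(1L, i - (window - 1L))
    cand <- lo:(i - 1L)
    cand <- cand[!is.na(orient[cand])]
    if (!length(cand)) next
    x <- G[, i]
    if (all(is.na(x))) next
    Y <- G[, cand, drop = FALSE]
    shared <- colSums(!is.na(Y) & !is.na(x))
    keep <- shared >= 2
    cand <- cand[keep]
    if (!length(cand)) next
    Y <- Y[, keep, drop = FALSE]
    r <- suppressWarnings(as.numeric(
      cor(x, Y, use = "pairwise.complete.obs")))
    r2 <- r^2
    if (all(is.na(r2))) next
    j <- cand[which.max(r2)]
    both <- !is.na(x) & !is.na(G[, j])
    same <- sum(x[both] == G[both, j])
    diff <- sum(both) - same
    if (same > diff) {
      orient[i] <- orient[j]
    } else if (diff > same) {
      orient[i] <- !orient[j]
    } else {
      orient[i] <- TRUE  # deterministic tie-break; logged by caller
      ties <- ties + 1L
    }
  }
  list(orient = orient, ties = ties)
}

#' @export
print.phased_snvs <- function(x, ...) {
  cat(sprintf("phased_snvs: %d sites (%d unphased); ALT on hap1 at %.1f%%\n",
              length(x$alt_on_hap1), sum(is.na(x$alt_on_hap1)),
              100 * mean(x$alt_on_hap1, na.rm = TRUE)))
  invisible(x)
}

#' Recode genotypes as parental haplotype labels
#'
#' Maps each individual's genotype at each phased SNV to the parental
#' haplotype it inherited: 0 for haplotype 1, 1 for haplotype 2.  A het
#' call means the individual carries the ALT allele, i.e. the haplotype the
#' ALT allele sits on; missing genotypes and unphased sites propagate as
#' missing labels.
#'
#' @param m An [snv_matrix()] (codes 0/1 after hom-alt conversion).
#' @param phased A [phase_snvs()] result for the same sites.
#' @return Object of class `hap_labels`: list with `sites`, `labels`
#'   (integer matrix individuals x sites in {0, 1, NA}), `alt_on_hap1`,
#'   and `individuals`.
#' @export
genotype_to_haplotype <- function(m, phased) {
  stopifnot(inherits(phased, "phased_snvs"))
  if (ncol(m$geno) != length(phased$alt_on_hap1))
    stopf("matrix and phasing describe different site sets")
  g <- m$geno
  g[g == GT_HOM_ALT] <- GT_HET  # defensive: treat any residual 2 as ALT-carrying
  a <- as.integer(phased$alt_on_hap1)
  ## het & alt-on-hap1 -> hap1 (0); hom-ref & alt-on-hap1 -> hap2 (1); mirrored
  L <- abs(sweep(g, 2, a, "-"))
  L[, is.na(phased$alt_on_hap1)] <- NA_integer_
  storage.mode(L) <- "integer"
  structure(list(sites = m$sites, labels = L,
                 alt_on_hap1 = phased$alt_on_hap1,
                 individuals = rownames(m$geno)),
            class = "hap_labels")
}

#' @export
print.hap_labels <- function(x, ...) {
  cat(sprintf("hap_labels: %d individuals x %d sites (%.1f%% missing)\n",
              nrow(x$labels), ncol(x$labels),
              100 * mean(is.na(x$labels))))
  invisible(x)
}

#' Write the phase table and label matrix as TSV
#'
#' @param phased A [phase_snvs()] result.
#' @param m The matching [snv_matrix()].
#' @param path Output TSV path (chrom, pos, hap1 allele, hap2 allele).
#' @return Invisibly, the path.
#' @export
write_phase_table <- function(phased, m, path) {
  a <- phased$alt_on_hap1
  out <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                    hap1_allele = ifelse(is.na(a), ".",
                                         ifelse(a, m$sites$alt, m$sites$ref)),
                    hap2_allele = ifelse(is.na(a), ".",
                                         ifelse(a, m$sites$ref, m$sites$alt)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_table
#' @param labels A [genotype_to_haplotype()] result.
#' @export
write_label_matrix <- function(labels, path) {
  out <- cbind(labels$sites[c("chrom", "pos")],
               as.data.frame(t(labels$labels)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
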