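## Genotype codes used throughout: 0 = HOM_REF, 1 = HET, 2 = HOM_ALT,
## NA = MISSING.  Sites are 1-based and sorted within chromosome; columns of
## the genotype/depth matrices are parallel to rows of `sites`.

GT_HOM_REF <- 0L
GT_HET     <- 1L
GT_HOM_ALT <- 2L

#' Construct an SNV genotype matrix
#'
#' The central container of the pipeline: a per-site by per-individual
#' genotype matrix with read depths, for markers segregating 1:1 in an F1
#' pseudo-testcross (heterozygous parent x inbred parent).
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per site, sorted by position within chromosome.
#' @param geno integer matrix, individuals x sites; codes 0 (hom-ref),
#'   1 (het), 2 (hom-alt), `NA` (missing).
#' @param depth integer matrix of read depths, same shape as `geno`.
#' @return An object of class `snv_matrix`.
#' @export
snv_matrix <- function(sites, geno, depth) {
  sites <- as.data.frame(sites)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(sites)))
    stopf("sites must have columns %s", paste(need, collapse = ", "))
  geno <- as.matrix(geno); storage.mode(geno) <- "integer"
  depth <- as.matrix(depth); storage.mode(depth) <- "integer"
  if (!all(dim(geno) == dim(depth)))
    stopf("geno and depth must have identical dimensions")
  if (ncol(geno) != nrow(sites))
    stopf("ncol(geno) [%d] must equal nrow(sites) [%d]", ncol(geno), nrow(sites))
  if (any(depth < 0, na.rm = TRUE)) stopf("depths must be non-negative")
  bad <- !(geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stopf("genotype codes must be 0, 1, 2 or NA")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      d <- p[which(diff(p) <= 0)[1] + 1]
      stopf("positions not strictly increasing on %s (near %s:%d)", ch, ch, d)
    }
  }
  if (is.null(rownames(geno)))
    rownames(geno) <- paste0("ind", seq_len(nrow(geno)))
  rownames(depth) <- rownames(geno)
  structure(list(sites = sites, geno = geno, depth = depth),
            class = "snv_matrix")
}

#' @export
print.snv_matrix <- function(x, ...) {
  nm <- sum(is.na(x$geno))
  cat(sprintf("snv_matrix: %d individuals x %d sites on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$sites$chrom))))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * nm / length(x$geno)))
  invisible(x)
}

#' @export
dim.snv_matrix <- function(x) dim(x$geno)

## Subset an snv_matrix by site index (keeps all individuals).
subset_sites <- function(m, keep) {
  snv_matrix(m$sites[keep, , drop = FALSE],
             m$geno[, keep, drop = FALSE],
             m$depth[, keep, drop = FALSE])
}

#' Sites of an SNV matrix as a GRanges
#' @param m An [snv_matrix()].
#' @return A width-1 `GRanges`, one range per site.
#' @export
sites_granges <- function(m) {
  GenomicRanges::GRanges(m$sites$chrom,
                         IRanges::IRanges(m$sites$pos, width = 1))
}

#' Write an SNV matrix as VCF
#'
#' Emits a minimal VCF 4.2 with per-sample `GT:DP` fields (1-based
#' positions; missing genotypes as `./.`).  Writing goes through
#' \pkg{vcfR}, which gzip-compresses the output.
#'
#' @param m An [snv_matrix()].
#' @param path Output path; `.gz` is appended if absent.
#' @param layout Optional [genome_layout()] used to emit contig header lines.
#' @return Invisibly, the path written.
#' @export
write_snv_vcf <- function(m, path, layout = NULL) {
  if (!grepl("\\.gz$", path)) path <- paste0(path, ".gz")
  meta <- c("##fileformat=VCFv4.2",
            "##source=xomap",
            '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
            '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  if (!is.null(layout))
    meta <- c(meta, sprintf("##contig=<ID=%s,length=%d>",
                            names(layout), as.integer(layout)))
  ns <- nrow(m$sites)
  fix <- cbind(CHROM = as.character(m$sites$chrom),
               POS = as.character(m$sites$pos),
               ID = rep(".", ns),
               REF = as.character(m$sites$ref),
               ALT = as.character(m$sites$alt),
               QUAL = rep(".", ns),
               FILTER = rep("PASS", ns),
               INFO = rep(".", ns))
  gt_chr <- matrix("./.", nrow(m$geno), ncol(m$geno))
  gt_chr[m$geno == 0L] <- "0/0"
  gt_chr[m$geno == 1L] <- "0/1"
  gt_chr[m$geno == 2L] <- "1/1"
  dp <- m$depth; dp[is.na(dp)] <- 0L
  body <- matrix(paste(gt_chr, dp, sep = ":"),
                 nrow = nrow(m$geno), ncol = ncol(m$geno))
  gt <- cbind(FORMAT = rep("GT:DP", ns), t(body))
  colnames(gt) <- c("FORMAT", rownames(m$geno))
  v <- new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
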