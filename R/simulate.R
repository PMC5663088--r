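## Meiosis + low-coverage sequencing simulator for a one-way pseudo-testcross:
## a heterozygous parent (two segregating haplotypes) crossed to an inbred
## parent, so each F1 inherits one recombinant parental haplotype and every
## marker segregates hom-ref : het 1:1.

#' Simulate the two haplotypes of a heterozygous parent
#'
#' Draws SNV sites along each chromosome and places the ALT allele on
#' haplotype 1 or haplotype 2 with equal probability, mirroring the balanced
#' distribution of alternative alleles between parental haplotypes seen in
#' real testcross parents.
#'
#' @param layout A [genome_layout()].
#' @param snv_density Expected heterozygous SNVs per Mb (> 0); per-chromosome
#'   counts are Poisson.
#' @param seed Optional integer seed.
#' @return An object of class `parental_haplotypes`: list with `layout` and
#'   `sites` (data.frame `chrom`, `pos`, `ref`, `alt`, `alt_on_hap1`).
#' @export
simulate_parents <- function(layout, snv_density = 1000, seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (snv_density <= 0) stopf("snv_density must be > 0")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    out <- lapply(names(layout), function(ch) {
      len <- layout[[ch]]
      n <- rpois(1, snv_density * len / 1e6)
      n <- max(n, 2L)  # a chromosome needs at least one marker pair
      pos <- sort(sample.int(len, min(n, len)))
      ref <- sample(bases, length(pos), replace = TRUE)
      alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
      data.frame(chrom = ch, pos = pos, ref = ref, alt = unname(alt),
                 alt_on_hap1 = runif(length(pos)) < 0.5,
                 stringsAsFactors = FALSE)
    })
    sites <- do.call(rbind, out)
    rownames(sites) <- NULL
    structure(list(layout = layout, sites = sites),
              class = "parental_haplotypes")
  })
}

#' @export
print.parental_haplotypes <- function(x, ...) {
  cat(sprintf("parental_haplotypes: %d sites on %d chromosome(s); %.1f%% ALT on hap1\n",
              nrow(x$sites), length(x$layout), 100 * mean(x$sites$alt_on_hap1)))
  invisible(x)
}

#' Crossover position density profiles
#'
#' Discretized densities on relative chromosome position `[0, 1]`, used by
#' [simulate_meiosis()].  `co_density_uniform()` is flat;
#' `co_density_ushape()` is a symmetric U-shape that concentrates crossovers
#' in distal chromosome regions and depletes the (peri)centromeric middle,
#' the pattern typical of large plant chromosomes.
#'
#' @param n_bins Number of equal-width bins on `[0, 1]`.
#' @param floor Minimum relative density in the chromosome middle (U-shape
#'   only); larger values flatten the profile.
#' @return Numeric vector of non-negative bin weights (normalized to sum 1).
#' @export
co_density_uniform <- function(n_bins = 100) rep(1 / n_bins, n_bins)

#' @rdname co_density_uniform
#' @export
co_density_ushape <- function(n_bins = 100, floor = 0.1) {
  u <- (seq_len(n_bins) - 0.5) / n_bins
  w <- floor + (1 - floor) * (2 * (u - 0.5))^2
  w / sum(w)
}

## Sample n relative positions in [0,1] from a discretized density.
sample_profile <- function(n, profile) {
  if (n == 0) return(numeric(0))
  profile <- profile / sum(profile)
  b <- sample.int(length(profile), n, replace = TRUE, prob = profile)
  (b - runif(n)) / length(profile)
}

#' Simulate one meiosis of the heterozygous parent
#'
#' Per chromosome, the crossover count is Poisson(`lambda_co`) (no
#' interference) and crossover positions are i.i.d. draws from
#' `density_profile`, each placed in the gap between its two flanking SNVs.
#' The gamete is the alternating sequence of parental haplotype segments.
#' Crossovers falling outside the marker range, and pairs landing in the
#' same inter-SNV gap (which cancel and are invisible to any marker-based
#' detector), are not recorded: the recorded breakpoints are exactly the
#' haplotype switches present in the gamete.
#'
#' @param parents A [simulate_parents()] result.
#' @param lambda_co Expected crossovers per chromosome (>= 0).
#' @param density_profile Discretized density on `[0, 1]`
#'   (see [co_density_ushape()]).
#' @param seed Optional integer seed.
#' @return List with `hap` (integer vector per site: 0 = haplotype 1,
#'   1 = haplotype 2) and `crossovers` (data.frame `chrom`, `pos`,
#'   `left_pos`, `right_pos`).
#' @export
simulate_meiosis <- function(parents, lambda_co = 1,
                             density_profile = co_density_ushape(),
                             seed = NULL) {
  stopifnot(inherits(parents, "parental_haplotypes"))
  if (lambda_co < 0) stopf("lambda_co must be >= 0")
  if (any(density_profile < 0) || sum(density_profile) <= 0)
    stopf("density_profile must be non-negative with positive mass")
  with_seed(seed, {
    sites <- parents$sites
    hap <- integer(nrow(sites))
    cos <- list()
    for (ch in names(parents$layout)) {
      idx <- which(sites$chrom == ch)
      pos <- sites$pos[idx]
      len <- parents$layout[[ch]]
      n_co <- rpois(1, lambda_co)
      bp <- sort(round(sample_profile(n_co, density_profile) * len))
      bp <- pmin(pmax(bp, 1), len)
      ## gap index g: crossover lies between SNVs g and g+1 (0 or n = outside)
      g <- findInterval(bp, pos)
      ok <- g >= 1 & g < length(pos)
      bp <- bp[ok]; g <- g[ok]
      ## two crossovers in one gap cancel; keep gaps hit an odd number of times
      tab <- table(g)
      eff <- as.integer(names(tab))[as.integer(tab) %% 2 == 1]
      eff <- sort(eff)
      start <- rbinom(1, 1, 0.5)
      seg <- cumsum(tabulate(eff + 1L, nbins = length(pos)))
      ## tabulate(eff+1): switch takes effect at SNV index eff+1
      hap[idx] <- (start + seg) %% 2L
      if (length(eff)) {
        keep_bp <- bp[match(eff, g)]  # representative physical position
        cos[[ch]] <- data.frame(chrom = ch, pos = keep_bp,
                                left_pos = pos[eff], right_pos = pos[eff + 1L],
                                stringsAsFactors = FALSE)
      }
    }
    crossovers <- if (length(cos)) do.call(rbind, cos) else
      data.frame(chrom = character(0), pos = numeric(0),
                 left_pos = numeric(0), right_pos = numeric(0))
    rownames(crossovers) <- NULL
    list(hap = hap, crossovers = crossovers)
  })
}

#' Simulate a sequenced F1 pseudo-testcross population
#'
#' For every individual a gamete is drawn by [simulate_meiosis()]; the other
#' parent contributes the REF allele at every segregating site, so the true
#' genotype is het where the inherited haplotype carries ALT and hom-ref
#' otherwise.  Sequencing is modeled per site and individual as depth
#' ~ Poisson(`coverage`) with reads drawn from the two alleles and per-read
#' base error `base_error`:
#' \itemize{
#'   \item truly het: any ALT read yields a het call, otherwise hom-ref
#'     (allele dropout);
#'   \item truly hom-ref: no ALT read yields hom-ref; all reads erroneously
#'     ALT yields a spurious hom-alt call; a proper subset yields het.
#' }
#' Calls with depth below `depth_floor` are missing, and an additional
#' i.i.d. missingness `missing_rate` can be applied on top.
#'
#' @param parents A [simulate_parents()] result.
#' @param n_individuals Number of F1 individuals (>= 2).
#' @param lambda_co,density_profile Passed to [simulate_meiosis()].
#' @param coverage Mean sequencing depth per site (> 0).
#' @param base_error Per-read base error rate in `[0, 0.5)`.
#' @param missing_rate Extra i.i.d. per-call missingness in `[0, 1]`.
#' @param depth_floor Depth below which a call is missing (default 1:
#'   only zero-depth calls are missing).
#' @param seed Integer seed; all randomness flows from it.
#' @return List with `matrix` (an [snv_matrix()]) and `truth` (class
#'   `sim_truth`: `hap` label matrix, `crossovers` data.frame with an
#'   `individual` column, and `params`).
#' @export
simulate_population <- function(parents, n_individuals = 90, lambda_co = 1,
                                density_profile = co_density_ushape(),
                                coverage = 2, base_error = 0.01,
                                missing_rate = 0, depth_floor = 1,
                                seed = 1) {
  stopifnot(inherits(parents, "parental_haplotypes"))
  if (n_individuals < 2) stopf("n_individuals must be >= 2")
  if (coverage <= 0) stopf("coverage must be > 0")
  if (base_error < 0 || base_error >= 0.5) stopf("base_error must be in [0, 0.5)")
  if (missing_rate < 0 || missing_rate > 1) stopf("missing_rate must be in [0, 1]")
  with_seed(seed, {
    sites <- parents$sites
    ns <- nrow(sites)
    inds <- paste0("ind", seq_len(n_individuals))
    H <- matrix(NA_integer_, n_individuals, ns, dimnames = list(inds, NULL))
    colist <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      g <- simulate_meiosis(parents, lambda_co, density_profile, seed = NULL)
      H[i, ] <- g$hap
      if (nrow(g$crossovers)) {
        g$crossovers$individual <- inds[i]
        colist[[i]] <- g$crossovers
      }
    }
    crossovers <- do.call(rbind, colist[!vapply(colist, is.null, TRUE)])
    if (is.null(crossovers))
      crossovers <- data.frame(chrom = character(0), pos = numeric(0),
                               left_pos = numeric(0), right_pos = numeric(0),
                               individual = character(0))
    rownames(crossovers) <- NULL
    a <- sites$alt_on_hap1
    het <- sweep(H == 0L, 2, a, "&") | sweep(H == 1L, 2, !a, "&")
    D <- matrix(rpois(length(H), coverage), n_individuals, ns)
    p_alt <- ifelse(het, 0.5, base_error)
    n_alt <- matrix(rbinom(length(D), as.vector(D), as.vector(p_alt)),
                    n_individuals, ns)
    G <- matrix(GT_HOM_REF, n_individuals, ns)
    G[het & n_alt >= 1L] <- GT_HET
    G[!het & n_alt >= 1L & n_alt < D] <- GT_HET
    G[!het & D >= 1L & n_alt == D] <- GT_HOM_ALT
    G[D < depth_floor] <- NA_integer_
    if (missing_rate > 0)
      G[runif(length(G)) < missing_rate] <- NA_integer_
    dimnames(G) <- list(inds, NULL)
    m <- snv_matrix(sites[c("chrom", "pos", "ref", "alt")], G, D)
    truth <- structure(
      list(hap = H, crossovers = crossovers, sites = sites,
           params = list(lambda_co = lambda_co, coverage = coverage,
                         base_error = base_error, missing_rate = missing_rate,
                         depth_floor = depth_floor, seed = seed)),
      class = "sim_truth")
    list(matrix = m, truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d individuals, %d sites, %d true crossovers\n",
              nrow(x$hap), ncol(x$hap), nrow(x$crossovers)))
  invisible(x)
}

#' Simulate a gene/transposon annotation with optional promoter bias
#'
#' Places non-overlapping gene models (5'UTR, alternating exons and introns,
#' 3'UTR partitioning the gene body exactly), derives promoters (1 kb
#' upstream of the TSS) and 1-kb downstream regions, and scatters
#' Stowaway-class MITE intervals (lengths centered on the 224-bp family
#' median).  Each element lands inside a random gene's promoter with
#' probability `stowaway_tss_bias` and uniformly on the genome otherwise.
#' Intergenic space is everything at least 2 kb from any gene, excluding
#' transposons.
#'
#' @param layout A [genome_layout()].
#' @param n_genes Number of gene models to place.
#' @param stowaway_tss_bias Probability in `[0, 1]` that an element inserts
#'   in a promoter.
#' @param n_stowaway Number of Stowaway elements (default `n_genes`).
#' @param seed Optional integer seed.
#' @return List of class `annotation_set` with `genes` (`GRanges`) and
#'   `features` (`GRanges` with a `class` column: `five_prime_UTR`, `exon`,
#'   `intron`, `three_prime_UTR`, `promoter`, `downstream1kb`,
#'   `TE:Stowaway`, `intergenic`).
#' @export
simulate_annotation <- function(layout, n_genes = 200, stowaway_tss_bias = 0.5,
                                n_stowaway = n_genes, seed = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  if (stowaway_tss_bias < 0 || stowaway_tss_bias > 1)
    stopf("stowaway_tss_bias must be in [0, 1]")
  with_seed(seed, {
    si <- as_seqinfo(layout)
    tot <- sum(layout)
    per_chr <- pmax(1L, round(n_genes * as.numeric(layout) / tot))
    margin <- 3000  # promoter + spacing either side
    genes <- list(); parts <- list()
    gid <- 0L
    for (ci in seq_along(layout)) {
      ch <- names(layout)[ci]; len <- layout[[ci]]
      ng <- per_chr[ci]
      slot <- floor(len / ng)
      for (s in seq_len(ng)) {
        gid <- gid + 1L
        n_ex <- sample(1:5, 1)
        ex <- round(runif(n_ex, 150, 400))
        intr <- if (n_ex > 1) round(runif(n_ex - 1, 100, 800)) else integer(0)
        u5 <- 200L; u3 <- 300L
        glen <- u5 + sum(ex) + sum(intr) + u3
        if (glen + 2 * margin > slot)
          stopf("gene density too high to place without overlap on %s (need %d bp per gene, slot %d bp); reduce n_genes",
                ch, glen + 2 * margin, slot)
        lo <- (s - 1) * slot + margin + 1
        hi <- s * slot - margin - glen
        gstart <- floor(runif(1, lo, hi))
        strand <- sample(c("+", "-"), 1)
        widths <- c(u5, as.vector(rbind(ex, c(intr, NA)))[-(2 * n_ex)], u3)
        types <- c("five_prime_UTR",
                   as.vector(rbind(rep("exon", n_ex),
                                   c(rep("intron", n_ex - 1), NA)))[-(2 * n_ex)],
                   "three_prime_UTR")
        if (strand == "-") { widths <- rev(widths); types <- rev(types) }
        starts <- gstart + cumsum(c(0, head(widths, -1)))
        parts[[length(parts) + 1L]] <- data.frame(
          chrom = ch, start = starts, end = starts + widths - 1,
          class = types, strand = strand, gene_id = gid)
        genes[[length(genes) + 1L]] <- data.frame(
          chrom = ch, start = gstart, end = gstart + glen - 1,
          strand = strand, gene_id = gid)
      }
    }
    genes <- do.call(rbind, genes)
    parts <- do.call(rbind, parts)
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start, genes$end),
                                  strand = genes$strand, seqinfo = si)
    ggr$gene_id <- genes$gene_id
    tss <- ifelse(genes$strand == "+", genes$start, genes$end)
    tts <- ifelse(genes$strand == "+", genes$end, genes$start)
    prom <- data.frame(chrom = genes$chrom,
                       start = ifelse(genes$strand == "+", tss - 1000, tss + 1),
                       end = ifelse(genes$strand == "+", tss - 1, tss + 1000),
                       class = "promoter", strand = genes$strand,
                       gene_id = genes$gene_id)
    down <- data.frame(chrom = genes$chrom,
                       start = ifelse(genes$strand == "+", tts + 1, tts - 1000),
                       end = ifelse(genes$strand == "+", tts + 1000, tts - 1),
                       class = "downstream1kb", strand = genes$strand,
                       gene_id = genes$gene_id)
    ## Stowaway MITEs
    te <- NULL
    if (n_stowaway > 0) {
      te_len <- pmax(80L, round(rnorm(n_stowaway, 224, 40)))
      in_prom <- runif(n_stowaway) < stowaway_tss_bias
      te_chrom <- character(n_stowaway); te_start <- numeric(n_stowaway)
      for (t in seq_len(n_stowaway)) {
        if (in_prom[t]) {
          g <- sample.int(nrow(genes), 1)
          room <- 1000 - te_len[t]
          off <- if (room > 0) floor(runif(1, 0, room + 1)) else 0
          te_chrom[t] <- genes$chrom[g]
          te_start[t] <- if (genes$strand[g] == "+")
            tss[g] - 1000 + off else tss[g] + 1000 - te_len[t] - off
        } else {
          ci <- sample.int(length(layout), 1, prob = as.numeric(layout))
          te_chrom[t] <- names(layout)[ci]
          te_start[t] <- floor(runif(1, 1, layout[[ci]] - te_len[t]))
        }
      }
      te <- data.frame(chrom = te_chrom, start = te_start,
                       end = te_start + te_len - 1, class = "TE:Stowaway",
                       strand = "*", gene_id = NA_integer_)
    }
    feat <- rbind(parts[c("chrom", "start", "end", "class", "strand", "gene_id")],
                  prom, down,
                  if (!is.null(te)) te)
    fgr <- GenomicRanges::GRanges(feat$chrom,
                                  IRanges::IRanges(pmax(1, feat$start),
                                                   feat$end),
                                  strand = feat$strand, seqinfo = si)
    fgr$class <- feat$class
    fgr$gene_id <- feat$gene_id
    fgr <- GenomicRanges::trim(fgr)
    ## intergenic: >= 2 kb from genes, excluding TEs
    pad <- GenomicRanges::resize(ggr, GenomicRanges::width(ggr) + 4000,
                                 fix = "center")
    inter <- GenomicRanges::gaps(GenomicRanges::reduce(pad,
                                                       ignore.strand = TRUE))
    inter <- inter[GenomicRanges::strand(inter) == "*"]
    if (!is.null(te)) {
      tegr <- fgr[fgr$class == "TE:Stowaway"]
      inter <- GenomicRanges::setdiff(inter, tegr, ignore.strand = TRUE)
    }
    if (length(inter)) {
      inter$class <- "intergenic"
      inter$gene_id <- NA_integer_
      fgr <- c(fgr, inter)
    }
    structure(list(genes = ggr, features = fgr, layout = layout),
              class = "annotation_set")
  })
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d genes, %d feature intervals\n",
              length(x$genes), length(x$features)))
  print(table(x$features$class))
  invisible(x)
}

#' Simulate a per-bin signal track
#'
#' Gamma-noise background with optional multiplicative enrichment over a set
#' of anchor intervals; a convenience generator for read-count-like tracks
#' (DNase, ChIP) used when exercising the enrichment statistics.
#'
#' @param layout A [genome_layout()].
#' @param binsize Bin width in bp.
#' @param background Mean background signal per bin.
#' @param anchors Optional `GRanges`; bins overlapping them get
#'   `peak_fold` times the background mean.
#' @param peak_fold Fold enrichment at anchors.
#' @param seed Optional integer seed.
#' @return A `GRanges` with a numeric `score` column (bedGraph-like).
#' @export
simulate_signal_track <- function(layout, binsize = 1000, background = 10,
                                  anchors = NULL, peak_fold = 5, seed = NULL) {
  with_seed(seed, {
    bins <- layout_bins(layout, binsize)
    mu <- rep(background, length(bins))
    if (!is.null(anchors)) {
      hit <- GenomicRanges::countOverlaps(bins, anchors,
                                          ignore.strand = TRUE) > 0
      mu[hit] <- mu[hit] * peak_fold
    }
    bins$score <- rpois(length(bins), mu)
    bins
  })
}

#' Export simulation truth and annotation artifacts
#'
#' `write_truth_bed()` writes true crossover breakpoints as BED6 (0-based
#' half-open inter-SNV gaps, name = individual); `write_annotation_gff3()`
#' writes the feature set as GFF3; `write_signal_bedgraph()` writes a scored
#' track as bedGraph.
#'
#' @param truth A `sim_truth` object.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_truth_bed <- function(truth, path) {
  co <- truth$crossovers
  gr <- GenomicRanges::GRanges(co$chrom,
                               IRanges::IRanges(co$left_pos, co$right_pos))
  gr$name <- co$individual
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_truth_bed
#' @param ann An `annotation_set`.
#' @export
write_annotation_gff3 <- function(ann, path) {
  gr <- ann$features
  gr$type <- gr$class
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}

#' @rdname write_truth_bed
#' @param track A `GRanges` with a `score` column.
#' @export
write_signal_bedgraph <- function(track, path) {
  GenomicRanges::strand(track) <- "*"
  rtracklayer::export(track, path, format = "bedGraph")
  invisible(path)
}
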