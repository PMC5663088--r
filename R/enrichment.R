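## Interval-level enrichment statistics around crossovers: feature overlap
## with Monte-Carlo shuffle nulls, matched cold-region sampling,
## transposon-family Fisher tests, aggregate (metagene-style) profiles,
## binned rank correlations, Poisson goodness-of-fit of crossover counts,
## a crossover-count GLM, and the promoter/Stowaway quartile analyses.

## ---- overlap machinery ----------------------------------------------------

feature_classes_ <- function(features) {
  cls <- features$class
  if (is.null(cls)) cls <- rep("feature", length(features))
  as.character(cls)
}

#' Count query intervals overlapping each feature class
#'
#' A 1-bp minimum overlap is used and a query counts toward every class it
#' touches, so per-class rates need not sum to one.
#'
#' @param queries A `GRanges` of query intervals (e.g. crossovers).
#' @param features A `GRanges` with a `class` metadata column.
#' @return data.frame: `class`, `count` (queries touching >= 1 feature of
#'   the class), `rate` (`count / length(queries)`).
#' @export
overlap_counts <- function(queries, features) {
  cls <- feature_classes_(features)
  classes <- sort(unique(cls))
  cnt <- vapply(classes, function(cl) {
    sum(GenomicRanges::countOverlaps(
      queries, features[cls == cl], ignore.strand = TRUE) > 0)
  }, numeric(1))
  data.frame(class = classes, count = as.integer(cnt),
             rate = cnt / max(length(queries), 1L), row.names = NULL)
}

## Place length-matched intervals uniformly at random, preserving each
## interval's chromosome.
shuffle_intervals_ <- function(queries, layout, genome_wide = FALSE) {
  w <- GenomicRanges::width(queries)
  chr <- as.character(GenomicRanges::seqnames(queries))
  if (genome_wide)
    chr <- sample(names(layout), length(queries), replace = TRUE,
                  prob = as.numeric(layout))
  len <- as.numeric(layout[chr])
  if (any(w > len))
    stopf("an interval is longer than its chromosome; cannot shuffle")
  start <- floor(runif(length(w), 1, len - w + 2))
  GenomicRanges::GRanges(chr, IRanges::IRanges(start, width = w))
}

#' Monte-Carlo shuffle test of feature overlap
#'
#' Compares the observed per-class overlap rate of the queries against a
#' null built by placing length-matched intervals uniformly at random
#' (chromosome assignment preserved by default).  Empirical p-values use
#' the add-one estimator `(1 + r) / (1 + n_perm)`, reported for both
#' enrichment and depletion, alongside the null mean and SD of the rate.
#'
#' @param queries,features As in [overlap_counts()].
#' @param layout A [genome_layout()].
#' @param n_perm Number of permutations (> 0; 10,000 in a full analysis).
#' @param genome_wide Place shuffled intervals on any chromosome
#'   (probability proportional to length) instead of their own.
#' @param seed Optional integer seed.
#' @return data.frame per class: `count`, `rate`, `null_mean`, `null_sd`,
#'   `p_enrich`, `p_deplete`.
#' @export
shuffle_mc <- function(queries, layout, features, n_perm = 10000,
                       genome_wide = FALSE, seed = NULL) {
  if (n_perm <= 0) stopf("n_perm must be positive")
  obs <- overlap_counts(queries, features)
  cls <- feature_classes_(features)
  flist <- lapply(obs$class, function(cl) features[cls == cl])
  nq <- length(queries)
  w <- GenomicRanges::width(queries)
  chr0 <- as.character(GenomicRanges::seqnames(queries))
  if (!genome_wide && any(w > as.numeric(layout[chr0])))
    stopf("an interval is longer than its chromosome; cannot shuffle")
  with_seed(seed, {
    null <- matrix(NA_real_, n_perm, nrow(obs))
    ## permutations are materialized in blocks of ~2e5 intervals so one
    ## overlap query serves many permutations
    block <- max(1L, floor(2e5 / nq))
    done <- 0L
    while (done < n_perm) {
      b <- min(block, n_perm - done)
      chr <- if (genome_wide)
        sample(names(layout), b * nq, replace = TRUE,
               prob = as.numeric(layout)) else rep(chr0, b)
      len <- as.numeric(layout[chr])
      wv <- rep(w, b)
      if (any(wv > len))
        stopf("an interval is longer than its chromosome; cannot shuffle")
      start <- floor(runif(b * nq, 1, len - wv + 2))
      gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start, width = wv))
      pid <- rep(seq_len(b), each = nq)
      for (j in seq_along(flist)) {
        hit <- GenomicRanges::countOverlaps(gr, flist[[j]],
                                            ignore.strand = TRUE) > 0
        null[done + seq_len(b), j] <- tabulate(pid[hit], nbins = b) / nq
      }
      done <- done + b
    }
    obs$null_mean <- colMeans(null)
    obs$null_sd <- apply(null, 2, sd)
    obs$p_enrich <- vapply(seq_len(nrow(obs)), function(j)
      empirical_p(obs$rate[j], null[, j], "greater"), numeric(1))
    obs$p_deplete <- vapply(seq_len(nrow(obs)), function(j)
      empirical_p(obs$rate[j], null[, j], "less"), numeric(1))
    obs
  })
}

## ---- matched cold regions -------------------------------------------------

## GC content of regions from either a per-window GC track (GRanges with a
## `score` fraction) or a DNAStringSet of chromosome sequences.
region_gc_ <- function(gr, gc) {
  if (methods::is(gc, "GRanges")) {
    hits <- GenomicRanges::findOverlaps(gr, gc, ignore.strand = TRUE)
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    gc[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    s <- gc$score[S4Vectors::subjectHits(hits)] * w
    num <- tapply(s, S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    out <- rep(NA_real_, length(gr))
    out[as.integer(names(num))] <- num / den
    out
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      stopf("Biostrings is required to compute GC from sequence")
    seqs <- Biostrings::getSeq(gc, gr)
    as.numeric(Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))
  }
}

region_snv_density_ <- function(gr, snvs) {
  GenomicRanges::countOverlaps(gr, snvs, ignore.strand = TRUE) /
    GenomicRanges::width(gr)
}

#' Sample recombination cold regions matched to crossovers
#'
#' For every crossover interval, rejection-samples a control region
#' satisfying: (i) GC content within `tol` (relative) of the match;
#' (ii) 10-1000 kb (the `band`) from any crossover; (iii) identical
#' length; (iv) SNV density within `tol` (relative); (v) same chromosome.
#' Candidates are drawn uniformly within the distance band around the
#' matched crossover.
#'
#' @param crossovers `GRanges` of crossover intervals.
#' @param layout A [genome_layout()].
#' @param gc GC source: per-window `GRanges` track with fraction `score`,
#'   or a `DNAStringSet` of chromosome sequences.
#' @param snvs `GRanges` (width 1) of segregating SNV positions.
#' @param band Numeric length-2 distance band in bp (default
#'   `c(1e4, 1e6)`).
#' @param tol Relative matching tolerance for GC and SNV density
#'   (default 0.10).
#' @param max_tries Sampling attempts per region before giving up.
#' @param on_fail `"error"` (default) to fail loudly naming the criterion
#'   that failed most, or `"warn"` to drop unmatchable regions.
#' @param seed Optional integer seed.
#' @return `GRanges` of cold regions with metadata `matched` (index of the
#'   matched crossover), `gc`, `snv_density`.
#' @export
sample_cold_regions <- function(crossovers, layout, gc, snvs,
                                band = c(1e4, 1e6), tol = 0.10,
                                max_tries = 2000,
                                on_fail = c("error", "warn"), seed = NULL) {
  on_fail <- match.arg(on_fail)
  with_seed(seed, {
    n <- length(crossovers)
    chr <- as.character(GenomicRanges::seqnames(crossovers))
    w <- GenomicRanges::width(crossovers)
    xo_gc <- region_gc_(crossovers, gc)
    xo_sd <- region_snv_density_(crossovers, snvs)
    res_start <- numeric(n); ok <- logical(n)
    fail_reason <- character(0)
    for (i in seq_len(n)) {
      len <- as.numeric(layout[[chr[i]]])
      cstart <- GenomicRanges::start(crossovers)[i]
      fails <- c(gc = 0L, distance = 0L, snv_density = 0L, bounds = 0L)
      for (t in seq_len(max_tries)) {
        off <- floor(runif(1, band[1], band[2] + 1)) *
          sample(c(-1, 1), 1)
        s <- cstart + off
        if (s < 1 || s + w[i] - 1 > len) { fails["bounds"] <- fails["bounds"] + 1L; next }
        cand <- GenomicRanges::GRanges(chr[i], IRanges::IRanges(s, width = w[i]))
        dst <- GenomicRanges::distanceToNearest(cand, crossovers,
                                                ignore.strand = TRUE)
        dmin <- as.numeric(S4Vectors::mcols(dst)$distance)
        if (!length(dmin) || dmin < band[1] || dmin > band[2]) {
          fails["distance"] <- fails["distance"] + 1L; next
        }
        g <- region_gc_(cand, gc)
        if (is.na(g) || is.na(xo_gc[i]) ||
            abs(g - xo_gc[i]) > tol * xo_gc[i]) {
          fails["gc"] <- fails["gc"] + 1L; next
        }
        sdens <- region_snv_density_(cand, snvs)
        if (abs(sdens - xo_sd[i]) > tol * xo_sd[i]) {
          fails["snv_density"] <- fails["snv_density"] + 1L; next
        }
        res_start[i] <- s; ok[i] <- TRUE
        break
      }
      if (!ok[i])
        fail_reason <- c(fail_reason, sprintf(
          "region %d (%s:%d, %d bp): most-failed criterion '%s'",
          i, chr[i], cstart, w[i], names(which.max(fails))))
    }
    if (length(fail_reason)) {
      msg <- sprintf("could not match %d of %d cold region(s):\n  %s",
                     sum(!ok), n,
                     paste(head(fail_reason, 10), collapse = "\n  "))
      if (on_fail == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    cold <- GenomicRanges::GRanges(chr[ok],
                                   IRanges::IRanges(res_start[ok],
                                                    width = w[ok]))
    cold$matched <- which(ok)
    cold$gc <- region_gc_(cold, gc)
    cold$snv_density <- region_snv_density_(cold, snvs)
    cold
  })
}

#' Validate matched cold regions against their criteria
#'
#' Independent post-hoc checker: re-derives every matching criterion for
#' each emitted region.
#'
#' @inheritParams sample_cold_regions
#' @param cold A [sample_cold_regions()] result.
#' @return Logical matrix, one row per cold region, columns `gc`,
#'   `distance`, `length`, `snv_density`, `chromosome`.
#' @export
validate_cold_regions <- function(cold, crossovers, gc, snvs,
                                  band = c(1e4, 1e6), tol = 0.10) {
  m <- cold$matched
  xo <- crossovers[m]
  xo_gc <- region_gc_(xo, gc)
  xo_sd <- region_snv_density_(xo, snvs)
  dst <- GenomicRanges::distanceToNearest(cold, crossovers,
                                          ignore.strand = TRUE)
  dmin <- rep(NA_real_, length(cold))
  dmin[S4Vectors::queryHits(dst)] <- as.numeric(S4Vectors::mcols(dst)$distance)
  cbind(gc = abs(region_gc_(cold, gc) - xo_gc) <= tol * xo_gc,
        distance = !is.na(dmin) & dmin >= band[1] & dmin <= band[2],
        length = GenomicRanges::width(cold) == GenomicRanges::width(xo),
        snv_density = abs(region_snv_density_(cold, snvs) - xo_sd) <=
          tol * xo_sd,
        chromosome = as.character(GenomicRanges::seqnames(cold)) ==
          as.character(GenomicRanges::seqnames(xo)))
}

## ---- TE-family Fisher tests -----------------------------------------------

#' Fisher tests of transposon-family content, crossovers vs cold regions
#'
#' For each family, builds the 2x2 table of intervals containing at least
#' one element of the family versus not, in the crossover and matched cold
#' sets, and applies a two-sided Fisher exact test with Bonferroni
#' correction across families.  Families present in neither set are
#' skipped.
#'
#' @param crossovers,cold Equal-size `GRanges` sets.
#' @param te_features `GRanges` of transposon copies with a `class` (or
#'   `family`) metadata column.
#' @return data.frame per family: `n_crossover`, `n_cold`, `odds_ratio`,
#'   `p`, `p_bonferroni`.
#' @export
te_family_fisher <- function(crossovers, cold, te_features) {
  if (length(crossovers) != length(cold))
    stopf("crossover and cold sets must have equal size")
  fam <- te_features$family %||% feature_classes_(te_features)
  fams <- sort(unique(as.character(fam)))
  rows <- lapply(fams, function(fm) {
    fgr <- te_features[fam == fm]
    a <- sum(GenomicRanges::countOverlaps(crossovers, fgr,
                                          ignore.strand = TRUE) > 0)
    b <- sum(GenomicRanges::countOverlaps(cold, fgr,
                                          ignore.strand = TRUE) > 0)
    if (a == 0 && b == 0) return(NULL)
    tab <- matrix(c(a, length(crossovers) - a, b, length(cold) - b), 2)
    ft <- fisher.test(tab)
    data.frame(family = fm, n_crossover = a, n_cold = b,
               odds_ratio = unname(ft$estimate), p = ft$p.value)
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(res)) stopf("no transposon family present in either set")
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  rownames(res) <- NULL
  res
}

## ---- aggregate profiles ---------------------------------------------------

signal_coverage_ <- function(signal, layout = NULL) {
  if (is.null(signal$score)) signal$score <- 1
  sl <- if (!is.null(layout)) as.numeric(layout)[match(
    GenomeInfoDb::seqlevels(signal), names(layout))] else NA
  GenomicRanges::coverage(signal, weight = "score")
}

## Mean per-base signal of [start, end] split into `nb` near-equal bins.
bin_means_ <- function(cov_chr, start, end, nb) {
  edges <- round(seq(start - 1, end, length.out = nb + 1))
  s <- edges[-(nb + 1)] + 1; e <- edges[-1]
  bad <- e < s
  s <- pmax(s, 1); e <- pmin(e, length(cov_chr))
  v <- IRanges::Views(cov_chr, start = pmin(s, length(cov_chr)), end = pmax(e, 1))
  out <- IRanges::viewSums(v) / pmax(e - s + 1, 1)
  out[bad] <- NA_real_
  out
}

#' Aggregate signal profile over anchors (metagene-style)
#'
#' Each anchor's body is split into `body_bins` windows with the signal
#' normalized per nucleotide; flanks up to `flank` bp either side are
#' averaged in fixed `flank_bin`-bp bins.  Minus-strand anchors are
#' flipped so all profiles read 5' to 3'; unstranded anchors are treated
#' as plus.  An optional permutation null (length-matched random anchors,
#' chromosome preserved) yields a mean and 2-SD band per bin.
#'
#' @param anchors Stranded or unstranded `GRanges`.
#' @param signal `GRanges` with a numeric `score` (per-interval signal;
#'   missing score counts each interval once per base).
#' @param body_bins Number of body windows (default 50).
#' @param flank Flank extent in bp (default 5000).
#' @param flank_bin Flank bin width in bp (default 10; use 25 for coarser
#'   profiles).
#' @param n_perm Permutations for the null band (0 disables; 100 in a full
#'   analysis).
#' @param layout Required when `n_perm > 0`.
#' @param seed Optional integer seed.
#' @return List: `profile` (mean per bin), `position` (bin labels:
#'   negative flank, `body_1..body_n`, positive flank), `matrix`
#'   (anchors x bins), `null_mean`, `null_sd` (when permuted),
#'   `n_used`, `n_skipped` (anchors shorter than `body_bins`).
#' @export
aggregate_profile <- function(anchors, signal, body_bins = 50, flank = 5000,
                              flank_bin = 10, n_perm = 0, layout = NULL,
                              seed = NULL) {
  cov <- signal_coverage_(signal)
  nfl <- as.integer(flank / flank_bin)
  profile_one_set <- function(anc) {
    keep <- GenomicRanges::width(anc) >= body_bins
    anc <- anc[keep]
    M <- matrix(NA_real_, length(anc), 2 * nfl + body_bins)
    for (i in seq_along(anc)) {
      ch <- as.character(GenomicRanges::seqnames(anc))[i]
      if (!ch %in% names(cov)) next
      cc <- cov[[ch]]
      s <- GenomicRanges::start(anc)[i]; e <- GenomicRanges::end(anc)[i]
      up <- bin_means_(cc, s - flank, s - 1, nfl)
      body <- bin_means_(cc, s, e, body_bins)
      dn <- bin_means_(cc, e + 1, e + flank, nfl)
      row <- c(up, body, dn)
      if (as.character(GenomicRanges::strand(anc))[i] == "-") row <- rev(row)
      M[i, ] <- row
    }
    M
  }
  M <- profile_one_set(anchors)
  n_skipped <- length(anchors) - nrow(M)
  if (n_skipped > 0)
    xo_log(n_skipped, " anchor(s) shorter than body_bins skipped")
  res <- list(profile = colMeans(M, na.rm = TRUE),
              position = c(-(nfl:1) * flank_bin,
                           paste0("body_", seq_len(body_bins)),
                           (1:nfl) * flank_bin),
              matrix = M, n_used = nrow(M), n_skipped = n_skipped)
  if (n_perm > 0) {
    if (is.null(layout)) stopf("layout is required for the permutation null")
    with_seed(seed, {
      nullp <- matrix(NA_real_, n_perm, ncol(M))
      for (p in seq_len(n_perm)) {
        sh <- shuffle_intervals_(anchors, layout)
        nullp[p, ] <- colMeans(profile_one_set(sh), na.rm = TRUE)
      }
      res$null_mean <- colMeans(nullp)
      res$null_sd <- apply(nullp, 2, sd)
    })
  }
  res
}

## ---- signal Monte-Carlo ---------------------------------------------------

region_mean_signal_ <- function(gr, cov) {
  out <- numeric(length(gr))
  chr <- as.character(GenomicRanges::seqnames(gr))
  for (i in seq_along(gr)) {
    if (!chr[i] %in% names(cov)) { out[i] <- NA_real_; next }
    cc <- cov[[chr[i]]]
    s <- max(1, GenomicRanges::start(gr)[i])
    e <- min(length(cc), GenomicRanges::end(gr)[i])
    if (e < s) { out[i] <- NA_real_; next }
    out[i] <- sum(IRanges::viewSums(IRanges::Views(cc, s, e))) / (e - s + 1)
  }
  out
}

#' Monte-Carlo test of mean signal over queries vs nearby matched regions
#'
#' The observed statistic is the mean (over queries) of the per-base mean
#' signal.  Each permutation displaces every query by a random offset
#' drawn uniformly from the distance `band` (random side, reflected when
#' it would leave the chromosome), length preserved, and recomputes the
#' statistic; add-one empirical p-values are reported for enrichment and
#' depletion.
#'
#' @param queries `GRanges` of intervals.
#' @param signal `GRanges` signal track with `score`.
#' @param layout A [genome_layout()].
#' @param band Distance band in bp (default `c(1e4, 1e6)`).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List: `observed`, `null` (vector), `p_enrich`, `p_deplete`.
#' @export
signal_mc <- function(queries, signal, layout, band = c(1e4, 1e6),
                      n_perm = 10000, seed = NULL) {
  if (n_perm <= 0) stopf("n_perm must be positive")
  cov <- signal_coverage_(signal)
  chr <- as.character(GenomicRanges::seqnames(queries))
  len <- as.numeric(layout[chr])
  w <- GenomicRanges::width(queries)
  if (any(len - w < 2 * band[1]))
    stopf("distance band is empty for at least one query")
  obs <- mean(region_mean_signal_(queries, cov), na.rm = TRUE)
  with_seed(seed, {
    null <- numeric(n_perm)
    st0 <- GenomicRanges::start(queries)
    for (p in seq_len(n_perm)) {
      off <- floor(runif(length(w), band[1], band[2] + 1)) *
        sample(c(-1, 1), length(w), replace = TRUE)
      s <- st0 + off
      flip <- s < 1 | (s + w - 1) > len
      s[flip] <- st0[flip] - off[flip]
      s <- pmin(pmax(s, 1), len - w + 1)
      sh <- GenomicRanges::GRanges(chr, IRanges::IRanges(s, width = w))
      null[p] <- mean(region_mean_signal_(sh, cov), na.rm = TRUE)
    }
    list(observed = obs, null = null,
         p_enrich = empirical_p(obs, null, "greater"),
         p_deplete = empirical_p(obs, null, "less"))
  })
}

## ---- binned correlations --------------------------------------------------

#' Bin signal tracks and compute rank correlations
#'
#' Sums (or averages) each track in fixed windows and computes Spearman
#' correlations (ties mid-ranked) genome-wide and per chromosome, with
#' p-values from [stats::cor.test()].
#'
#' @param tracks Named list of `GRanges` with `score` columns, or a
#'   numeric matrix of pre-binned values (columns = tracks; then `layout`
#'   is ignored and `bins` must be supplied or per-chromosome output is
#'   skipped).
#' @param layout A [genome_layout()].
#' @param binsize Window width in bp (1e5 or 1e6 typical).
#' @param summary Per-track summary: `"sum"` (read-count-like, default) or
#'   `"mean"` (per-base level, e.g. methylation); recycled.
#' @param min_bins Minimum bins required (default 10).
#' @return List: `values` (bins x tracks matrix), `bins` (`GRanges`),
#'   `rho` and `p` (genome-wide matrices), `per_chrom` (named list of rho
#'   matrices).  Constant tracks give `NA` correlations with a warning.
#' @export
binned_stats <- function(tracks, layout, binsize = 1e5, summary = "sum",
                         min_bins = 10) {
  if (is.matrix(tracks)) {
    V <- tracks
    bins <- NULL
    chroms <- NULL
  } else {
    bins <- layout_bins(layout, binsize)
    summary <- rep(summary, length.out = length(tracks))
    V <- sapply(seq_along(tracks), function(j) {
      cov <- signal_coverage_(tracks[[j]])
      v <- numeric(length(bins))
      chr <- as.character(GenomicRanges::seqnames(bins))
      for (i in seq_along(bins)) {
        if (!chr[i] %in% names(cov)) next
        cc <- cov[[chr[i]]]
        s <- GenomicRanges::start(bins)[i]
        e <- min(GenomicRanges::end(bins)[i], length(cc))
        if (e < s) next
        tot <- sum(IRanges::viewSums(IRanges::Views(cc, s, e)))
        v[i] <- if (summary[j] == "mean") tot / (e - s + 1) else tot
      }
      v
    })
    colnames(V) <- names(tracks) %||% paste0("track", seq_along(tracks))
    chroms <- as.character(GenomicRanges::seqnames(bins))
  }
  if (nrow(V) < min_bins) stopf("need at least %d bins", min_bins)
  const <- apply(V, 2, function(x) length(unique(x[!is.na(x)])) <= 1)
  if (any(const))
    warnf("constant track(s): %s; correlations are NA",
          paste(colnames(V)[const], collapse = ", "))
  nt <- ncol(V)
  rho <- matrix(NA_real_, nt, nt, dimnames = list(colnames(V), colnames(V)))
  pm <- rho
  for (a in seq_len(nt)) for (b in seq_len(nt)) {
    if (const[a] || const[b]) next
    ct <- suppressWarnings(stats::cor.test(V[, a], V[, b],
                                           method = "spearman", exact = FALSE))
    rho[a, b] <- unname(ct$estimate)
    pm[a, b] <- ct$p.value
  }
  per_chrom <- NULL
  if (!is.null(chroms)) {
    per_chrom <- lapply(split(seq_len(nrow(V)), chroms), function(ix) {
      if (length(ix) < 3) return(NULL)
      suppressWarnings(cor(V[ix, , drop = FALSE], method = "spearman",
                           use = "pairwise.complete.obs"))
    })
  }
  list(values = V, bins = bins, rho = rho, p = pm, per_chrom = per_chrom)
}

#' Normalize per-window SNV counts by read coverage
#'
#' Per window: count times the fraction of bases covered by reads, divided
#' by the total reads in the window (windows with no reads give 0).
#'
#' @param counts Per-window SNV counts.
#' @param covered_fraction Fraction of bases covered by reads per window.
#' @param total_reads Total reads per window.
#' @return Normalized density vector.
#' @export
normalize_snv_track <- function(counts, covered_fraction, total_reads) {
  out <- counts * covered_fraction / total_reads
  out[!is.finite(out)] <- 0
  out
}

## ---- crossover count models -----------------------------------------------

#' Poisson goodness-of-fit for per-individual crossover counts
#'
#' Fits a Poisson by the mean crossover count, forms expected category
#' probabilities for 0, 1, 2 and >= 3 crossovers (tail pooled), and tests
#' the observed category counts by a multinomial chi-square.
#'
#' @param counts Integer vector of crossover counts (one chromosome) or a
#'   matrix individuals x chromosomes (each column tested separately).
#' @return For a vector: list `lambda`, `table` (category, observed,
#'   expected), `p_value`; for a matrix, a named list of such results.
#' @export
poisson_fit_counts <- function(counts) {
  if (is.matrix(counts))
    return(lapply(setNames(seq_len(ncol(counts)),
                           colnames(counts) %||% paste0("chrom", seq_len(ncol(counts)))),
                  function(j) poisson_fit_counts(counts[, j])))
  if (any(counts < 0)) stopf("counts must be non-negative")
  n <- length(counts)
  if (n < 20) warnf("only %d individuals; goodness-of-fit test has low validity", n)
  lambda <- mean(counts)
  probs <- c(dpois(0:2, lambda), 1 - sum(dpois(0:2, lambda)))
  probs <- pmax(probs, 0)
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
           sum(counts >= 3))
  tab <- data.frame(category = c("0", "1", "2", ">=3"), observed = obs,
                    expected = n * probs)
  p <- if (lambda == 0) {
    if (all(counts == 0)) 1 else 0
  } else {
    suppressWarnings(chisq.test(obs, p = probs)$p.value)
  }
  list(lambda = lambda, table = tab, p_value = p)
}

#' Crossover counts per individual per chromosome
#' @param co A crossover data.frame (see [call_crossovers()]).
#' @param individuals,chroms Character vectors fixing the full margins
#'   (individuals or chromosomes without crossovers count 0).
#' @return Integer matrix individuals x chromosomes.
#' @export
count_crossovers <- function(co, individuals, chroms) {
  M <- table(factor(co$individual, levels = individuals),
             factor(co$chrom, levels = chroms))
  matrix(as.integer(M), nrow = length(individuals),
         dimnames = list(individuals, chroms))
}

#' Generalized linear model of windowed crossover counts
#'
#' Fits a log-link Poisson GLM (quasi-Poisson optional for overdispersion)
#' of per-window crossover counts on genomic/chromatin covariates and
#' reports the sequential (type I) analysis-of-deviance table.
#' Rank-deficient covariates are dropped with a warning.
#'
#' @param data data.frame: one row per window, a response column plus
#'   covariates.
#' @param response Name of the count column (default `"crossovers"`).
#' @param covariates Covariate column names (default all other columns).
#' @param family `"poisson"` (default) or `"quasipoisson"`.
#' @return List: `model` (the `glm` fit), `anova` (sequential deviance
#'   table with p-values), `dispersion` (residual deviance / df).
#' @export
glm_crossovers <- function(data, response = "crossovers", covariates = NULL,
                           family = c("poisson", "quasipoisson")) {
  family <- match.arg(family)
  covariates <- covariates %||% setdiff(names(data), response)
  data <- data[stats::complete.cases(data[c(response, covariates)]), ,
               drop = FALSE]
  if (length(covariates)) {
    X <- model.matrix(~ ., data[, covariates, drop = FALSE])
    q <- qr(X)
    if (q$rank < ncol(X)) {
      aliased <- colnames(X)[q$pivot[-seq_len(q$rank)]]
      bad <- covariates[vapply(covariates, function(v)
        any(startsWith(aliased, v)), TRUE)]
      if (length(bad)) {
        warnf("dropping rank-deficient covariate(s): %s",
              paste(bad, collapse = ", "))
        covariates <- setdiff(covariates, bad)
      }
    }
  }
  fml <- as.formula(paste(response, "~",
                          if (length(covariates))
                            paste(covariates, collapse = " + ") else "1"))
  fit <- glm(fml, data = data, family = family)
  an <- anova(fit, test = if (family == "poisson") "Chisq" else "F")
  disp <- fit$deviance / fit$df.residual
  if (family == "poisson" && is.finite(disp) && disp > 2)
    xo_log(sprintf("overdispersion check: deviance/df = %.2f; consider quasipoisson",
                   disp))
  list(model = fit, anova = an, dispersion = disp)
}

## ---- promoter / Stowaway quartile analyses --------------------------------

#' Promoter recombination-rate and Stowaway quartile analyses
#'
#' Two complementary tests of whether Stowaway-class elements in promoters
#' track recombination rate: (a) promoters overlapping windows in the top
#' versus bottom recombination-rate quartile are compared for their
#' Stowaway counts by a Wilcoxon rank-sum test; (b) promoters carrying at
#' least one element are compared, for their mean overlying window-scaled
#' rate, against a Monte-Carlo null of equally many nearby (within
#' `match_dist`) element-free promoters.
#'
#' @param promoters `GRanges` of promoters.
#' @param stowaways `GRanges` of Stowaway elements.
#' @param track A [interpolate_rate()] result (or `GRanges` with `score`
#'   in cM/Mb).
#' @param n_perm Permutations for (b); scaled down from the 1e6 of a full
#'   analysis as needed.
#' @param match_dist Maximum distance pairing element-free promoters to
#'   element-bearing ones (default 5e5).
#' @param seed Optional integer seed.
#' @return List: `wilcox_p`, `counts_top`, `counts_bottom` (per-promoter
#'   element counts by quartile group), `mc_p`, `observed_rate`,
#'   `null_rates`, `n_with`, `n_without_pool`.  When either promoter group
#'   of (b) is empty the Monte-Carlo fields are `NA` with a warning.
#' @export
promoter_quartile_analysis <- function(promoters, stowaways, track,
                                       n_perm = 1000, match_dist = 5e5,
                                       seed = NULL) {
  tgr <- if (methods::is(track, "GRanges")) track else track_granges(track)
  q <- quantile(tgr$score, c(0.25, 0.75), na.rm = TRUE)
  top <- tgr[tgr$score >= q[2]]
  bottom <- tgr[tgr$score <= q[1]]
  in_top <- GenomicRanges::countOverlaps(promoters, top,
                                         ignore.strand = TRUE) > 0
  in_bottom <- !in_top & GenomicRanges::countOverlaps(promoters, bottom,
                                                      ignore.strand = TRUE) > 0
  if (!any(in_top) || !any(in_bottom))
    stopf("a recombination-rate quartile group is empty")
  cnt <- GenomicRanges::countOverlaps(promoters, stowaways,
                                      ignore.strand = TRUE)
  wt <- suppressWarnings(wilcox.test(cnt[in_top], cnt[in_bottom]))
  ## (b) rate of element-bearing vs matched element-free promoters
  with_g <- promoters[cnt > 0]
  without <- promoters[cnt == 0]
  near <- GenomicRanges::countOverlaps(
    without,
    GenomicRanges::resize(with_g, GenomicRanges::width(with_g) + 2 * match_dist,
                          fix = "center"),
    ignore.strand = TRUE) > 0
  pool <- without[near]
  if (length(with_g) == 0 || length(pool) == 0) {
    warnf("empty promoter group; skipping the Monte-Carlo comparison")
    return(list(wilcox_p = wt$p.value,
                counts_top = cnt[in_top], counts_bottom = cnt[in_bottom],
                mc_p = NA_real_, observed_rate = NA_real_,
                null_rates = numeric(0),
                n_with = length(with_g), n_without_pool = length(pool)))
  }
  prom_rate <- function(gr) mean(region_mean_signal_(
    gr, signal_coverage_(tgr)), na.rm = TRUE)
  obs <- prom_rate(with_g)
  with_seed(seed, {
    null <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      take <- sample.int(length(pool), min(length(with_g), length(pool)),
                         replace = length(pool) < length(with_g))
      null[p] <- prom_rate(pool[take])
    }
    list(wilcox_p = wt$p.value,
         counts_top = cnt[in_top], counts_bottom = cnt[in_bottom],
         mc_p = empirical_p(obs, null, "greater"),
         observed_rate = obs, null_rates = null,
         n_with = length(with_g), n_without_pool = length(pool))
  })
}
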