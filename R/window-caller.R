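## Binomial/Bayes haplotype window calling.  Within a window of n
## non-missing haplotype labels, the count k of labels discordant with
## haplotype 1 is binomial with the genotyping error rate E_T if the window
## truly derives from haplotype 1, and the count of labels discordant with
## haplotype 2 (n - k) is binomial with E_T under the alternative.  With a
## flat 0.5/0.5 prior the posterior decides the window call.

#' Binomial likelihood of k discordant labels
#'
#' Computes `choose(n, k) * E_T^k * (1 - E_T)^(n - k)` in log space for
#' numerical stability.
#'
#' @param n Number of non-missing labels in the window (>= 0).
#' @param k Number of discordant labels (0 <= k <= n).
#' @param E_T Genotyping error rate in `[0, 1]`.
#' @param log Return the log-likelihood?
#' @return Numeric (vectorized over `n`, `k`).
#' @export
binom_likelihood <- function(n, k, E_T, log = FALSE) {
  if (any(E_T < 0 | E_T > 1)) stopf("E_T must be in [0, 1]")
  if (any(k < 0) || any(k > n)) stopf("k must satisfy 0 <= k <= n")
  lterm <- function(cnt, p) ifelse(cnt == 0, 0, cnt * base::log(p))
  ll <- lchoose(n, k) + lterm(k, E_T) + lterm(n - k, 1 - E_T)
  if (log) ll else exp(ll)
}

#' Posterior probability of each parental haplotype for a window
#'
#' Bayes' theorem over the two hypotheses: `p1` is proportional to
#' `binom_likelihood(n, k, E_T) * prior` and `p2` to
#' `binom_likelihood(n, n - k, E_T) * (1 - prior)` (k discordances with
#' haplotype 1 are `n - k` discordances with haplotype 2).  With symmetric
#' evidence (`k = n/2`) the posterior equals the prior.
#'
#' @inheritParams binom_likelihood
#' @param prior Prior probability of haplotype 1 (default 0.5).
#' @return List with numeric vectors `p1` and `p2` (`p1 + p2 = 1`).
#' @export
hap_posterior <- function(n, k, E_T, prior = 0.5) {
  if (prior <= 0 || prior >= 1) stopf("prior must be in (0, 1)")
  l1 <- binom_likelihood(n, k, E_T, log = TRUE)
  l2 <- binom_likelihood(n, n - k, E_T, log = TRUE)
  p1 <- plogis((l1 - l2) + base::log(prior / (1 - prior)))
  both0 <- is.infinite(l1) & is.infinite(l2) & l1 < 0 & l2 < 0
  if (any(both0)) {
    warnf("zero likelihood under both haplotypes; returning the prior")
    p1[both0] <- 0.5
  }
  list(p1 = p1, p2 = 1 - p1)
}

#' Call haplotype windows across a chromosome
#'
#' Slides a `window`-SNV window in steps of `step` SNVs over the haplotype
#' label matrix.  Per individual and window, `n` counts non-missing labels
#' and `k` labels equal to haplotype 2; the call is the haplotype with the
#' larger posterior (`P_max`).  Windows with fewer than `min_calls`
#' non-missing labels, or with exactly tied posteriors, are missing.
#'
#' @param labels A [genotype_to_haplotype()] result.
#' @param window Window size in SNVs (default 50).
#' @param step Shift in SNVs (default 5).
#' @param min_calls Minimum non-missing labels per window (default 5).
#' @param E_T Genotyping error rate (an `error_rate` object or a number);
#'   a zero estimate is floored at 1e-6 so mixed windows stay decidable.
#' @param prior Prior probability of haplotype 1.
#' @return Object of class `window_calls`: `windows` data.frame (`chrom`,
#'   `first_idx`, `last_idx` global site-column indices, `first_pos`,
#'   `last_pos`, `mid_pos`), matrices `call` (0/1/NA), `p_max`, `n`, `k`
#'   (individuals x windows), plus `E_T` and `individuals`.
#' @export
call_windows <- function(labels, window = 50, step = 5, min_calls = 5, E_T,
                         prior = 0.5) {
  stopifnot(inherits(labels, "hap_labels"))
  if (inherits(E_T, "error_rate")) E_T <- E_T$E_T
  if (E_T <= 0) {
    ## observing no hom-alt calls does not make errors impossible; a zero
    ## rate would leave mixed windows undecidable
    xo_log("estimated E_T is 0; floored at 1e-6")
    E_T <- 1e-6
  }
  if (min_calls < 1) stopf("min_calls must be >= 1")
  L <- labels$labels
  chroms <- labels$sites$chrom
  pos <- labels$sites$pos
  win_list <- list(); Ns <- list(); Ks <- list()
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    nsnv <- length(idx)
    if (nsnv < window) {
      xo_log("chromosome ", ch, " shorter than one window (", nsnv,
             " SNVs); using a single truncated window")
      starts <- 1L
      w <- nsnv
    } else {
      starts <- seq.int(1L, nsnv - window + 1L, by = step)
      w <- window
    }
    ends <- pmin(starts + w - 1L, nsnv)
    Lc <- L[, idx, drop = FALSE]
    notna <- !is.na(Lc)
    isk <- !is.na(Lc) & Lc == 1L
    cn <- cbind(0, t(apply(notna, 1, cumsum)))
    ck <- cbind(0, t(apply(isk, 1, cumsum)))
    nmat <- cn[, ends + 1L, drop = FALSE] - cn[, starts, drop = FALSE]
    kmat <- ck[, ends + 1L, drop = FALSE] - ck[, starts, drop = FALSE]
    win_list[[ch]] <- data.frame(
      chrom = ch,
      first_idx = idx[starts], last_idx = idx[ends],
      first_pos = pos[idx[starts]], last_pos = pos[idx[ends]],
      mid_pos = (pos[idx[starts]] + pos[idx[ends]]) / 2)
    Ns[[ch]] <- nmat; Ks[[ch]] <- kmat
  }
  windows <- do.call(rbind, win_list); rownames(windows) <- NULL
  N <- do.call(cbind, Ns); K <- do.call(cbind, Ks)
  post <- hap_posterior(as.vector(N), as.vector(K), E_T, prior)
  P1 <- matrix(post$p1, nrow(N), ncol(N))
  call <- matrix(NA_integer_, nrow(N), ncol(N))
  call[P1 > 0.5] <- 0L
  call[P1 < 0.5] <- 1L
  call[N < min_calls] <- NA_integer_
  pmaxm <- pmax(P1, 1 - P1)
  pmaxm[is.na(call)] <- NA_real_
  dimnames(call) <- list(labels$individuals, NULL)
  structure(list(windows = windows, call = call, p_max = pmaxm,
                 n = N, k = K, E_T = E_T, individuals = labels$individuals),
            class = "window_calls")
}

#' @export
print.window_calls <- function(x, ...) {
  cat(sprintf("window_calls: %d windows x %d individuals (E_T = %.4g, %.1f%% missing)\n",
              nrow(x$windows), nrow(x$call), x$E_T,
              100 * mean(is.na(x$call))))
  invisible(x)
}

## Bridge missing window calls per individual by carrying the last
## confident call forward (and the first confident call backward over a
## leading gap), so that low-coverage gaps do not fragment skeleton bins.
bridge_calls_ <- function(C) {
  B <- C
  bridged <- matrix(FALSE, nrow(C), ncol(C))
  for (i in seq_len(nrow(C))) {
    v <- C[i, ]
    if (all(is.na(v)) || !anyNA(v)) next
    f <- zoo::na.locf(v, na.rm = FALSE)
    f <- zoo::na.locf(f, fromLast = TRUE, na.rm = FALSE)
    bridged[i, ] <- is.na(v) & !is.na(f)
    B[i, ] <- f
  }
  list(call = B, bridged = bridged)
}

#' Merge identically segregating windows into skeleton bins
#'
#' Adjacent windows whose cross-individual call vectors are identical are
#' merged into maximal runs ("skeleton bins"), the uniquely segregating
#' units between which crossovers are sought.  Missing window calls are
#' bridged per individual by carrying the nearest confident call (flagged
#' in the output), so sequencing gaps do not split bins.
#'
#' @param wc A [call_windows()] result.
#' @return Object of class `skeleton_bins`: `bins` data.frame (`chrom`,
#'   `bin`, `win_first`, `win_last`, `first_idx`, `last_idx`, `first_pos`,
#'   `last_pos`, `n_windows`), `pattern` (individuals x bins call matrix),
#'   `bridged` (fraction of bridged calls per bin), `individuals`.
#' @export
build_skeleton <- function(wc) {
  stopifnot(inherits(wc, "window_calls"))
  bins <- list(); pats <- list(); brid <- list()
  bin_id <- 0L
  for (ch in unique(wc$windows$chrom)) {
    wi <- which(wc$windows$chrom == ch)
    br <- bridge_calls_(wc$call[, wi, drop = FALSE])
    C <- br$call
    key <- apply(C, 2, function(col) paste(ifelse(is.na(col), "N", col),
                                           collapse = ""))
    r <- rle(key)
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (b in seq_along(starts)) {
      bin_id <- bin_id + 1L
      wfirst <- wi[starts[b]]; wlast <- wi[stops[b]]
      bins[[bin_id]] <- data.frame(
        chrom = ch, bin = bin_id,
        win_first = wfirst, win_last = wlast,
        first_idx = wc$windows$first_idx[wfirst],
        last_idx = wc$windows$last_idx[wlast],
        first_pos = wc$windows$first_pos[wfirst],
        last_pos = wc$windows$last_pos[wlast],
        n_windows = stops[b] - starts[b] + 1L)
      pats[[bin_id]] <- C[, starts[b]]
      brid[[bin_id]] <- mean(br$bridged[, starts[b]:stops[b]])
    }
  }
  structure(list(bins = do.call(rbind, bins),
                 pattern = do.call(cbind, pats),
                 bridged = unlist(brid),
                 individuals = wc$individuals),
            class = "skeleton_bins")
}

#' @export
print.skeleton_bins <- function(x, ...) {
  cat(sprintf("skeleton_bins: %d bins on %d chromosome(s)\n",
              nrow(x$bins), length(unique(x$bins$chrom))))
  invisible(x)
}

#' Export skeleton bins as BED or TSV
#'
#' @param sk A [build_skeleton()] result.
#' @param path Output path (BED uses 0-based half-open spans).
#' @return Invisibly, the path.
#' @export
write_skeleton_bed <- function(sk, path) {
  gr <- GenomicRanges::GRanges(sk$bins$chrom,
                               IRanges::IRanges(sk$bins$first_pos,
                                                sk$bins$last_pos))
  gr$name <- paste0("bin", sk$bins$bin)
  gr$score <- sk$bins$n_windows
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_skeleton_bed
#' @export
write_skeleton_tsv <- function(sk, path) {
  out <- cbind(sk$bins, as.data.frame(t(sk$pattern)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
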