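## Genetic map from haplotype window markers, Marey map (cM vs bp) and
## cubic-spline interpolation of recombination rate onto fixed windows.

#' Map functions
#'
#' Convert a recombination fraction `r` to a map distance in centimorgans.
#' Haldane assumes no interference (consistent with a Poisson crossover
#' model); Kosambi allows moderate positive interference.
#'
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Map distance in cM.
#' @export
haldane_cM <- function(r) -50 * log(1 - 2 * r)

#' @rdname haldane_cM
#' @export
kosambi_cM <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' Build a Marey map from haplotype window calls
#'
#' Each called window is a genetic marker at its physical midpoint.  The
#' recombination fraction between adjacent markers is the fraction of
#' individuals whose calls differ among those informative (non-missing) at
#' both; map increments accumulate from 0 per chromosome through the
#' chosen map function.  Missing window calls carry each individual's
#' nearest confident call (as in skeleton construction), so a haplotype
#' switch across a low-coverage gap still contributes its map distance at
#' the junction where the call changes.  Marker ordering follows physical
#' position (assembly order is taken as correct).
#'
#' @param wc A [call_windows()] result.
#' @param map_fun `"haldane"` (default) or `"kosambi"`.
#' @return Object of class `marey_map`: data.frame `chrom`, `pos` (marker
#'   midpoint, bp), `cM`, `r` (fraction to the previous marker),
#'   `n_informative`.  Marker pairs with no informative individual get a
#'   0 increment and are flagged in attribute `n_uninformative`.
#' @export
genetic_positions <- function(wc, map_fun = c("haldane", "kosambi")) {
  stopifnot(inherits(wc, "window_calls"))
  map_fun <- match.arg(map_fun)
  fn <- if (map_fun == "haldane") haldane_cM else kosambi_cM
  out <- list(); n_unin <- 0L; n_capped <- 0L
  for (ch in unique(wc$windows$chrom)) {
    wi <- which(wc$windows$chrom == ch)
    C <- bridge_calls_(wc$call[, wi, drop = FALSE])$call
    nw <- length(wi)
    r <- numeric(nw); ninf <- integer(nw)
    if (nw > 1) {
      for (b in 2:nw) {
        both <- !is.na(C[, b - 1L]) & !is.na(C[, b])
        ninf[b] <- sum(both)
        if (ninf[b] == 0L) { n_unin <- n_unin + 1L; r[b] <- 0; next }
        r[b] <- sum(C[both, b - 1L] != C[both, b]) / ninf[b]
        if (r[b] >= 0.5) { r[b] <- 0.4999; n_capped <- n_capped + 1L }
      }
    }
    out[[ch]] <- data.frame(chrom = ch, pos = wc$windows$mid_pos[wi],
                            cM = cumsum(fn(r)), r = r, n_informative = ninf)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  if (n_unin > 0)
    xo_log(n_unin, " marker interval(s) had no informative individuals (0 cM)")
  if (n_capped > 0)
    xo_log(n_capped, " recombination fraction(s) >= 0.5 capped at 0.4999")
  attr(res, "map_fun") <- map_fun
  attr(res, "n_uninformative") <- n_unin
  class(res) <- c("marey_map", class(res))
  res
}

#' Total genetic map length per chromosome
#' @param marey A [genetic_positions()] result.
#' @return Named numeric vector of chromosome map lengths (cM).
#' @export
map_length <- function(marey) {
  vapply(split(marey$cM, marey$chrom), max, numeric(1))
}

#' Interpolate recombination rate onto fixed windows
#'
#' Fits a cubic smoothing spline of genetic position (cM) against physical
#' position (bp) per chromosome and differentiates it over a fixed window
#' grid: the rate of a window is its cM increment divided by its width in
#' Mb.  The fitted curve is clamped to the observed cM range and
#' monotonized (running maximum) before differencing, so negative
#' increments from spline wiggles are clipped to zero (and counted) while
#' the windowed rates still integrate to the chromosome map length;
#' chromosomes with fewer than 4 markers fall back to piecewise linear
#' interpolation.
#'
#' @param marey A [genetic_positions()] result.
#' @param binsize Window width in bp (default 1e5).
#' @param spar Smoothing parameter passed to [stats::smooth.spline()];
#'   `NULL` (default) selects it by generalized cross-validation.
#' @return data.frame of class `recomb_track`: `chrom`, `start`, `end`
#'   (1-based closed), `rate` (cM/Mb); attribute `n_clipped` counts
#'   clipped windows.
#' @export
interpolate_rate <- function(marey, binsize = 1e5, spar = NULL) {
  stopifnot(inherits(marey, "marey_map"))
  out <- list(); clipped <- 0L
  for (ch in unique(marey$chrom)) {
    d <- marey[marey$chrom == ch, ]
    d <- d[!duplicated(d$pos), ]
    if (nrow(d) < 2) next
    if (nrow(d) >= 4) {
      fit <- smooth.spline(d$pos, d$cM, spar = spar)
      f <- function(z) predict(fit, z)$y
    } else {
      xo_log("chromosome ", ch, " has < 4 markers; linear interpolation")
      f <- approxfun(d$pos, d$cM, rule = 2)
    }
    lo <- floor(min(d$pos) / binsize) * binsize
    hi <- ceiling(max(d$pos) / binsize) * binsize
    edges <- seq(lo, hi, by = binsize)
    cm <- pmin(pmax(f(edges), 0), max(d$cM))
    clipped <- clipped + sum(diff(cm) < 0)
    cm <- cummax(cm)
    rate <- diff(cm) / (binsize / 1e6)
    out[[ch]] <- data.frame(chrom = ch, start = head(edges, -1) + 1,
                            end = tail(edges, -1), rate = rate)
  }
  res <- do.call(rbind, out); rownames(res) <- NULL
  if (clipped > 0)
    xo_log(clipped, " window(s) with negative spline increment clipped to 0")
  attr(res, "n_clipped") <- clipped
  class(res) <- c("recomb_track", class(res))
  res
}

#' Recombination track as a GRanges
#' @param track A [interpolate_rate()] result.
#' @return `GRanges` with a `score` column in cM/Mb.
#' @export
track_granges <- function(track) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start, track$end))
  gr$score <- track$rate
  gr
}

#' Export a Marey map / recombination track
#'
#' @param marey A [genetic_positions()] result.
#' @param path Output path (TSV for the Marey map, bedGraph for the track).
#' @return Invisibly, the path.
#' @export
write_marey_tsv <- function(marey, path) {
  write.table(as.data.frame(marey), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_marey_tsv
#' @param track A [interpolate_rate()] result.
#' @export
write_track_bedgraph <- function(track, path) {
  write_signal_bedgraph(track_granges(track), path)
  invisible(path)
}
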