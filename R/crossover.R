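## Crossover detection: haplotype transitions between adjacent skeleton
## bins, localized to a minimal SNV interval by ridge-penalized logistic
## regression of the binary haplotype label on physical position.

#' Find candidate haplotype transitions per individual
#'
#' Each adjacent skeleton-bin pair whose call differs for an individual is
#' a candidate crossover.  Candidates whose flanking bins are physically
#' disjoint and non-adjacent in SNV index space (possible on assemblies
#' with misplaced scaffolds) are discarded and counted.
#'
#' @param sk A [build_skeleton()] result.
#' @return data.frame with `individual`, `chrom`, `left_bin`, `right_bin`
#'   (row indices into `sk$bins`); attribute `n_discarded` counts
#'   non-overlapping flank pairs that were dropped.
#' @export
find_transitions <- function(sk) {
  stopifnot(inherits(sk, "skeleton_bins"))
  out <- list(); dropped <- 0L
  for (ch in unique(sk$bins$chrom)) {
    bi <- which(sk$bins$chrom == ch)
    if (length(bi) < 2) next
    P <- sk$pattern[, bi, drop = FALSE]
    for (b in seq_len(length(bi) - 1L)) {
      lb <- bi[b]; rb <- bi[b + 1L]
      adjacent <- sk$bins$first_idx[rb] <= sk$bins$last_idx[lb] + 1L
      switched <- which(!is.na(P[, b]) & !is.na(P[, b + 1L]) &
                          P[, b] != P[, b + 1L])
      if (!length(switched)) next
      if (!adjacent) {
        dropped <- dropped + length(switched)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        individual = sk$individuals[switched],
        chrom = ch, left_bin = lb, right_bin = rb)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual = character(0), chrom = character(0),
               left_bin = integer(0), right_bin = integer(0))
  rownames(res) <- NULL
  if (dropped > 0)
    xo_log(dropped, " transition(s) with non-overlapping flanking bins discarded")
  attr(res, "n_discarded") <- dropped
  res
}

## Logistic regression with a small L2 penalty on the slope (intercept
## unpenalized), by Newton iteration.  The penalty keeps the MLE finite
## under perfect separation (the typical clean-step case) while leaving
## fitted probabilities essentially 0/1 away from the breakpoint.
ridge_logistic_ <- function(x, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  mu0 <- min(max(mean(y), 0.05), 0.95)
  b <- c(qlogis(mu0), 0)
  X <- cbind(1, x)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    grad <- drop(crossprod(X, mu - y)) + c(0, lambda * b[2])
    H <- crossprod(X, w * X) + diag(c(0, lambda))
    step <- solve(H, grad)
    b <- b - step
    if (max(abs(step)) < tol) break
  }
  b
}

#' Localize one crossover to a minimal SNV interval
#'
#' Fits a logistic model of the binary haplotype label on SNV position
#' (centered and scaled internally by the median marker gap, so the
#' attainable step steepness is independent of marker density; a 1e-4 L2
#' penalty on the slope keeps the fit finite under perfect separation,
#' where a clean switch across a typical gap attains a crossover
#' probability of about 0.96 over its flanking pair).  The probability of a
#' crossover between two SNVs is the absolute difference of their fitted
#' probabilities.  The interval is seeded at the adjacent pair with the
#' largest crossover probability and grown one SNV at a time, extending to
#' whichever side most increases the endpoint-pair probability, until it
#' exceeds `threshold`.
#'
#' @param x Numeric SNV positions (bp), increasing.
#' @param y Binary haplotype labels (0/1) at `x`; `NA`s are dropped.
#' @param threshold Crossover probability to attain (default 0.95).
#' @param ridge L2 penalty on the slope (default 1e-4).
#' @return List: `left`, `right` (bounding SNV positions), `prob`
#'   (attained crossover probability), `low_confidence` (`TRUE` when all
#'   SNVs were consumed without reaching `threshold`), `coef`.
#' @export
localize_crossover <- function(x, y, threshold = 0.95, ridge = 1e-4) {
  keep <- !is.na(y) & !is.na(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stopf("need >= 2 non-missing labels")
  o <- order(x); x <- x[o]; y <- y[o]
  if (length(unique(y)) < 2)
    stopf("labels contain a single class; no transition to localize")
  scale <- stats::median(diff(x))
  if (scale <= 0) scale <- 1
  xs <- (x - mean(x)) / scale
  b <- ridge_logistic_(xs, y, lambda = ridge)
  p <- plogis(b[1] + b[2] * xs)
  dp <- abs(diff(p))
  s <- which.max(dp)
  L <- s; R <- s + 1L
  prob <- abs(p[R] - p[L])
  while (prob <= threshold && (L > 1L || R < length(x))) {
    gl <- if (L > 1L) abs(p[R] - p[L - 1L]) else -Inf
    gr <- if (R < length(x)) abs(p[R + 1L] - p[L]) else -Inf
    if (gl >= gr) L <- L - 1L else R <- R + 1L
    prob <- abs(p[R] - p[L])
  }
  list(left = x[L], right = x[R], prob = prob,
       low_confidence = prob <= threshold, coef = b)
}

#' Detect and localize all crossovers in a population
#'
#' Runs [find_transitions()] on the skeleton and [localize_crossover()] on
#' every candidate, feeding each fit the individual's per-SNV haplotype
#' labels across the union span of the two flanking bins.
#'
#' @param sk A [build_skeleton()] result.
#' @param labels The [genotype_to_haplotype()] result the skeleton was
#'   built from.
#' @param threshold Crossover probability threshold (default 0.95).
#' @param population Population tag recorded per interval.
#' @return data.frame of class `crossover_set`: `individual`, `chrom`,
#'   `left`, `right` (1-based bounding SNV positions), `prob`,
#'   `resolution` (`right - left`), `low_confidence`, `population`.
#'   Candidates whose label span held a single class are skipped and
#'   counted in attribute `n_skipped`.
#' @export
call_crossovers <- function(sk, labels, threshold = 0.95,
                            population = "pop1") {
  stopifnot(inherits(sk, "skeleton_bins"), inherits(labels, "hap_labels"))
  tr <- find_transitions(sk)
  ind_index <- match(tr$individual, labels$individuals)
  out <- vector("list", nrow(tr)); skipped <- 0L
  for (r in seq_len(nrow(tr))) {
    i1 <- sk$bins$first_idx[tr$left_bin[r]]
    i2 <- sk$bins$last_idx[tr$right_bin[r]]
    span <- i1:i2
    x <- labels$sites$pos[span]
    y <- labels$labels[ind_index[r], span]
    fit <- tryCatch(localize_crossover(x, y, threshold = threshold),
                    error = function(e) NULL)
    if (is.null(fit)) { skipped <- skipped + 1L; next }
    out[[r]] <- data.frame(
      individual = tr$individual[r], chrom = tr$chrom[r],
      left = fit$left, right = fit$right, prob = fit$prob,
      resolution = fit$right - fit$left,
      low_confidence = fit$low_confidence,
      population = population)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(individual = character(0), chrom = character(0),
                      left = numeric(0), right = numeric(0), prob = numeric(0),
                      resolution = numeric(0), low_confidence = logical(0),
                      population = character(0))
  rownames(res) <- NULL
  if (skipped > 0)
    xo_log(skipped, " candidate(s) skipped (single-class label span)")
  attr(res, "n_skipped") <- skipped
  class(res) <- c("crossover_set", class(res))
  res
}

#' Pool crossover sets and keep fine-resolution intervals
#'
#' Concatenates crossover tables (their `population` tags are preserved)
#' and retains intervals whose resolution is strictly below `max_span`.
#' With `max_span = Inf` this simply merges the sets.
#'
#' @param ... Crossover data.frames from [call_crossovers()], or one list
#'   of them.
#' @param max_span Resolution cutoff in bp (default 5000: "fine-scale").
#' @return A pooled crossover data.frame.
#' @export
merge_fine <- function(..., max_span = 5000) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) && !is.data.frame(sets[[1]]))
    sets <- sets[[1]]
  if (!length(sets))
    return(data.frame(individual = character(0), chrom = character(0),
                      left = numeric(0), right = numeric(0),
                      prob = numeric(0), resolution = numeric(0),
                      low_confidence = logical(0), population = character(0)))
  all <- do.call(rbind, lapply(sets, as.data.frame))
  rownames(all) <- NULL
  all[all$resolution < max_span, , drop = FALSE]
}

#' Export crossover intervals
#'
#' BED output is 0-based half-open `(left - 1, right)`; the TSV keeps
#' 1-based bounding SNV coordinates.
#'
#' @param co A crossover data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_crossovers_bed <- function(co, path) {
  gr <- GenomicRanges::GRanges(co$chrom, IRanges::IRanges(co$left, co$right))
  gr$name <- co$individual
  gr$score <- round(1000 * co$prob)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_crossovers_bed
#' @export
write_crossovers_tsv <- function(co, path) {
  write.table(as.data.frame(co), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Crossover intervals as a GRanges
#' @param co A crossover data.frame.
#' @param layout Optional [genome_layout()] for seqinfo.
#' @return A `GRanges` spanning `[left, right]` per crossover.
#' @export
crossovers_granges <- function(co, layout = NULL) {
  gr <- GenomicRanges::GRanges(co$chrom, IRanges::IRanges(co$left, co$right),
                               seqinfo = if (!is.null(layout)) as_seqinfo(layout))
  gr$individual <- co$individual
  gr$population <- co$population
  gr
}
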