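#' Within-array intensity-trend normalization of a two-colour array
#'
#' Removes the intensity-dependent dye bias of a two-colour hybridisation:
#' the log-ratio M = log2(ch1/ch2) is regressed on the mean log-intensity
#' A = (log2 ch1 + log2 ch2)/2 with a locally weighted robust fit (tricube
#' weights, span 0.3, 2 robustness iterations) and the fitted trend is
#' subtracted. Non-positive intensities are floored at `epsilon` (with a
#' message) before taking logs.
#'
#' @param ch1,ch2 numeric vectors of ChIP and input channel intensities.
#' @param span,iterations loess span and number of robustness iterations.
#' @param epsilon additive floor applied to non-positive intensities.
#' @param center if `TRUE` (default) the fitted trend is subtracted; with
#'   `FALSE` the raw log-ratios are returned (floored channels only).
#' @return numeric vector of normalized log2 ratios.
#' @export
normalize_within_array <- function(ch1, ch2, span = 0.3, iterations = 2,
                                   epsilon = 0.5, center = TRUE) {
  if (length(ch1) != length(ch2))
    stop("channel vectors must have equal length", call. = FALSE)
  n_floor <- sum(ch1 <= 0) + sum(ch2 <= 0)
  if (n_floor > 0) {
    message("floored ", n_floor, " non-positive intensities to epsilon = ",
            epsilon)
    ch1 <- pmax(ch1, epsilon)
    ch2 <- pmax(ch2, epsilon)
  }
  m <- log2(ch1) - log2(ch2)
  if (!center) return(m)
  a <- (log2(ch1) + log2(ch2)) / 2
  if (length(m) < 20) {
    warning("fewer than 20 probes: falling back to median-centering")
    return(m - stats::median(m))
  }
  fit <- limma::loessFit(m, a, span = span, iterations = iterations)
  m - fit$fitted
}

#' Quantile normalization across arrays
#'
#' Forces every column of the matrix onto the identical distribution (the
#' per-rank mean across arrays) while preserving within-array ranks; ties
#' receive the average of the tied ranks' target values. Applying it twice
#' equals applying it once.
#'
#' @param mat numeric matrix, probes x arrays (>= 2 columns).
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2)
    stop("quantile normalization needs >= 2 arrays", call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Replicate-averaged, zero-clipped probe scores
#'
#' The probe score is the arithmetic mean of a probe's normalized
#' log2(ChIP/input) ratios over the biological replicates, with negative
#' means assigned zero. On this scale a score of `s` corresponds to
#' `2^s`-fold enrichment of ChIP over total input (score 1 = 2-fold).
#' Missing replicate values are averaged over the available replicates and
#' the affected probes flagged.
#'
#' @param reps numeric matrix of normalized log-ratios, probes x replicates
#'   (a vector is treated as a single replicate).
#' @return numeric vector of probe scores (named by rownames); probes with
#'   any missing replicate are listed in attribute `"flagged"`.
#' @export
compute_probe_scores <- function(reps) {
  if (is.null(dim(reps))) reps <- matrix(reps, ncol = 1)
  if (ncol(reps) < 1) stop("need >= 1 replicate", call. = FALSE)
  nmiss <- rowSums(is.na(reps))
  if (any(nmiss == ncol(reps)))
    stop("some probes are missing in every replicate", call. = FALSE)
  s <- pmax(rowMeans(reps, na.rm = TRUE), 0)
  names(s) <- rownames(reps)
  structure(s, flagged = rownames(reps)[nmiss > 0])
}

#' Fold enrichment implied by a probe or window score
#'
#' @param s numeric scores (log2 scale, clipped at zero).
#' @return `2^s`, the implied ChIP/input fold enrichment.
#' @export
score_to_fold <- function(s) 2^s
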