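#' Undecimated level-1 Haar wavelet frame
#'
#' Decomposes a plane into the four level-1 coefficient planes of a
#' shift-invariant (undecimated) Daubechies-1 wavelet packet frame. The
#' low-pass is the pair average `(x[i] + x[i+1]) / 2` and the high-pass
#' the pair difference `(x[i] - x[i+1]) / 2`, applied separably along both
#' axes with edge replication, so every plane has the shape of the input
#' and `cA1` of a constant image is that constant (DC-preserving
#' convention). `cA1` is the approximation plane used as tissue evidence;
#' `cH1`/`cV1` respond to horizontal/vertical edges and `cD1` to diagonal
#' detail.
#'
#' @param pol Numeric matrix (typically the preprocessed polar frame).
#' @return A list with planes `cA1`, `cH1`, `cV1`, `cD1`, each the same
#'   shape as the input. Polar geometry attributes are carried over.
#' @examples
#' p <- dwpf_level1(matrix(3, 4, 4))
#' range(p$cA1)  # 3 3
#' max(abs(p$cD1))  # 0
#' @export
dwpf_level1 <- function(pol) {
  x <- unclass(.as_gray(as.matrix(pol)))
  nr <- nrow(x); nc <- ncol(x)
  xr <- x[c(seq_len(nr - 1) + 1L, nr), , drop = FALSE]   # shifted down, edge replicated
  Lr <- (x + xr) / 2; Hr <- (x - xr) / 2
  shift_c <- function(m) m[, c(seq_len(nc - 1) + 1L, nc), drop = FALSE]
  planes <- list(
    cA1 = (Lr + shift_c(Lr)) / 2,
    cH1 = (Hr + shift_c(Hr)) / 2,   # high along r: horizontal structure
    cV1 = (Lr - shift_c(Lr)) / 2,   # high along columns: vertical edges
    cD1 = (Hr - shift_c(Hr)) / 2
  )
  lapply(planes, .copy_geom, from = pol)
}

#' Otsu threshold of an intensity sample
#'
#' Builds a 256-bin histogram over the sample's own range and returns the
#' cut that maximizes the between-class variance
#' `sigma2_B(t) = w0 * w1 * (mu0 - mu1)^2`, with ties broken toward the
#' lowest cut. Class means are accumulated from the actual sample values
#' in each bin (not bin centers), and the returned threshold is the
#' midpoint between the largest value of the lower class and the smallest
#' value of the upper class, so classifying with `value > threshold`
#' reproduces the selected histogram partition exactly. A sample whose
#' range is below `1e-6` (of the unit intensity scale) carries no
#' separable evidence and is flagged degenerate.
#'
#' @param values Numeric vector (at least one value; two or more for a
#'   meaningful split).
#' @param n_bins Number of histogram bins (default 256).
#' @return A list with `threshold` (numeric) and `degenerate` (logical).
#' @examples
#' otsu_threshold(c(rep(0, 50), rep(1, 50)))$threshold  # in (0, 1)
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  if (length(values) == 0L) stop("'values' must be non-empty")
  if (anyNA(values) || any(!is.finite(values))) stop("'values' must be finite")
  lo <- min(values); hi <- max(values)
  if (hi - lo < 1e-6)
    return(list(threshold = lo, degenerate = TRUE))
  w <- (hi - lo) / n_bins
  bin <- pmin(as.integer(floor((values - lo) / w)), n_bins - 1L)  # 0-based
  counts <- tabulate(bin + 1L, n_bins)
  sums <- numeric(n_bins)
  agg <- rowsum(values, bin)
  sums[as.integer(rownames(agg)) + 1L] <- agg
  W <- cumsum(counts); S <- cumsum(sums)
  N <- W[n_bins]; Tot <- S[n_bins]
  k <- seq_len(n_bins - 1L)                 # cut after bin k-1 (0-based)
  w0 <- W[k]; w1 <- N - w0
  valid <- w0 > 0 & w1 > 0
  sigma2 <- rep(-Inf, n_bins - 1L)
  mu0 <- S[k][valid] / w0[valid]
  mu1 <- (Tot - S[k][valid]) / w1[valid]
  sigma2[valid] <- (w0[valid] / N) * (w1[valid] / N) * (mu0 - mu1)^2
  kstar <- which.max(sigma2)                # lowest index on ties
  low_max <- max(values[bin < kstar])
  high_min <- min(values[bin >= kstar])
  list(threshold = (low_max + high_min) / 2, degenerate = FALSE)
}

#' Per-A-line Otsu binarization
#'
#' Thresholds every column of the approximation plane independently with
#' [otsu_threshold()]; pixels strictly greater than their column's
#' threshold become foreground (tissue). A column flagged degenerate
#' (essentially constant, e.g. a shadowed A-line with no tissue return
#' and hence no contrast) binarizes to all foreground — a shadowed A-line
#' must not split the tissue band in two, and the resulting full column
#' shows up as an abrupt drop of the boundary height signal that the
#' shadow-gap machinery detects and repairs later. If *every* column is
#' degenerate the frame carries no evidence at all and the whole mask is
#' background. Thresholding each A-line on its own histogram makes the
#' binarization invariant to the angular contrast loss caused by an
#' off-center catheter: each column's histogram is bimodal regardless of
#' its absolute gain, where a single global Otsu cut loses the low-contrast
#' sectors.
#'
#' @param cA1 Numeric matrix in polar orientation (columns = A-lines).
#' @return A logical matrix (`cA1_bin`) with attribute `domain = "polar"`.
#' @export
columnwise_otsu <- function(cA1) {
  x <- unclass(.as_gray(as.matrix(cA1)))
  out <- matrix(FALSE, nrow(x), ncol(x))
  degen <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    ot <- otsu_threshold(x[, j])
    degen[j] <- ot$degenerate
    if (!ot$degenerate) out[, j] <- x[, j] > ot$threshold
  }
  if (all(degen)) {
    out[] <- FALSE            # no contrast anywhere: no tissue evidence
  } else {
    out[, degen] <- TRUE      # shadowed A-lines: repaired by gap correction
  }
  out <- .copy_geom(out, cA1)
  attr(out, "domain") <- "polar"
  out
}
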