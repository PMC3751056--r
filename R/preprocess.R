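#' Blank the catheter-ring artifact
#'
#' Display-format TD-OCT frames carry a bright catheter reflection ring of
#' known maximum radius around the catheter axis. Every pixel whose
#' Euclidean distance from the center is at most `r_max_px` is set to the
#' background level 0; all other pixels are left untouched. The operation
#' is idempotent and never increases intensity.
#'
#' @param img Numeric matrix (square grayscale image).
#' @param r_max_px Ring maximum radius in pixels; must be `< side / 2`.
#' @param center `c(row, col)` of the catheter axis (default: geometric
#'   image center).
#' @return The image with the ring region blanked.
#' @examples
#' m <- matrix(1, 9, 9)
#' sum(remove_catheter_ring(m, 2) == 0)  # 13 pixels within distance 2
#' @export
remove_catheter_ring <- function(img, r_max_px, center = NULL) {
  img <- .as_gray(img)
  side <- nrow(img)
  if (ncol(img) != side) stop("image must be square")
  .check_r_max(r_max_px, side)
  cc <- .center_of(img, center)
  d2 <- outer((seq_len(side) - cc[1])^2, (seq_len(side) - cc[2])^2, "+")
  img[d2 <= r_max_px^2] <- 0
  img
}

#' 2-D median filter with edge replication
#'
#' Despeckles the frame and fades the thin alignment-mark lines while
#' preserving edges. Each output pixel is the exact median of its
#' `window x window` neighborhood; the border is handled by replicating
#' edge pixels.
#'
#' @param img Numeric matrix.
#' @param window Odd window size (default 5).
#' @return Filtered matrix of the same shape.
#' @export
median_filter <- function(img, window = 5L) {
  img <- .as_gray(img)
  if (window %% 2 != 1 || window < 3) stop("'window' must be an odd integer >= 3")
  nr <- nrow(img); nc <- ncol(img)
  half <- (window - 1L) %/% 2L
  offs <- -half:half
  npix <- nr * nc
  k <- window * window
  stack <- matrix(0, npix, k)
  ri <- rep.int(seq_len(nr), nc)
  ci <- rep(seq_len(nc), each = nr)
  s <- 0L
  for (dr in offs) {
    rr <- pmin(pmax(ri + dr, 1L), nr)
    for (dc in offs) {
      s <- s + 1L
      cc <- pmin(pmax(ci + dc, 1L), nc)
      stack[, s] <- img[cbind(rr, cc)]
    }
  }
  # exact row-wise median: sort within rows via order(), take middle column
  sorted <- matrix(stack[order(row(stack), stack)], nrow = npix, byrow = TRUE)
  mid <- (k + 1L) %/% 2L
  matrix(sorted[, mid], nr, nc)
}

#' Resample a Cartesian frame to the polar domain
#'
#' Samples the image on an `n_r x n_theta` grid around `center`: row `i`
#' (1-based) corresponds to radius `(i - 1) * r_scale_px` and column `j`
#' to angle `(j - 1) * 2 * pi / n_theta`, with angle 0 pointing east and
#' angles increasing counter-clockwise. The radial scale is chosen so the
#' last row maps to the largest radius whose full circle lies inside the
#' pixel grid, `(side - 1) / 2` (half the side up to the half-pixel
#' border). Sampling is bilinear; samples outside the image are 0.
#'
#' @param img Square numeric matrix.
#' @param n_r,n_theta Polar grid size (defaults 200 x 630).
#' @param center `c(row, col)` of the polar origin (default: image center).
#' @return An `n_r x n_theta` matrix of class `"polar_image"` carrying the
#'   sampling geometry (`r_scale_px`, `center`, `side_px`) as attributes.
#' @export
cartesian_to_polar <- function(img, n_r = 200L, n_theta = 630L, center = NULL) {
  img <- .as_gray(img)
  side <- nrow(img)
  if (ncol(img) != side) stop("image must be square")
  if (n_r < 2 || n_theta < 8) stop("polar grid must have n_r >= 2, n_theta >= 8")
  cc <- .center_of(img, center)
  r_scale <- ((side - 1) / 2) / (n_r - 1)
  r <- (seq_len(n_r) - 1) * r_scale
  th <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  # visual counter-clockwise: +theta decreases the row index
  rows <- cc[1] - outer(r, sin(th))
  cols <- cc[2] + outer(r, cos(th))
  pol <- .bilinear(img, rows, cols)
  structure(pol,
            r_scale_px = r_scale, center = cc, side_px = side,
            class = c("polar_image", "matrix", "array"))
}

#' Resample a polar image back to the Cartesian domain
#'
#' Inverse of [cartesian_to_polar()]: each Cartesian pixel is interpolated
#' bilinearly on the `(r, theta)` grid, with the angular axis interpolated
#' circularly. Pixels beyond the maximum sampled radius are 0.
#'
#' @param pol A `polar_image` (or any matrix plus explicit geometry).
#' @param side_px Output image side (default: the side recorded in `pol`).
#' @param center Polar origin in the output image (default: recorded).
#' @return A `side_px x side_px` numeric matrix.
#' @export
polar_to_cartesian <- function(pol, side_px = NULL, center = NULL) {
  geo <- .polar_geometry(pol, side_px, center)
  side <- geo$side; cc <- geo$center
  n_r <- nrow(pol); n_theta <- ncol(pol)
  x <- outer(rep(1, side), seq_len(side) - cc[2])
  y <- outer(seq_len(side) - cc[1], rep(1, side))
  r_idx <- sqrt(x^2 + y^2) / geo$r_scale          # 0-based radial index
  th <- atan2(-y, x) %% (2 * pi)
  c_idx <- th * n_theta / (2 * pi)                # 0-based circular index
  out <- matrix(0, side, side)
  inside <- r_idx <= (n_r - 1) + 1e-9
  r0 <- pmin(floor(r_idx[inside]), n_r - 2); r0 <- pmax(r0, 0)
  fr <- r_idx[inside] - r0
  c0 <- floor(c_idx[inside]) %% n_theta
  fc <- c_idx[inside] - floor(c_idx[inside])
  c1 <- (c0 + 1) %% n_theta
  pm <- unclass(pol)
  i00 <- pm[cbind(r0 + 1, c0 + 1)]
  i10 <- pm[cbind(r0 + 2, c0 + 1)]
  i01 <- pm[cbind(r0 + 1, c1 + 1)]
  i11 <- pm[cbind(r0 + 2, c1 + 1)]
  out[inside] <- (1 - fr) * (1 - fc) * i00 + fr * (1 - fc) * i10 +
    (1 - fr) * fc * i01 + fr * fc * i11
  out
}

#' Run the full preprocessing stage
#'
#' Catheter-ring removal, median despeckling, and polar resampling, in
#' that order.
#'
#' @param img Square numeric matrix.
#' @param cfg A [pipeline_config()].
#' @return A `polar_image` (the preprocessed frame `I_PreProc(r, theta)`).
#' @export
preprocess <- function(img, cfg = pipeline_config()) {
  img <- remove_catheter_ring(img, cfg$r_max_px, cfg$center)
  img <- median_filter(img, cfg$median_window)
  cartesian_to_polar(img, cfg$n_r, cfg$n_theta, cfg$center)
}

# ---- internal helpers -------------------------------------------------

.as_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || anyNA(img) || any(!is.finite(img)))
    stop("image must be a finite numeric matrix")
  img
}

.center_of <- function(img, center) {
  if (is.null(center)) center <- c((nrow(img) + 1) / 2, (ncol(img) + 1) / 2)
  if (length(center) != 2 || any(center < 1) ||
      center[1] > nrow(img) || center[2] > ncol(img))
    stop("'center' must be c(row, col) inside the image")
  as.numeric(center)
}

# bilinear sampling of img at fractional (rows, cols); outside -> 0
.bilinear <- function(img, rows, cols) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nrow(rows), ncol(rows))
  ok <- rows >= 1 & rows <= nr & cols >= 1 & cols <= nc
  r <- rows[ok]; c <- cols[ok]
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  out[ok] <- (1 - fr) * (1 - fc) * img[cbind(r0, c0)] +
    fr * (1 - fc) * img[cbind(r0 + 1, c0)] +
    (1 - fr) * fc * img[cbind(r0, c0 + 1)] +
    fr * fc * img[cbind(r0 + 1, c0 + 1)]
  out
}

.polar_geometry <- function(pol, side_px = NULL, center = NULL) {
  side <- if (is.null(side_px)) attr(pol, "side_px") else side_px
  if (is.null(side)) stop("output side unknown: supply 'side_px'")
  r_scale <- attr(pol, "r_scale_px")
  if (is.null(r_scale)) r_scale <- ((side - 1) / 2) / (nrow(pol) - 1)
  cc <- if (is.null(center)) attr(pol, "center") else center
  if (is.null(cc)) cc <- c((side + 1) / 2, (side + 1) / 2)
  list(side = as.integer(side), r_scale = r_scale, center = as.numeric(cc))
}

# carry polar geometry attributes from one plane to another
.copy_geom <- function(to, from) {
  for (a in c("r_scale_px", "center", "side_px")) attr(to, a) <- attr(from, a)
  to
}
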