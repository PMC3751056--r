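#' Discrete Euclidean disk structuring element
#'
#' A pixel belongs to the element iff its center lies within `diam / 2`
#' of the origin. `disk_se(3)` is the full 3x3 square; `disk_se(2)` is the
#' 4-connected cross.
#'
#' @param diam Disk diameter in pixels (>= 1).
#' @return A 0/1 matrix of odd size.
#' @export
disk_se <- function(diam) {
  if (diam < 1) stop("'diam' must be >= 1")
  r <- diam / 2
  m <- floor(r)
  off <- -m:m
  k <- outer(off^2, off^2, "+") <= r^2 + 1e-9
  storage.mode(k) <- "integer"
  k
}

#' Polar reconstruction of the binary tissue object
#'
#' Turns the raw per-A-line binarization `cA1_bin` into the solid
#' complementary polar lumen object `l_polar*` by four morphological
#' steps: (1) binary opening with a 3-px disk, detaching and deleting
#' speckle-sized clutter; (2) upward filling — in every column all rows
#' from the first tissue return down to the bottom become foreground,
#' since OCT carries no information behind the first interface; (3) area
#' selection — only the largest 8-connected component survives, with the
#' angular axis treated as circular; (4) binary closing with a disk of
#' adaptive diameter `D = r_max_px`, smoothing boundary irregularities
#' without reshaping the contour. The closing pads the angular axis by
#' wrap-around and the bottom edge with foreground so the object stays
#' bottom-attached; a final upward fill guarantees a column-solid result.
#'
#' @param cA1_bin Logical matrix in polar orientation.
#' @param r_max_px Adaptive closing diameter `D` (the catheter-ring
#'   maximum radius, in pixels).
#' @param se_small_diam_px Opening element diameter (default 3).
#' @return Logical polar mask `l_polar*`: one solid region attached to the
#'   bottom (maximum-radius) edge.
#' @export
polar_reconstruct <- function(cA1_bin, r_max_px, se_small_diam_px = 3L) {
  m <- .as_mask(cA1_bin)
  if (!any(m)) stop("no tissue detected")
  opened <- .binary_open(m, disk_se(se_small_diam_px), circular = TRUE)
  if (!any(opened)) stop("no tissue detected")
  # an A-line with no tissue evidence left after cleanup is a shadowed
  # column: mark it fully foreground (like a no-contrast gap column) so a
  # shadow never severs the tissue band; gap correction repairs it later
  empty_col <- colSums(opened) == 0L
  opened[, empty_col] <- TRUE
  filled <- apply(opened, 2, cummax) > 0
  lab <- label_components(filled, circular = TRUE)
  sizes <- tabulate(lab[lab > 0])
  selected <- lab == which.max(sizes)
  D <- max(1, round(r_max_px))
  closed <- .binary_close(selected, disk_se(D), circular = TRUE,
                          bottom_fg = TRUE)
  out <- apply(closed, 2, cummax) > 0
  out <- .copy_geom(out, cA1_bin)
  attr(out, "domain") <- "polar"
  out
}

#' Height signal of a polar object
#'
#' For every A-line (column) `j`, `h[j]` is the 0-based row index of the
#' first foreground pixel — the inner boundary radius of the tissue object
#' — or `n_r` when the column is empty. This is the lumen contour in polar
#' coordinates.
#'
#' @param obj Logical matrix in polar orientation.
#' @return Integer vector of length `n_theta` with attribute `n_r`.
#' @export
height_signal <- function(obj) {
  m <- .as_mask(obj)
  n_r <- nrow(m)
  h <- vapply(seq_len(ncol(m)), function(j) {
    i <- which(m[, j])
    if (length(i)) i[1] - 1L else n_r
  }, integer(1))
  structure(h, n_r = n_r, class = "height_signal")
}

#' Detect shadow gaps in a height signal
#'
#' A side-branch ostium (or an intraluminal artifact) leaves an angular
#' run of A-lines whose boundary radius jumps abruptly away from its
#' neighbors. Gaps are found on the circular first difference
#' `d[j] = h[j+1] - h[j]`: columns where `|d| > T`, with
#' `T = k * SD(d)` over the whole derivative signal (default `k = 5`),
#' mark gap shoulders, and each shoulder crossing is paired with the next
#' crossing of opposite sign to delimit one gap. Both polarities are
#' handled, so runs jumping outward (empty shadowed columns) and inward
#' (columns flooded by an artifact) are both detected.
#'
#' @param h A [height_signal()] (or plain numeric vector, length >= 8).
#' @param k Threshold multiplier (default 5).
#' @return A list of gaps, each `list(start, end, cause = "detected")`
#'   with 1-based inclusive circular column indices; empty when the
#'   derivative never exceeds the threshold.
#' @export
detect_gaps <- function(h, k = 5) {
  h <- as.numeric(h)
  n <- length(h)
  if (n < 8) stop("height signal must have length >= 8")
  d <- c(h[-1], h[1]) - h
  s <- sd(d)
  if (!is.finite(s) || s == 0) return(list())
  thr <- k * s
  cross <- which(abs(d) > thr)
  if (length(cross) == 0L) return(list())
  # each above-threshold jump either enters or leaves an anomalous run:
  # the anomalous side of the jump is the one farther from the circle's
  # typical boundary level (the median height). An entry opens a gap and
  # the next exit closes it; stray exits without a matching entry (e.g. a
  # jump whose entry slope was smeared below threshold) are ignored.
  med <- median(h)
  after <- h[(cross %% n) + 1L]
  is_entry <- abs(after - med) > abs(h[cross] - med)
  # scan circularly starting from a typical (non-anomalous) column
  anchor <- which.min(abs(h - median(h)))[1]
  ord <- order((cross - anchor) %% n)
  gaps <- list()
  open_at <- NA_integer_
  for (i in ord) {
    if (is_entry[i]) {
      if (is.na(open_at)) open_at <- cross[i]
    } else if (!is.na(open_at)) {
      start <- (open_at %% n) + 1L
      end <- cross[i]
      len <- ((end - start) %% n) + 1
      if (len >= 1 && len < n)
        gaps[[length(gaps) + 1L]] <-
          list(start = start, end = end, cause = "detected")
      open_at <- NA_integer_
    }
  }
  gaps
}

#' Repair gaps by shape-preserving interpolation
#'
#' Deletes the height values inside every detected gap (plus a guard band
#' of 2 columns at each side, since the closing can round gap shoulders)
#' and restores them by piecewise cubic Hermite interpolation (pchip — a
#' shape-preserving scheme with no overshoot) of the surviving samples on
#' the circularly unwrapped column axis. Interpolated values are rounded
#' to integers and clipped to `[0, n_r - 1]`.
#'
#' @param h A [height_signal()].
#' @param gaps Gap list from [detect_gaps()].
#' @param guard Guard band width in columns (default 2).
#' @return The corrected height signal (same attributes).
#' @export
correct_gaps <- function(h, gaps, guard = 2L) {
  if (length(gaps) == 0L) return(h)
  n <- length(h)
  n_r <- attr(h, "n_r")
  if (is.null(n_r)) n_r <- max(h)
  miss <- logical(n)
  for (g in gaps) {
    len <- ((g$end - g$start) %% n) + 1
    idx <- ((g$start - 1 - guard + seq_len(len + 2 * guard) - 1) %% n) + 1
    miss[idx] <- TRUE
  }
  good <- which(!miss)
  if (length(good) < 4) stop("too few support columns for gap interpolation")
  xx <- c(good - n, good, good + n)
  yy <- rep(as.numeric(h[good]), 3)
  fix <- which(miss)
  vals <- pracma::pchip(xx, yy, fix)
  out <- as.integer(h)
  out[fix] <- as.integer(pmax(0, pmin(n_r - 1, round(vals))))
  structure(out, n_r = n_r, class = "height_signal")
}

#' Rebuild a polar mask from a height signal
#'
#' Column `j` is foreground exactly on rows `>= h[j]` (0-based), the
#' inverse of [height_signal()] for bottom-attached column-solid objects.
#'
#' @param h A [height_signal()] (values in `[0, n_r]`).
#' @param shape `c(n_r, n_theta)`; defaults to the signal's own geometry.
#' @return Logical polar mask.
#' @export
rebuild_from_height <- function(h, shape = NULL) {
  if (is.null(shape)) shape <- c(attr(h, "n_r"), length(h))
  n_r <- shape[1]; n_theta <- shape[2]
  if (length(h) != n_theta) stop("height signal length must match n_theta")
  outer(0:(n_r - 1), as.numeric(h), ">=")
}

#' Cartesian reconstruction of the binary lumen object
#'
#' Negates the complementary polar object `l_polar*` to obtain the polar
#' lumen, transforms it back to the Cartesian domain (interpolated mask
#' thresholded at 0.5), and polishes it with one last binary opening whose
#' disk diameter adapts to `R_min`, the minimum radius between the center
#' and the lumen border (floored at 3 px so the element never degenerates).
#' Finally only the connected component containing (or nearest to) the
#' center is kept.
#'
#' @param l_polar_star Logical polar mask from [polar_reconstruct()] (or
#'   the gap-corrected rebuild), carrying polar geometry attributes.
#' @param side_px Output image side (default: geometry recorded in the mask).
#' @param center Lumen/catheter center in the output image (default:
#'   recorded geometry).
#' @return Logical Cartesian mask `lumen_bin` with attribute
#'   `domain = "cartesian"`.
#' @export
cartesian_reconstruct <- function(l_polar_star, side_px = NULL, center = NULL) {
  m <- .as_mask(l_polar_star)
  lum_pol <- !m
  if (!any(lum_pol)) stop("lumen not found")
  geo <- .polar_geometry(l_polar_star, side_px, center)
  pol_num <- .copy_geom(lum_pol * 1.0, l_polar_star)
  cart <- polar_to_cartesian(pol_num, geo$side, geo$center) >= 0.5
  h <- height_signal(m)
  r_min <- max(3, floor(min(h) * geo$r_scale))
  opened <- .binary_open(cart, disk_se(r_min), circular = FALSE)
  lab <- label_components(opened, circular = FALSE)
  if (max(lab) == 0L) stop("lumen not found")
  cc <- geo$center
  ctr_lab <- lab[round(cc[1]), round(cc[2])]
  if (ctr_lab == 0L) {
    idx <- which(lab > 0L, arr.ind = TRUE)
    d2 <- (idx[, 1] - cc[1])^2 + (idx[, 2] - cc[2])^2
    ctr_lab <- lab[idx[which.min(d2), , drop = FALSE]]
  }
  out <- lab == ctr_lab
  attr(out, "domain") <- "cartesian"
  out
}

#' Extract the lumen contour
#'
#' Traces the outer boundary of the binary lumen object as an ordered
#' closed polyline with sub-pixel vertices: marching squares at level 0.5
#' on the zero-padded indicator field, pre-smoothed with a 3x3 box filter
#' so the level set lands on the true boundary instead of the staircase
#' (a raw binary field inflates a disk's perimeter by about 6%). Very
#' small masks that vanish under smoothing fall back to the raw field.
#'
#' @param lumen_bin Logical Cartesian mask, single component, non-empty.
#' @return A data frame with columns `x` (column coordinate) and `y` (row
#'   coordinate) in pixels; first and last vertex coincide.
#' @export
extract_contour <- function(lumen_bin) {
  m <- .as_mask(lumen_bin)
  if (!any(m)) stop("empty mask")
  nr <- nrow(m); nc <- ncol(m)
  z <- matrix(0, nr + 4, nc + 4)
  z[3:(nr + 2), 3:(nc + 2)] <- m
  zs <- (z[1:(nr + 2), 1:(nc + 2)] + z[1:(nr + 2), 2:(nc + 3)] +
           z[1:(nr + 2), 3:(nc + 4)] +
           z[2:(nr + 3), 1:(nc + 2)] + z[2:(nr + 3), 2:(nc + 3)] +
           z[2:(nr + 3), 3:(nc + 4)] +
           z[3:(nr + 4), 1:(nc + 2)] + z[3:(nr + 4), 2:(nc + 3)] +
           z[3:(nr + 4), 3:(nc + 4)]) / 9
  cl <- grDevices::contourLines(x = 0:(nr + 1), y = 0:(nc + 1), z = zs,
                                levels = 0.5)
  if (length(cl) == 0L)   # mask too small to survive smoothing
    cl <- grDevices::contourLines(x = 0:(nr + 1), y = 0:(nc + 1),
                                  z = z[2:(nr + 3), 2:(nc + 3)], levels = 0.5)
  if (length(cl) == 0L) stop("empty mask")
  best <- cl[[which.max(vapply(cl, function(g) length(g$x), numeric(1)))]]
  xs <- best$y; ys <- best$x   # contourLines x follows rows, y follows columns
  if (xs[1] != xs[length(xs)] || ys[1] != ys[length(ys)]) {
    xs <- c(xs, xs[1]); ys <- c(ys, ys[1])
  }
  data.frame(x = xs, y = ys)
}

#' Label connected components (8-connected, optionally circular)
#'
#' 8-connected labeling of a binary mask; with `circular = TRUE` the last
#' and first columns are treated as adjacent (the angular seam of a polar
#' image).
#'
#' @param mask Logical matrix.
#' @param circular Wrap the column axis.
#' @return Integer matrix of labels (0 = background).
#' @export
label_components <- function(mask, circular = FALSE) {
  m <- .as_mask(mask)
  lab <- EBImage::bwlabel(m * 1L)            # 4-connected
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)
  if (nlab <= 1L) {
    if (circular && nlab == 1L) return(lab)
    if (!circular) return(lab)
  }
  parent <- seq_len(max(nlab, 1L))
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  merge_pairs <- function(la, lb) {
    sel <- la > 0L & lb > 0L & la != lb
    if (any(sel)) {
      pr <- unique(cbind(la[sel], lb[sel]))
      for (i in seq_len(nrow(pr))) unite(pr[i, 1], pr[i, 2])
    }
  }
  nr <- nrow(m); nc <- ncol(m)
  # diagonal adjacency (bwlabel is 4-connected; add the two diagonals)
  merge_pairs(lab[-nr, -nc], lab[-1, -1])
  merge_pairs(lab[-nr, -1], lab[-1, -nc])
  if (circular && nc > 1L) {
    merge_pairs(lab[, nc], lab[, 1])
    merge_pairs(lab[-nr, nc], lab[-1, 1])
    merge_pairs(lab[-1, nc], lab[-nr, 1])
  }
  if (nlab > 0L) {
    roots <- vapply(seq_len(nlab), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    lab[lab > 0L] <- relab[lab[lab > 0L]]
  }
  lab
}

# ---- internal morphology helpers --------------------------------------

.as_mask <- function(m) {
  x <- as.matrix(m)
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x > 0.5)
  stop("mask must be a logical (or 0/1 numeric) matrix")
}

# pad: columns wrapped (circular) or FALSE; rows replicated at bottom,
# FALSE above the top; value-pad for closing keeps the bottom attached
.pad_mask <- function(m, w, circular, bottom_fg) {
  nr <- nrow(m); nc <- ncol(m)
  if (circular) {
    wl <- ((seq_len(w) - 1L) %% nc) + 1L
    left <- m[, rev(nc + 1L - wl), drop = FALSE]
    right <- m[, wl, drop = FALSE]
  } else {
    left <- right <- matrix(FALSE, nr, w)
  }
  wide <- cbind(left, m, right)
  top <- matrix(FALSE, w, ncol(wide))
  bot <- if (bottom_fg) matrix(rep(wide[nr, ], each = w), w, ncol(wide))
         else matrix(FALSE, w, ncol(wide))
  rbind(top, wide, bot)
}

.crop_mask <- function(p, w, nr, nc) p[w + seq_len(nr), w + seq_len(nc)]

.binary_open <- function(m, kern, circular) {
  w <- (nrow(kern) - 1L) %/% 2L + 1L
  p <- .pad_mask(m, w, circular, bottom_fg = FALSE)
  r <- EBImage::dilate(EBImage::erode(p * 1, kern), kern)
  .crop_mask(matrix(as.numeric(r) > 0.5, nrow(p), ncol(p)), w, nrow(m), ncol(m))
}

.binary_close <- function(m, kern, circular, bottom_fg = FALSE) {
  w <- nrow(kern) %/% 2L + 1L
  p <- .pad_mask(m, w, circular, bottom_fg)
  r <- EBImage::erode(EBImage::dilate(p * 1, kern), kern)
  .crop_mask(matrix(as.numeric(r) > 0.5, nrow(p), ncol(p)), w, nrow(m), ncol(m))
}
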