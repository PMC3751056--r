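# fixtures built in code and brute-force oracles shared across tests

# centered disk mask: TRUE where distance from center <= r (pixels)
disk_mask <- function(side, r, center = c((side + 1) / 2, (side + 1) / 2)) {
  d2 <- outer((seq_len(side) - center[1])^2, (seq_len(side) - center[2])^2, "+")
  d2 <- matrix(d2, side, side)
  d2 <= r^2
}

# polar step mask: rows >= row0 (1-based) foreground in every column
step_mask <- function(n_r, n_theta, row0) {
  outer(seq_len(n_r), rep(1, n_theta)) >= row0
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# brute-force median filter with edge replication
median_filter_brute <- function(img, window) {
  half <- (window - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  out <- img
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    rr <- pmin(pmax(i + (-half:half), 1), nr)
    cc <- pmin(pmax(j + (-half:half), 1), nc)
    out[i, j] <- median(img[rr, cc])
  }
  out
}

# exhaustive Otsu oracle: maximize between-class variance over every cut
# between consecutive distinct values; returns the foreground membership
otsu_brute_partition <- function(values) {
  u <- sort(unique(values))
  if (length(u) == 1) return(rep(FALSE, length(values)))
  n <- length(values)
  best <- -Inf; best_cut <- u[1]
  for (i in seq_len(length(u) - 1)) {
    cut <- (u[i] + u[i + 1]) / 2
    lo <- values <= cut
    w0 <- sum(lo) / n; w1 <- 1 - w0
    s2 <- w0 * w1 * (mean(values[lo]) - mean(values[!lo]))^2
    if (s2 > best + 1e-12) { best <- s2; best_cut <- cut }
  }
  values > best_cut
}

# brute-force max set-to-set deviations in pixels
max_dev_brute <- function(seg, gold) {
  pix <- function(m) which(m, arr.ind = TRUE)
  setdist <- function(from, to) {
    if (nrow(from) == 0) return(0)
    max(apply(from, 1, function(p)
      sqrt(min((to[, 1] - p[1])^2 + (to[, 2] - p[2])^2))))
  }
  c(fp = setdist(pix(seg & !gold), pix(gold)),
    fn = setdist(pix(gold & !seg), pix(seg)))
}

# random blobby mask for property tests
random_mask <- function(side, p = 0.3) matrix(runif(side * side) < p, side, side)

# drop all attributes except dim (masks carry domain/geometry attributes)
bare <- function(m) matrix(as.vector(m), nrow(m), ncol(m))
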