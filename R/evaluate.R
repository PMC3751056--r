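#' Area fractions against a gold-standard mask
#'
#' True-positive, false-positive and false-negative areas, each expressed
#' as a percentage of the gold-standard lumen area:
#' `TP = 100 |S & G| / |G|`, `FP = 100 |S \ G| / |G|`,
#' `FN = 100 |G \ S| / |G|`, so `TP + FN = 100` by construction.
#'
#' @param seg,gold Logical masks of identical shape; `gold` non-empty.
#' @return Named numeric vector `c(tp_pct, fp_pct, fn_pct)`.
#' @examples
#' g <- matrix(FALSE, 4, 4); g[2:3, 2:3] <- TRUE
#' s <- matrix(FALSE, 4, 4); s[2:3, 2] <- TRUE; s[2, 3] <- TRUE; s[1, 1:2] <- TRUE
#' area_fractions(s, g)  # 75, 50, 25
#' @export
area_fractions <- function(seg, gold) {
  seg <- .as_mask(seg); gold <- .as_mask(gold)
  .same_shape(seg, gold)
  g <- sum(gold)
  if (g == 0) stop("gold mask is empty")
  tp <- 100 * sum(seg & gold) / g
  fp <- 100 * sum(seg & !gold) / g
  c(tp_pct = tp, fp_pct = fp, fn_pct = 100 - tp)
}

#' Maximum boundary deviations in millimetres
#'
#' `max_fp_mm` is the largest distance from a falsely segmented pixel
#' (`S \ G`) to the gold mask; `max_fn_mm` the largest distance from a
#' missed gold pixel (`G \ S`) to the segmentation. Distances are exact
#' Euclidean pixel-set-to-set distances scaled by `px_mm`; an empty
#' difference set contributes 0.
#'
#' @param seg,gold Logical masks of identical shape.
#' @param px_mm Millimetres per pixel (default: `fov_mm` over the image
#'   side with a 6 mm field of view).
#' @param fov_mm Field-of-view side used for the default `px_mm`.
#' @return Named numeric vector `c(max_fp_mm, max_fn_mm)`.
#' @export
max_deviations <- function(seg, gold, px_mm = NULL, fov_mm = 6) {
  seg <- .as_mask(seg); gold <- .as_mask(gold)
  .same_shape(seg, gold)
  if (is.null(px_mm)) px_mm <- fov_mm / ncol(seg)
  if (px_mm <= 0) stop("'px_mm' must be > 0")
  fp_set <- seg & !gold
  fn_set <- gold & !seg
  if (!any(seg) && any(fn_set)) stop("undefined deviation: segmentation is empty")
  max_fp <- if (any(fp_set)) {
    d <- .dist_to_set(gold)
    max(d[fp_set]) * px_mm
  } else 0
  max_fn <- if (any(fn_set)) {
    d <- .dist_to_set(seg)
    max(d[fn_set]) * px_mm
  } else 0
  c(max_fp_mm = max_fp, max_fn_mm = max_fn)
}

#' Overlap ratio (Jaccard) and overlap Dice, in percent
#'
#' `OR = 100 |S & G| / |S | G|` and `OD = 100 * 2 |S & G| / (|S| + |G|)`;
#' the two are linked by `OD = 200 OR / (100 + OR)`.
#'
#' @param seg,gold Logical masks of identical shape, union non-empty.
#' @return Named numeric vector `c(or_pct, od_pct)`.
#' @export
overlap_scores <- function(seg, gold) {
  seg <- .as_mask(seg); gold <- .as_mask(gold)
  .same_shape(seg, gold)
  u <- sum(seg | gold)
  if (u == 0) stop("both masks are empty")
  i <- sum(seg & gold)
  c(or_pct = 100 * i / u, od_pct = 100 * 2 * i / (sum(seg) + sum(gold)))
}

#' Full seven-value accuracy panel
#'
#' Convenience wrapper computing [area_fractions()], [max_deviations()]
#' and [overlap_scores()] in one call.
#'
#' @inheritParams max_deviations
#' @return A one-row data frame with columns `tp_pct`, `fp_pct`, `fn_pct`,
#'   `max_fp_mm`, `max_fn_mm`, `or_pct`, `od_pct`.
#' @export
segmentation_metrics <- function(seg, gold, px_mm = NULL, fov_mm = 6) {
  af <- area_fractions(seg, gold)
  md <- max_deviations(seg, gold, px_mm, fov_mm)
  ov <- overlap_scores(seg, gold)
  as.data.frame(as.list(c(af, md, ov)))
}

#' Summarize a batch of accuracy panels
#'
#' Mean and standard deviation of each metric over a set of frames, the
#' usual reporting layout for a segmentation study.
#'
#' @param metrics Data frame of per-frame rows as returned by
#'   [segmentation_metrics()].
#' @return Data frame with columns `metric`, `mean`, `sd`.
#' @export
summarize_metrics <- function(metrics) {
  stopifnot(is.data.frame(metrics), nrow(metrics) >= 1)
  data.frame(
    metric = names(metrics),
    mean = vapply(metrics, mean, numeric(1)),
    sd = vapply(metrics, function(x) if (length(x) > 1) sd(x) else 0, numeric(1)),
    row.names = NULL
  )
}

# exact Euclidean distance from every pixel to the nearest TRUE pixel
.dist_to_set <- function(mask) {
  d <- EBImage::distmap((!mask) * 1, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

.same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("masks must have identical shape")
  invisible(TRUE)
}
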