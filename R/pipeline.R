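#' Run the full lumen-segmentation pipeline on one frame
#'
#' Executes the three stages in order — preprocessing (catheter-ring
#' removal, median despeckling, polar resampling), feature extraction
#' (level-1 Haar frame, per-A-line Otsu), and binary morphological
#' reconstruction (polar opening / upward filling / area selection /
#' adaptive closing, optional shadow-gap detection and repair, Cartesian
#' rebuild with adaptive final opening) — and extracts the lumen contour.
#' The pipeline contains no randomness: identical input and configuration
#' give bit-identical output.
#'
#' @param img Square numeric matrix, intensities in `[0, 1]`.
#' @param cfg A [pipeline_config()].
#' @return A list of class `"lumen_segmentation"` with elements
#'   `lumen_bin` (logical Cartesian mask), `contour` (data frame `x`, `y`),
#'   and `report` (list: `gaps` — detected gap intervals, `gap_corrected`,
#'   `r_min_px`, `config`, `version`, `stage_seconds`).
#' @examples
#' ph <- generate_phantom(phantom_params(speckle_contrast = 0, seed = 7))
#' res <- run_pipeline(ph$image, pipeline_config(r_max_px = 20))
#' segmentation_metrics(res$lumen_bin, ph$gold)
#' @export
run_pipeline <- function(img, cfg = pipeline_config()) {
  timings <- c()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- tryCatch(force(expr), error = function(e)
      stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    v
  }
  pol <- clock("preprocess", preprocess(img, cfg))
  cA1_bin <- clock("features", {
    planes <- dwpf_level1(pol)
    columnwise_otsu(planes$cA1)
  })
  gaps <- list()
  l_star <- clock("morphrec_polar",
                  polar_reconstruct(cA1_bin, cfg$r_max_px, cfg$se_small_diam_px))
  if (cfg$gap_correction) {
    h <- height_signal(l_star)
    gaps <- detect_gaps(h, cfg$gap_k)
    if (length(gaps)) {
      lp <- .copy_geom(rebuild_from_height(correct_gaps(h, gaps)), l_star)
      attr(lp, "domain") <- "polar"
      l_star <- lp
    }
  }
  lumen_bin <- clock("morphrec_cartesian",
                     cartesian_reconstruct(l_star, nrow(img), cfg$center))
  contour <- clock("contour", extract_contour(lumen_bin))
  h_final <- height_signal(l_star)
  structure(list(
    lumen_bin = lumen_bin,
    contour = contour,
    report = list(
      gaps = gaps,
      gap_corrected = length(gaps) > 0 && cfg$gap_correction,
      r_min_px = max(3, floor(min(h_final) * attr(l_star, "r_scale_px"))),
      config = cfg,
      version = as.character(utils::packageVersion("octlumen")),
      stage_seconds = timings
    )
  ), class = "lumen_segmentation")
}

#' Segment one frame and optionally score it against a gold standard
#'
#' Thin wrapper around [run_pipeline()] that attaches the seven-value
#' accuracy panel when a gold mask is supplied.
#'
#' @param img Square numeric matrix.
#' @param cfg A [pipeline_config()].
#' @param gold Optional logical gold-standard lumen mask.
#' @return The [run_pipeline()] result; with `gold`, an extra `metrics`
#'   element (one-row data frame).
#' @export
segment_image <- function(img, cfg = pipeline_config(), gold = NULL) {
  res <- run_pipeline(img, cfg)
  if (!is.null(gold))
    res$metrics <- segmentation_metrics(res$lumen_bin, gold,
                                        fov_mm = cfg$fov_mm)
  res
}

#' Segment a batch of frames and summarize accuracy
#'
#' Runs the pipeline over a list of frames (with optional golds) and,
#' when golds are present, returns per-frame metric rows plus the
#' mean-and-SD summary layout.
#'
#' @param imgs List of square numeric matrices.
#' @param cfg A [pipeline_config()].
#' @param golds Optional list of gold masks, same length as `imgs`.
#' @return A list with `results` (per-frame segmentations), and when
#'   golds are given `metrics` (data frame, one row per frame) and
#'   `summary` (from [summarize_metrics()]).
#' @export
segment_batch <- function(imgs, cfg = pipeline_config(), golds = NULL) {
  stopifnot(is.list(imgs))
  if (!is.null(golds)) stopifnot(length(golds) == length(imgs))
  results <- lapply(seq_along(imgs), function(i)
    segment_image(imgs[[i]], cfg, if (is.null(golds)) NULL else golds[[i]]))
  out <- list(results = results)
  if (!is.null(golds)) {
    out$metrics <- do.call(rbind, lapply(results, `[[`, "metrics"))
    out$summary <- summarize_metrics(out$metrics)
  }
  out
}

#' Plot a segmentation result over the frame
#'
#' Displays the grayscale frame with the extracted lumen contour (and
#' optionally the gold-standard outline) overlaid.
#'
#' @param img Numeric matrix (the original frame).
#' @param result A `"lumen_segmentation"` from [run_pipeline()].
#' @param gold Optional gold mask whose outline is drawn for comparison.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `NULL`.
#' @export
plot_segmentation <- function(img, result, gold = NULL, ...) {
  nr <- nrow(img)
  graphics::image(seq_len(ncol(img)), seq_len(nr), t(img[nr:1, , drop = FALSE]),
                  col = grDevices::gray(seq(0, 1, length.out = 256)),
                  asp = 1, xlab = "", ylab = "", axes = FALSE, ...)
  ct <- result$contour
  graphics::lines(ct$x, nr + 1 - ct$y, col = "green", lwd = 2)
  if (!is.null(gold)) {
    gc <- extract_contour(gold)
    graphics::lines(gc$x, nr + 1 - gc$y, col = "blue", lwd = 1.5, lty = 2)
  }
  invisible(NULL)
}

#' @export
print.lumen_segmentation <- function(x, ...) {
  cat("IVOCT lumen segmentation\n")
  cat("  lumen area (px):", sum(x$lumen_bin), "\n")
  cat("  contour vertices:", nrow(x$contour), "\n")
  cat("  gaps detected:", length(x$report$gaps),
      if (x$report$gap_corrected) "(corrected)" else "", "\n")
  if (!is.null(x$metrics)) {
    cat("  metrics:\n")
    print(round(x$metrics, 3))
  }
  invisible(x)
}
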