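#' Pipeline configuration
#'
#' Bundles every tunable parameter of the segmentation pipeline. Defaults
#' follow the method's fixed operating point: a 200 x 630 polar grid
#' (about 0.57 degrees per A-line), a 5x5 median window, a 3-px opening
#' element, a closing element whose diameter adapts to the catheter-ring
#' maximum radius, and a 5-standard-deviation derivative threshold for
#' shadow-gap detection.
#'
#' @param r_max_px Catheter-ring maximum radius in Cartesian pixels; every
#'   pixel within this distance of the catheter axis is blanked, and the
#'   polar closing element diameter `D` equals this value.
#' @param median_window Odd window size of the despeckling median filter.
#' @param n_r,n_theta Polar grid size (radial samples x A-lines).
#' @param se_small_diam_px Diameter of the small disk structuring element
#'   used by the polar opening.
#' @param gap_k Multiplier `k` of the derivative standard deviation in the
#'   shadow-gap threshold `T = k * SD(dh)`.
#' @param fov_mm Physical side length of the (square) field of view.
#' @param center Optional catheter-axis position `c(row, col)` in pixels;
#'   `NULL` means the geometric image center.
#' @param gap_correction Logical; run shadow-gap detection/repair.
#'
#' @return A list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(r_max_px = 20)
#' cfg$n_theta
#' @export
pipeline_config <- function(r_max_px = 20L,
                            median_window = 5L,
                            n_r = 200L,
                            n_theta = 630L,
                            se_small_diam_px = 3L,
                            gap_k = 5,
                            fov_mm = 6,
                            center = NULL,
                            gap_correction = TRUE) {
  if (!is.numeric(r_max_px) || length(r_max_px) != 1L || r_max_px < 1)
    stop("'r_max_px' must be a single number >= 1")
  if (median_window %% 2 != 1 || median_window < 3)
    stop("'median_window' must be an odd integer >= 3")
  if (n_r < 2 || n_theta < 8)
    stop("polar grid must have n_r >= 2 and n_theta >= 8")
  if (gap_k <= 0) stop("'gap_k' must be > 0")
  if (fov_mm <= 0) stop("'fov_mm' must be > 0")
  structure(list(
    r_max_px = as.numeric(r_max_px),
    median_window = as.integer(median_window),
    n_r = as.integer(n_r),
    n_theta = as.integer(n_theta),
    se_small_diam_px = as.integer(se_small_diam_px),
    gap_k = as.numeric(gap_k),
    fov_mm = as.numeric(fov_mm),
    center = center,
    gap_correction = isTRUE(gap_correction)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' Configurations serialize as plain YAML `key: value` files holding the
#' fields of [pipeline_config()]; unknown keys are rejected.
#'
#' @param path File path.
#' @param cfg A `pipeline_config` object.
#' @return `read_config()` returns a `pipeline_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# validate r_max against a concrete image side
.check_r_max <- function(r_max_px, side) {
  if (r_max_px < 0 || r_max_px >= side / 2)
    stop("'r_max_px' must lie in [0, image side / 2)")
  invisible(TRUE)
}
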