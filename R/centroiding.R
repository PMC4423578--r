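# Profile-scan peak picking: one instantaneous neutromer hull per strict
# local intensity maximum, bounded by zero-intensity points and by
# local-minimum separator points (which belong to neither adjacent hull).

#' Centroider configuration
#'
#' @param min_points Minimum raw points per hull; smaller hulls are
#'   discarded (default 1).
#' @param intensity_floor Points with intensity at or below this value are
#'   treated as zero (default 0).
#' @param intensity_mode How a neutroid's intensity summarises its hull:
#'   `"sum"` of member point intensities (default; makes intensity
#'   conservation exact) or `"apex"` height.
#' @return An object of class `centroider_config`.
#' @export
centroider_config <- function(min_points = 1L, intensity_floor = 0,
                              intensity_mode = c("sum", "apex")) {
  if (min_points < 1) stop("min_points must be >= 1")
  if (intensity_floor < 0) stop("intensity_floor must be >= 0")
  structure(list(min_points = as.integer(min_points),
                 intensity_floor = as.numeric(intensity_floor),
                 intensity_mode = match.arg(intensity_mode)),
            class = "centroider_config")
}

# Classify each point of an intensity vector for segmentation.
# Returns integer codes: 0 = ordinary, 1 = zero/floored, 2 = interior
# local-minimum separator (every point of a minimum plateau).
.point_classes <- function(y, floor = 0) {
  n <- length(y)
  cls <- integer(n)
  cls[y <= floor] <- 1L
  # run-length view of the non-floored values to find minimum plateaus
  i <- 1L
  while (i <= n) {
    if (cls[i] == 1L) { i <- i + 1L; next }
    j <- i
    while (j < n && cls[j + 1L] != 1L && y[j + 1L] == y[i]) j <- j + 1L
    left_higher <- i > 1L && cls[i - 1L] != 1L && y[i - 1L] > y[i]
    right_higher <- j < n && cls[j + 1L] != 1L && y[j + 1L] > y[i]
    if (left_higher && right_higher) cls[i:j] <- 2L
    i <- j + 1L
  }
  cls
}

#' Detect instantaneous neutromer hulls in one scan
#'
#' Two-dimensional peak detection within a single spectrum: local intensity
#' maxima are found as a function of m/z (equal-intensity plateaus collapse
#' to their leftmost point; scan edges count as valleys) and each hull is
#' extended outward from its apex until the intensity drops to zero (or to
#' the configured floor) or a local minimum is reached. Separator minima
#' belong to neither adjacent hull, so hulls are disjoint.
#'
#' @param scan An [ms_scan()].
#' @param config A [centroider_config()].
#' @return List of [instantaneous_hull()] objects in ascending m/z order;
#'   empty list for an empty scan.
#' @export
detect_instantaneous_hulls <- function(scan, config = centroider_config()) {
  y <- scan$intensity
  n <- length(y)
  if (n == 0) return(list())
  cls <- .point_classes(y, config$intensity_floor)

  hulls <- list()
  i <- 1L
  while (i <= n) {
    if (cls[i] != 0L) { i <- i + 1L; next }
    # locate the apex plateau of the stretch starting at i
    j <- i
    while (j < n && cls[j + 1L] == 0L) j <- j + 1L
    # stretch i..j is one hull: exactly one maximum lives in it, because any
    # interior direction change would have produced a separator minimum
    seg <- i:j
    if (length(seg) >= config$min_points) {
      apex <- which.max(y[seg])  # leftmost on plateau ties
      hulls[[length(hulls) + 1L]] <- instantaneous_hull(
        scan_index = scan$scan_index, rt = scan$rt,
        mz = scan$mz[seg], intensity = y[seg],
        apex_index = apex, start_index = i)
    }
    i <- j + 1L
  }
  hulls
}

#' Centroid an instantaneous hull into a neutroid
#'
#' The neutroid m/z is the intensity-weighted mean of the member point m/z
#' values; a one-point hull's m/z is taken unchanged and a two-point hull
#' reduces to the intensity-weighted average of the two. Intensity is the
#' sum of member point intensities (or the apex height, per config).
#'
#' @param hull An [instantaneous_hull()].
#' @param config A [centroider_config()].
#' @return One-row `data.frame` with columns `scan_index`, `rt`, `mz`,
#'   `intensity`.
#' @export
centroid_hull <- function(hull, config = centroider_config()) {
  tot <- sum(hull$intensity)
  if (tot == 0) stop("cannot centroid an all-zero-intensity hull")
  # one raw data point: its m/z is the centroid position, taken exactly
  mz <- if (length(hull$mz) == 1L) hull$mz[1L]
        else sum(hull$mz * hull$intensity) / tot
  val <- if (config$intensity_mode == "apex") hull$intensity[hull$apex_index]
         else tot
  data.frame(scan_index = hull$scan_index, rt = hull$rt, mz = mz,
             intensity = val)
}

#' Centroid every scan of a run
#'
#' Applies [detect_instantaneous_hulls()] and [centroid_hull()] per scan of
#' a profile-mode run. A centroid-mode run is passed through: each point
#' becomes its own single-point hull and neutroid, m/z unchanged.
#'
#' @param run A [raw_run()].
#' @param config A [centroider_config()].
#' @return An object of class `centroided_run`: list with `neutroids`
#'   (data.frame of all neutroids: `scan_index`, `rt`, `mz`, `intensity`,
#'   `hull_id`, sorted by scan then m/z) and `hulls` (named list of the
#'   source [instantaneous_hull()] objects, keyed by `hull_id`).
#' @export
centroid_run <- function(run, config = centroider_config()) {
  hulls <- list()
  rows <- list()
  hid <- 0L
  for (scan in run$scans) {
    sc_hulls <- if (run$mode == "centroid") {
      lapply(seq_along(scan$mz), function(i)
        instantaneous_hull(scan$scan_index, scan$rt, scan$mz[i],
                           scan$intensity[i], apex_index = 1L,
                           start_index = i))
    } else {
      detect_instantaneous_hulls(scan, config)
    }
    for (h in sc_hulls) {
      hid <- hid + 1L
      id <- sprintf("H%06d", hid)
      hulls[[id]] <- h
      row <- centroid_hull(h, config)
      row$hull_id <- id
      rows[[hid]] <- row
    }
  }
  neutroids <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(scan_index = integer(0), rt = numeric(0), mz = numeric(0),
               intensity = numeric(0), hull_id = character(0))
  neutroids <- neutroids[order(neutroids$scan_index, neutroids$mz), ,
                         drop = FALSE]
  rownames(neutroids) <- NULL
  structure(list(neutroids = neutroids, hulls = hulls),
            class = "centroided_run")
}

#' Neutroids of a centroided run, grouped by scan
#'
#' @param x A `centroided_run` (from [centroid_run()]).
#' @return Named list mapping scan index (as character) to the data.frame of
#'   that scan's neutroids, ascending in m/z.
#' @export
neutroids_by_scan <- function(x) {
  stopifnot(inherits(x, "centroided_run"))
  split(x$neutroids, x$neutroids$scan_index)
}

#' @export
print.centroided_run <- function(x, ...) {
  cat(sprintf("<centroided_run> %d neutroids across %d scans\n",
              nrow(x$neutroids), length(unique(x$neutroids$scan_index))))
  invisible(x)
}
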