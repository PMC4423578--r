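# Assembly of neutroids across scans into neutromer traces, with culling of
# short traces and splitting of erroneously merged traces.

#' Trace builder configuration
#'
#' @param ppm_tol Link tolerance in ppm between a neutroid and the reference
#'   m/z of an open trace (default 7).
#' @param max_gap_scans Number of scans a trace may skip and still accept a
#'   neutroid (default 1: a match is sought in the previous or penultimate
#'   scan).
#' @param min_trace_length Minimum neutroid count for a trace to survive
#'   culling (default 2).
#' @param split_ratio A trace is split at an interior local minimum whose
#'   intensity is at most (lesser surrounding local maximum)/split_ratio
#'   (default 1.3).
#' @return An object of class `trace_builder_config`.
#' @export
trace_builder_config <- function(ppm_tol = 7, max_gap_scans = 1L,
                                 min_trace_length = 2L, split_ratio = 1.3) {
  if (ppm_tol <= 0) stop("ppm_tol must be positive")
  if (max_gap_scans < 0) stop("max_gap_scans must be >= 0")
  if (min_trace_length < 1) stop("min_trace_length must be >= 1")
  if (split_ratio <= 1) stop("split_ratio must be > 1")
  structure(list(ppm_tol = as.numeric(ppm_tol),
                 max_gap_scans = as.integer(max_gap_scans),
                 min_trace_length = as.integer(min_trace_length),
                 split_ratio = as.numeric(split_ratio)),
            class = "trace_builder_config")
}

ppm_diff <- function(mz, ref) abs(mz - ref) / ref * 1e6

#' Build neutromer traces from per-scan neutroids
#'
#' Scans are processed in ascending order. Each neutroid joins the open
#' trace whose reference m/z (the m/z of the trace's most recently added
#' neutroid) is nearest in ppm among all open traces within `ppm_tol` whose
#' last neutroid lies in the previous scan or up to `max_gap_scans` further
#' back; otherwise it opens a new trace. Competing claims on one trace are
#' resolved closest-in-ppm first, with displaced neutroids reconsidered
#' against the remaining traces. A trace receiving no neutroid for more than
#' `max_gap_scans + 1` consecutive scans is closed.
#'
#' @param x A `centroided_run` from [centroid_run()], or a data.frame of
#'   neutroids with columns `scan_index`, `rt`, `mz`, `intensity` (and
#'   optionally `hull_id`).
#' @param config A [trace_builder_config()].
#' @return List of [neutromer_trace()] objects in order of trace creation.
#' @export
build_neutromer_traces <- function(x, config = trace_builder_config()) {
  nd <- if (inherits(x, "centroided_run")) x$neutroids else x
  stopifnot(is.data.frame(nd))
  if (nrow(nd) == 0) return(list())
  if (!"hull_id" %in% names(nd)) nd$hull_id <- NA_character_
  if (anyDuplicated(nd[, c("scan_index", "mz")]))
    stop("duplicate neutroid (same scan_index and m/z)")
  nd <- nd[order(nd$scan_index, nd$mz), , drop = FALSE]

  open <- list()    # each: list(last_mz, last_scan, rows = list of row idx)
  done <- list()
  counter <- 0L
  max_reach <- config$max_gap_scans + 1L

  by_scan <- split(seq_len(nrow(nd)), nd$scan_index)
  scan_ids <- as.integer(names(by_scan))

  for (si in seq_along(scan_ids)) {
    n_scan <- scan_ids[si]
    # retire traces that have aged out of reach
    if (length(open) > 0) {
      ages <- vapply(open, function(t) n_scan - t$last_scan, numeric(1))
      retired <- ages > max_reach
      done <- c(done, open[retired])
      open <- open[!retired]
    }
    idx <- by_scan[[si]]
    # candidate (neutroid, trace) pairs within tolerance, matched greedily
    # by ascending ppm; ties broken by neutroid m/z, then trace seniority
    if (length(open) > 0) {
      cand <- expand.grid(ni = seq_along(idx), ti = seq_along(open))
      ref <- vapply(open, function(t) t$last_mz, numeric(1))[cand$ti]
      cand$ppm <- ppm_diff(nd$mz[idx[cand$ni]], ref)
      cand <- cand[cand$ppm <= config$ppm_tol, , drop = FALSE]
      cand <- cand[order(cand$ppm, nd$mz[idx[cand$ni]], cand$ti), ,
                   drop = FALSE]
      taken_n <- logical(length(idx))
      taken_t <- logical(length(open))
      for (r in seq_len(nrow(cand))) {
        ni <- cand$ni[r]; ti <- cand$ti[r]
        if (taken_n[ni] || taken_t[ti]) next
        taken_n[ni] <- TRUE; taken_t[ti] <- TRUE
        open[[ti]]$rows <- c(open[[ti]]$rows, idx[ni])
        open[[ti]]$last_mz <- nd$mz[idx[ni]]
        open[[ti]]$last_scan <- n_scan
      }
      unmatched <- idx[!taken_n]
    } else {
      unmatched <- idx
    }
    for (i in unmatched) {    # ascending m/z: deterministic trace ids
      counter <- counter + 1L
      open[[length(open) + 1L]] <- list(
        last_mz = nd$mz[i], last_scan = n_scan, rows = list(i),
        id = sprintf("T%05d", counter))
    }
  }
  done <- c(done, open)
  done <- done[order(vapply(done, `[[`, character(1), "id"))]  # creation order
  lapply(done, function(t) {
    rows <- unlist(t$rows)
    neutromer_trace(nd[rows, c("scan_index", "rt", "mz", "intensity",
                               "hull_id")], trace_id = t$id)
  })
}

#' Cull short neutromer traces
#'
#' Removes traces with fewer than `min_trace_length` neutroids (default 2:
#' at least two centroids must have been matched together); input order is
#' preserved.
#'
#' @param traces List of [neutromer_trace()].
#' @param config A [trace_builder_config()].
#' @return Filtered list of traces.
#' @export
cull_short_traces <- function(traces, config = trace_builder_config()) {
  keep <- vapply(traces, function(t) nrow(t$neutroids) >= config$min_trace_length,
                 logical(1))
  traces[keep]
}

# positions of strict local maxima / interior minima in an intensity vector,
# plateaus collapsing to their leftmost point
.extrema <- function(y) {
  n <- length(y)
  maxima <- integer(0); minima <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    left <- if (i > 1L) y[i - 1L] else NA_real_
    right <- if (j < n) y[j + 1L] else NA_real_
    if ((is.na(left) || left < y[i]) && (is.na(right) || right < y[i]))
      maxima <- c(maxima, i)
    if (!is.na(left) && !is.na(right) && left > y[i] && right > y[i])
      minima <- c(minima, i)
    i <- j + 1L
  }
  list(maxima = maxima, minima = minima)
}

# first split position in an intensity vector, or 0L if none triggers:
# an interior local minimum flanked by local maxima on both sides whose
# intensity is <= lesser flanking maximum / split_ratio
.split_point <- function(y, split_ratio) {
  ex <- .extrema(y)
  for (p in ex$minima) {
    lmax <- ex$maxima[ex$maxima < p]
    rmax <- ex$maxima[ex$maxima > p]
    if (length(lmax) == 0 || length(rmax) == 0) next
    lesser <- min(y[lmax[length(lmax)]], y[rmax[1L]])
    if (y[p] <= lesser / split_ratio) return(p)
  }
  0L
}

#' Split erroneously merged neutromer traces
#'
#' Wherever a trace contains an interior local intensity minimum whose value
#' is at most 1/`split_ratio` of the lesser of the two surrounding local
#' maxima, the trace is partitioned at that minimum, the minimum neutroid
#' joining the right-hand segment. Splitting is applied iteratively until no
#' minimum triggers; the resulting segments are then re-subjected to
#' [cull_short_traces()].
#'
#' @param traces List of [neutromer_trace()].
#' @param config A [trace_builder_config()].
#' @return List of traces; split segments carry ids `<parent>/1`,
#'   `<parent>/2`, ...
#' @export
split_traces <- function(traces, config = trace_builder_config()) {
  out <- list()
  for (tr in traces) {
    segs <- .split_recursive(tr$neutroids, config$split_ratio)
    if (length(segs) == 1L) {
      out[[length(out) + 1L]] <- tr
    } else {
      for (k in seq_along(segs)) {
        out[[length(out) + 1L]] <- neutromer_trace(
          segs[[k]], trace_id = sprintf("%s/%d", tr$trace_id, k))
      }
    }
  }
  cull_short_traces(out, config)
}

.split_recursive <- function(nd, split_ratio) {
  p <- .split_point(nd$intensity, split_ratio)
  if (p == 0L) return(list(nd))
  left <- nd[seq_len(p - 1L), , drop = FALSE]
  right <- nd[p:nrow(nd), , drop = FALSE]
  c(.split_recursive(left, split_ratio), .split_recursive(right, split_ratio))
}

#' Recover the raw-point hulls behind neutromer traces
#'
#' A neutromer trace is the centroided form of a neutromer hull; this
#' inverts the bookkeeping, collecting for each trace the instantaneous
#' hulls whose centroids are the trace's neutroids.
#'
#' @param traces List of [neutromer_trace()] whose neutroids carry
#'   `hull_id`s.
#' @param centroided A `centroided_run` from [centroid_run()] on the source
#'   run.
#' @return List of objects of class `neutromer_hull`, each with fields
#'   `trace_id` and `instantaneous_hulls` (ordered by scan index).
#' @export
extract_hulls <- function(traces, centroided) {
  stopifnot(inherits(centroided, "centroided_run"))
  lapply(traces, function(tr) {
    ids <- tr$neutroids$hull_id
    if (is.null(ids) || anyNA(ids) || !all(ids %in% names(centroided$hulls)))
      stop("trace ", tr$trace_id, " has a neutroid with no recorded source hull")
    structure(list(trace_id = tr$trace_id,
                   instantaneous_hulls = centroided$hulls[ids]),
              class = "neutromer_hull")
  })
}
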