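# ---- core constructors -----------------------------------------------------

#' Construct a single MS1 scan
#'
#' A scan is one spectrum acquired at one retention time: a sequence of
#' raw data points (m/z, intensity) ordered by ascending m/z.
#'
#' @param scan_index 0-based ordinal position of the scan within its run.
#' @param rt Retention time in seconds (non-negative).
#' @param mz Numeric vector of m/z values (Th), strictly ascending.
#' @param intensity Numeric vector of ion abundances (counts, all >= 0),
#'   same length as `mz`.
#' @return An object of class `ms_scan`.
#' @export
ms_scan <- function(scan_index, rt, mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz) > 0) {
    if (any(mz <= 0)) stop("scan m/z values must be positive")
    if (any(diff(mz) <= 0)) stop("scan points must be strictly ascending in m/z")
    if (any(intensity < 0)) stop("scan intensities must be non-negative")
  }
  if (rt < 0) stop("retention time must be non-negative")
  structure(
    list(scan_index = as.integer(scan_index), rt = as.numeric(rt),
         mz = as.numeric(mz), intensity = as.numeric(intensity)),
    class = "ms_scan")
}

#' Construct a raw MS1 run
#'
#' The source data object for the pipeline: scans ordered by ascending
#' retention time, in profile or centroid mode.
#'
#' @param scans List of [ms_scan()] objects with strictly increasing rt and
#'   contiguous 0-based scan indices.
#' @param mode `"profile"` or `"centroid"`.
#' @param metadata Free-form named list (source file, instrument, ...).
#' @return An object of class `raw_run`.
#' @export
raw_run <- function(scans, mode = c("profile", "centroid"), metadata = list()) {
  mode <- match.arg(mode)
  if (length(scans) > 0) {
    rts <- vapply(scans, function(s) s$rt, numeric(1))
    idx <- vapply(scans, function(s) s$scan_index, integer(1))
    if (any(diff(rts) <= 0)) stop("scan retention times must be strictly increasing")
    if (!identical(idx, seq_along(scans) - 1L))
      stop("scan_index must be contiguous from 0")
  }
  structure(list(scans = scans, mode = mode, metadata = metadata),
            class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  npts <- sum(vapply(x$scans, function(s) length(s$mz), integer(1)))
  cat(sprintf("<raw_run> %d scans (%s mode), %d raw points\n",
              length(x$scans), x$mode, npts))
  if (length(x$scans) > 0) {
    rts <- vapply(x$scans, function(s) s$rt, numeric(1))
    cat(sprintf("  RT %.2f .. %.2f s\n", min(rts), max(rts)))
  }
  invisible(x)
}

#' Construct an instantaneous neutromer hull
#'
#' The raw-point region of one isotopic species in one scan: a contiguous
#' sub-sequence of a scan's points around a local intensity maximum. Its
#' centroided form is a neutroid.
#'
#' @param scan_index 0-based index of the source scan.
#' @param rt Retention time of the source scan (seconds).
#' @param mz,intensity Member raw points (m/z ascending).
#' @param apex_index 1-based position of the local maximum within the points.
#' @param start_index 1-based position of the first member point within the
#'   source scan (bookkeeping for provenance).
#' @return An object of class `instantaneous_hull`.
#' @export
instantaneous_hull <- function(scan_index, rt, mz, intensity, apex_index,
                               start_index = NA_integer_) {
  stopifnot(length(mz) == length(intensity), length(mz) >= 1)
  if (apex_index < 1 || apex_index > length(mz)) stop("apex_index out of range")
  if (any(intensity > intensity[apex_index]))
    stop("apex must carry the greatest intensity in the hull")
  structure(
    list(scan_index = as.integer(scan_index), rt = as.numeric(rt),
         mz = as.numeric(mz), intensity = as.numeric(intensity),
         apex_index = as.integer(apex_index),
         start_index = as.integer(start_index)),
    class = "instantaneous_hull")
}

#' Construct a neutromer trace
#'
#' The RT-extended, centroided signal of one isotopic species: a collection
#' of neutroids, one per scan, ordered by scan index.
#'
#' @param neutroids `data.frame` with columns `scan_index`, `rt`, `mz`,
#'   `intensity` and (optionally) `hull_id`, ordered by `scan_index`.
#' @param trace_id Opaque identifier.
#' @return An object of class `neutromer_trace`.
#' @export
neutromer_trace <- function(neutroids, trace_id = "T") {
  stopifnot(is.data.frame(neutroids),
            all(c("scan_index", "rt", "mz", "intensity") %in% names(neutroids)))
  if (nrow(neutroids) > 1 && any(diff(neutroids$scan_index) <= 0))
    stop("neutroids must be ordered by strictly increasing scan_index")
  if (any(neutroids$intensity <= 0)) stop("neutroid intensities must be positive")
  structure(list(neutroids = neutroids, trace_id = as.character(trace_id)),
            class = "neutromer_trace")
}

#' @export
print.neutromer_trace <- function(x, ...) {
  cat(sprintf("<neutromer_trace %s> %d neutroids, m/z %.4f, RT %.1f..%.1f s\n",
              x$trace_id, nrow(x$neutroids), trace_mz(x),
              min(x$neutroids$rt), max(x$neutroids$rt)))
  invisible(x)
}

#' Summary coordinates of a neutromer trace
#'
#' `trace_mz()` is the intensity-weighted mean m/z of the member neutroids;
#' `trace_intensity()` their summed intensity; `trace_rt_span()` the closed
#' RT interval covered; `trace_apex_rt()` the RT of the most intense
#' neutroid (earliest scan on ties).
#'
#' @param trace A `neutromer_trace`.
#' @return A numeric scalar (length-2 vector for `trace_rt_span`).
#' @export
trace_mz <- function(trace) {
  nd <- trace$neutroids
  tot <- sum(nd$intensity)
  if (tot == 0) return(mean(nd$mz))
  sum(nd$mz * nd$intensity) / tot
}

#' @rdname trace_mz
#' @export
trace_intensity <- function(trace) sum(trace$neutroids$intensity)

#' @rdname trace_mz
#' @export
trace_rt_span <- function(trace) range(trace$neutroids$rt)

#' @rdname trace_mz
#' @export
trace_apex_rt <- function(trace) {
  nd <- trace$neutroids
  nd$rt[which.max(nd$intensity)]
}

#' Construct a chargite trace
#'
#' The isotope-grouped signal of one molecule at one charge state: neutromer
#' traces spaced (isotope spacing)/z apart in m/z, ordered by isotope index
#' k = 0, 1, 2, ...
#'
#' @param z Charge state (positive integer; 0 means undetermined).
#' @param traces List of `neutromer_trace` in ascending isotope order.
#' @param monoisotopic_mz m/z of the k = 0 trace (Th).
#' @param chargite_id Opaque identifier.
#' @return An object of class `chargite_trace`.
#' @export
chargite_trace <- function(z, traces, monoisotopic_mz, chargite_id = "C") {
  stopifnot(length(traces) >= 1, z >= 0)
  structure(list(z = as.integer(z), traces = traces,
                 monoisotopic_mz = as.numeric(monoisotopic_mz),
                 chargite_id = as.character(chargite_id)),
            class = "chargite_trace")
}

#' @export
print.chargite_trace <- function(x, ...) {
  cat(sprintf("<chargite_trace %s> z=%d, %d neutromer traces, mono m/z %.4f\n",
              x$chargite_id, x$z, length(x$traces), x$monoisotopic_mz))
  invisible(x)
}

#' Construct a molecular distribution trace
#'
#' The set of chargite traces generated by one molecule across its observed
#' charge states, with a consensus neutral mass.
#'
#' @param chargites List of `chargite_trace` with distinct z.
#' @param neutral_mass Consensus neutral mass (Da).
#' @param molecule_id Opaque identifier.
#' @return An object of class `molecular_distribution_trace`.
#' @export
molecular_distribution_trace <- function(chargites, neutral_mass,
                                         molecule_id = "M") {
  stopifnot(length(chargites) >= 1)
  zs <- vapply(chargites, function(c) c$z, integer(1))
  if (anyDuplicated(zs[zs > 0])) stop("member chargites must have distinct z")
  structure(list(chargites = chargites, neutral_mass = as.numeric(neutral_mass),
                 molecule_id = as.character(molecule_id)),
            class = "molecular_distribution_trace")
}

#' @export
print.molecular_distribution_trace <- function(x, ...) {
  zs <- vapply(x$chargites, function(c) c$z, integer(1))
  cat(sprintf("<molecular_distribution_trace %s> M = %.6f Da, z = {%s}\n",
              x$molecule_id, x$neutral_mass, paste(sort(zs), collapse = ",")))
  invisible(x)
}

# ---- projected entities ----------------------------------------------------

.rt_qualifiers <- c("integrated", "max", "average", "instantaneous")
.mz_qualifiers <- c("deisotoped", "reduced")
.form_qualifiers <- c("distribution", "hull")

projected_entities <- function(df, entity_kind, tags, source_id) {
  df$entity_kind <- entity_kind
  df$provenance <- paste(tags, collapse = "+")
  df$source_id <- source_id
  class(df) <- c("projected_entities", "data.frame")
  df
}

append_tags <- function(existing, new) {
  tags <- c(existing, new)
  if (anyDuplicated(tags)) stop("qualifier tags may appear at most once each")
  if (sum(tags %in% .rt_qualifiers) > 1)
    stop("at most one RT qualifier (integrated/max/average/instantaneous) may apply")
  tags
}

split_tags <- function(provenance) {
  if (length(provenance) == 0 || !nzchar(provenance)) character(0)
  else strsplit(provenance, "+", fixed = TRUE)[[1]]
}

# ---- RT projection ---------------------------------------------------------

#' Project an RT-extended entity through the retention-time dimension
#'
#' The four RT qualifier operators. `integrated` sums member intensities
#' (m/z and RT become intensity-weighted means); `max` takes the member
#' tuple of greatest intensity (earliest scan on ties); `average` takes the
#' arithmetic mean of member intensities (coordinates as for `integrated`);
#' `instantaneous` slices the trace at one member scan's RT.
#'
#' For a chargite trace the operator is applied to each constituent
#' neutromer trace and the rows are returned in isotope order.
#'
#' @param entity A `neutromer_trace` or `chargite_trace`.
#' @param mode One of `"integrated"`, `"max"`, `"average"`, `"instantaneous"`.
#' @param rt Required for `mode = "instantaneous"`: the RT (seconds) of a
#'   member scan.
#' @return A `projected_entities` data frame with columns `mz`, `rt`,
#'   `intensity`, `scan_index`, `isotope_index`, `entity_kind`,
#'   `provenance`, `source_id`. One row per neutromer trace.
#' @examples
#' tr <- neutromer_trace(data.frame(
#'   scan_index = 0:2, rt = c(10, 11, 12), mz = 500, intensity = c(2, 5, 3)))
#' project_rt(tr, "integrated")   # intensity 10, rt 11.1
#' project_rt(tr, "max")          # the (500, 11, 5) tuple
#' @export
project_rt <- function(entity, mode = c("integrated", "max", "average",
                                        "instantaneous"), rt = NULL) {
  mode <- match.arg(mode)
  UseMethod("project_rt")
}

#' @export
project_rt.neutromer_trace <- function(entity, mode = c("integrated", "max",
                                                        "average",
                                                        "instantaneous"),
                                       rt = NULL) {
  mode <- match.arg(mode)
  row <- .project_rows(entity$neutroids, mode, rt)
  row$isotope_index <- NA_integer_
  projected_entities(row, "neutromer_trace", mode, entity$trace_id)
}

#' @export
project_rt.chargite_trace <- function(entity, mode = c("integrated", "max",
                                                       "average",
                                                       "instantaneous"),
                                      rt = NULL) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(entity$traces), function(k) {
    row <- .project_rows(entity$traces[[k]]$neutroids, mode, rt)
    row$isotope_index <- k - 1L
    row
  })
  projected_entities(do.call(rbind, rows), "chargite_trace", mode,
                     entity$chargite_id)
}

.project_rows <- function(nd, mode, rt) {
  if (nrow(nd) == 0) stop("cannot project an empty entity")
  if (mode == "instantaneous") {
    if (is.null(rt)) stop("mode 'instantaneous' requires an rt")
    hit <- which(nd$rt == rt)
    if (length(hit) == 0) {
      nearest <- nd$rt[which.min(abs(nd$rt - rt))]
      stop(sprintf("no member scan at rt = %g s; nearest available rt is %g s",
                   rt, nearest))
    }
    i <- hit[1]
    return(data.frame(mz = nd$mz[i], rt = nd$rt[i], intensity = nd$intensity[i],
                      scan_index = nd$scan_index[i]))
  }
  if (mode == "max") {
    i <- which.max(nd$intensity)  # which.max returns the first (earliest scan)
    return(data.frame(mz = nd$mz[i], rt = nd$rt[i], intensity = nd$intensity[i],
                      scan_index = nd$scan_index[i]))
  }
  tot <- sum(nd$intensity)
  wmz <- if (tot > 0) sum(nd$mz * nd$intensity) / tot else mean(nd$mz)
  wrt <- if (tot > 0) sum(nd$rt * nd$intensity) / tot else mean(nd$rt)
  val <- if (mode == "integrated") tot else tot / nrow(nd)
  data.frame(mz = wmz, rt = wrt, intensity = val, scan_index = NA_integer_)
}

# ---- nomenclature lexicon --------------------------------------------------

.base_nouns <- c(
  neutromer_trace = "neutromer trace",
  neutromer_hull = "neutromer hull",
  chargite_trace = "chargite distribution trace",
  chargite_hull = "chargite distribution hull",
  molecular_distribution_trace = "molecular distribution trace",
  molecular_distribution_hull = "molecular distribution hull",
  neutroid = "neutroid")

#' Validate a qualifier chain against the nomenclature lexicon
#'
#' Checks that a sequence of qualifier tags applied to an entity kind forms
#' a licensed term: each tag at most once, at most one RT qualifier,
#' `deisotoped` only on chargite or molecular scope, `reduced` only on
#' molecular scope, and `distribution`/`hull` mutually exclusive.
#'
#' @param entity_kind One of `"neutromer_trace"`, `"neutromer_hull"`,
#'   `"chargite_trace"`, `"chargite_hull"`,
#'   `"molecular_distribution_trace"`, `"molecular_distribution_hull"`,
#'   `"neutroid"`.
#' @param tags Character vector of qualifier tags in application order.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_provenance <- function(entity_kind, tags) {
  if (!entity_kind %in% names(.base_nouns))
    stop("unknown entity kind: ", entity_kind)
  known <- c(.rt_qualifiers, .mz_qualifiers, .form_qualifiers)
  bad <- setdiff(tags, known)
  if (length(bad) > 0) stop("unknown qualifier tag(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(tags)) stop("qualifier tags may appear at most once each")
  if (sum(tags %in% .rt_qualifiers) > 1)
    stop("at most one RT qualifier may apply")
  if (all(c("distribution", "hull") %in% tags))
    stop("'distribution' and 'hull' are mutually exclusive")
  scope <- sub("_(trace|hull)$", "", entity_kind)
  if ("deisotoped" %in% tags &&
      !scope %in% c("chargite", "molecular_distribution"))
    stop("'deisotoped' applies only to chargite or molecular scope")
  if ("reduced" %in% tags && scope != "molecular_distribution")
    stop("'reduced' applies only to molecular scope")
  invisible(TRUE)
}

#' Render a qualifier chain as a nomenclature term
#'
#' The human-readable name encodes the reduction chain with the most recent
#' operation outermost (leftmost), so the term round-trips exactly to the
#' application-ordered tag list via [parse_provenance()].
#'
#' @inheritParams validate_provenance
#' @return A character scalar, e.g. `"integrated deisotoped chargite
#'   distribution trace"`.
#' @export
provenance_label <- function(entity_kind, tags = character(0)) {
  validate_provenance(entity_kind, tags)
  paste(c(rev(tags), .base_nouns[[entity_kind]]), collapse = " ")
}

#' Parse a nomenclature term back into entity kind and qualifier tags
#'
#' Inverse of [provenance_label()].
#'
#' @param label A nomenclature term string.
#' @return List with elements `entity_kind` and `tags` (application order).
#' @export
parse_provenance <- function(label) {
  for (kind in names(.base_nouns)) {
    noun <- .base_nouns[[kind]]
    if (endsWith(label, noun)) {
      head_part <- trimws(substr(label, 1, nchar(label) - nchar(noun)))
      tags <- if (nzchar(head_part)) rev(strsplit(head_part, " +")[[1]])
              else character(0)
      validate_provenance(kind, tags)
      return(list(entity_kind = kind, tags = tags))
    }
  }
  stop("no base term of the lexicon matches: ", label)
}
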