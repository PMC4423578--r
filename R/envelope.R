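# Isotopic-envelope grouping: neutromer traces -> chargite traces ->
# molecular distribution traces, and the m/z-dimension qualifier operators
# (deisotoped, reduced).

#' Envelope grouping configuration
#'
#' @param isotope_spacing Mass difference between adjacent isotopic species
#'   (Da). Defaults to 1.003355 (13C - 12C); set to 1.0 to reproduce the
#'   idealized "m/z 1/z apart" convention.
#' @param charge_range Inclusive integer interval of candidate charge
#'   states, as `c(lo, hi)` (default 1-5).
#' @param grouping_ppm_tol Tolerance (ppm) between an observed trace m/z and
#'   the predicted isotope position (default 10).
#' @param rt_overlap_min Minimum RT-span overlap fraction, measured as
#'   |intersection| / |shorter span|, for two signals to be considered
#'   co-eluting (default 0.5).
#' @param proton_mass Proton mass in Da (default 1.007276466812).
#' @param molecule_mass_tol_ppm Tolerance (ppm) between implied neutral
#'   masses for chargites to merge into one molecule (default 10).
#' @return An object of class `envelope_config`.
#' @export
envelope_config <- function(isotope_spacing = 1.003355,
                            charge_range = c(1L, 5L),
                            grouping_ppm_tol = 10,
                            rt_overlap_min = 0.5,
                            proton_mass = 1.007276466812,
                            molecule_mass_tol_ppm = 10) {
  if (isotope_spacing <= 0) stop("isotope_spacing must be positive")
  if (length(charge_range) != 2 || charge_range[1] > charge_range[2] ||
      charge_range[1] < 1)
    stop("charge_range must be a non-empty positive interval c(lo, hi)")
  if (rt_overlap_min <= 0 || rt_overlap_min > 1)
    stop("rt_overlap_min must be in (0, 1]")
  structure(list(isotope_spacing = isotope_spacing,
                 charge_range = as.integer(charge_range),
                 grouping_ppm_tol = grouping_ppm_tol,
                 rt_overlap_min = rt_overlap_min,
                 proton_mass = proton_mass,
                 molecule_mass_tol_ppm = molecule_mass_tol_ppm),
            class = "envelope_config")
}

# overlap fraction of two closed RT spans, relative to the shorter span;
# a zero-length span counts as fully overlapping when its point lies inside
# the other span
.rt_overlap <- function(a, b) {
  inter <- min(a[2], b[2]) - max(a[1], b[1])
  shorter <- min(a[2] - a[1], b[2] - b[1])
  if (shorter <= 0) return(if (inter >= 0) 1 else 0)
  max(inter, 0) / shorter
}

#' Group neutromer traces into chargite traces
#'
#' Greedy envelope assembly. The unassigned trace of greatest integrated
#' intensity seeds a candidate envelope; for each charge z in `charge_range`
#' neighbors are sought at the seed m/z plus/minus k * isotope_spacing / z
#' (k = 1, 2, ... outward in both directions, stopping at the first gap)
#' within `grouping_ppm_tol` and with RT overlap at least `rt_overlap_min`.
#' The z collecting the most members wins (ties go to the larger z), the
#' members are marked assigned, and the process repeats. Traces that attract
#' no neighbors at any z become singleton chargites with z = 0
#' (undetermined).
#'
#' @param traces List of [neutromer_trace()] (culled and split).
#' @param config An [envelope_config()].
#' @return List of [chargite_trace()] objects.
#' @export
group_chargites <- function(traces, config = envelope_config()) {
  n <- length(traces)
  if (n == 0) return(list())
  mzs <- vapply(traces, trace_mz, numeric(1))
  ints <- vapply(traces, trace_intensity, numeric(1))
  spans <- lapply(traces, trace_rt_span)

  assigned <- logical(n)
  out <- list()
  cid <- 0L
  repeat {
    pool <- which(!assigned)
    if (length(pool) == 0) break
    seed <- pool[order(-ints[pool], mzs[pool])][1]
    best_members <- seed
    best_z <- 0L
    for (z in seq(config$charge_range[1], config$charge_range[2])) {
      members <- seed
      for (dir in c(1, -1)) {
        k <- 1L
        repeat {
          expected <- mzs[seed] + dir * k * config$isotope_spacing / z
          cand <- setdiff(which(!assigned), members)
          if (length(cand) == 0) break
          off <- ppm_diff(mzs[cand], expected)
          ok <- off <= config$grouping_ppm_tol &
            vapply(cand, function(i) .rt_overlap(spans[[seed]], spans[[i]]),
                   numeric(1)) >= config$rt_overlap_min
          if (!any(ok)) break
          hit <- cand[ok][which.min(off[ok])]
          members <- c(members, hit)
          k <- k + 1L
        }
      }
      if (length(members) > length(best_members) ||
          (length(members) == length(best_members) && length(members) > 1)) {
        best_members <- members   # ascending z loop: ties resolve to larger z
        best_z <- z
      }
    }
    if (length(best_members) == 1) best_z <- 0L
    assigned[best_members] <- TRUE
    ord <- best_members[order(mzs[best_members])]
    cid <- cid + 1L
    out[[cid]] <- chargite_trace(
      z = best_z, traces = traces[ord], monoisotopic_mz = mzs[ord[1]],
      chargite_id = sprintf("C%04d", cid))
  }
  out
}

#' Sum a chargite's intensities through the m/z (isotope) dimension
#'
#' Per scan, the intensities of all member neutroids are summed into one
#' tuple anchored at the monoisotopic m/z. The result carries the
#' `deisotoped` qualifier; an RT qualifier can be applied in the same call
#' via `rt_mode` (e.g. a deisotoped, integrated chargite distribution).
#'
#' @param chargite A [chargite_trace()].
#' @param rt_mode Optional RT qualifier (`"integrated"`, `"max"`,
#'   `"average"`, `"instantaneous"`) applied after deisotoping.
#' @param rt RT for `rt_mode = "instantaneous"`.
#' @return A `projected_entities` data frame: one row per scan, or a single
#'   row when `rt_mode` is given.
#' @export
deisotope <- function(chargite, rt_mode = NULL, rt = NULL) {
  stopifnot(inherits(chargite, "chargite_trace"))
  if (length(chargite$traces) == 0) stop("cannot deisotope an empty chargite")
  all_nd <- do.call(rbind, lapply(chargite$traces, function(t) t$neutroids))
  agg <- aggregate(intensity ~ scan_index + rt, data = all_nd, FUN = sum)
  agg <- agg[order(agg$scan_index), , drop = FALSE]
  df <- data.frame(mz = chargite$monoisotopic_mz, rt = agg$rt,
                   intensity = agg$intensity, scan_index = agg$scan_index,
                   isotope_index = NA_integer_)
  tags <- "deisotoped"
  if (!is.null(rt_mode)) {
    row <- .project_rows(df, rt_mode, rt)
    row$mz <- chargite$monoisotopic_mz  # coordinate stays the monoisotopic anchor
    row$isotope_index <- NA_integer_
    df <- row
    tags <- append_tags(tags, rt_mode)
  }
  projected_entities(df, "chargite_trace", tags, chargite$chargite_id)
}

#' Group chargite traces into molecular distribution traces
#'
#' Each chargite with determined charge implies a neutral mass
#' M = z * (monoisotopic m/z - proton mass). Chargites whose implied masses
#' agree within `molecule_mass_tol_ppm` and whose RT spans overlap by at
#' least `rt_overlap_min` merge into one molecular distribution trace; the
#' consensus neutral mass is the intensity-weighted mean of the members'
#' implied masses. Seeding is greedy by total intensity. Chargites with
#' z = 0 are skipped.
#'
#' @param chargites List of [chargite_trace()].
#' @param config An [envelope_config()].
#' @return List of [molecular_distribution_trace()] objects.
#' @export
group_molecules <- function(chargites, config = envelope_config()) {
  chargites <- Filter(function(c) c$z >= 1, chargites)
  n <- length(chargites)
  if (n == 0) return(list())
  mass <- vapply(chargites, function(c)
    c$z * (c$monoisotopic_mz - config$proton_mass), numeric(1))
  ints <- vapply(chargites, function(c)
    sum(vapply(c$traces, trace_intensity, numeric(1))), numeric(1))
  spans <- lapply(chargites, function(c) {
    rng <- vapply(c$traces, trace_rt_span, numeric(2))
    c(min(rng[1, ]), max(rng[2, ]))
  })
  assigned <- logical(n)
  out <- list()
  mid <- 0L
  repeat {
    pool <- which(!assigned)
    if (length(pool) == 0) break
    seed <- pool[order(-ints[pool], mass[pool])][1]
    members <- seed
    for (i in setdiff(pool, seed)) {
      if (ppm_diff(mass[i], mass[seed]) > config$molecule_mass_tol_ppm) next
      if (.rt_overlap(spans[[seed]], spans[[i]]) < config$rt_overlap_min) next
      zi <- chargites[[i]]$z
      prev <- which(vapply(members, function(m) chargites[[m]]$z == zi,
                           logical(1)))
      if (length(prev) > 0) {
        # one chargite per charge state: keep the closer implied mass
        if (ppm_diff(mass[i], mass[seed]) <
            ppm_diff(mass[members[prev]], mass[seed]))
          members[prev] <- i
      } else {
        members <- c(members, i)
      }
    }
    assigned[members] <- TRUE
    consensus <- sum(mass[members] * ints[members]) / sum(ints[members])
    mid <- mid + 1L
    out[[mid]] <- molecular_distribution_trace(
      chargites[members][order(vapply(chargites[members], `[[`, integer(1),
                                      "z"))],
      neutral_mass = consensus, molecule_id = sprintf("M%04d", mid))
  }
  out
}

#' Reduce a molecular distribution trace to its lowest common charge state
#'
#' Each member chargite is deisotoped and its per-scan tuples re-coordinated
#' to the m/z the molecule would have at the target charge
#' z* = min member z, i.e. m/z' = (M + z* * proton_mass) / z*; intensities
#' are summed per scan across chargites. The result carries the
#' `deisotoped` and `reduced` qualifiers.
#'
#' @param molecule A [molecular_distribution_trace()].
#' @param config An [envelope_config()].
#' @param z_target Optional target charge state; defaults to the lowest
#'   member charge.
#' @return A `projected_entities` data frame, one row per scan.
#' @export
reduce_molecule <- function(molecule, config = envelope_config(),
                            z_target = NULL) {
  zs <- vapply(molecule$chargites, `[[`, integer(1), "z")
  if (any(zs == 0)) stop("cannot reduce: a member chargite has undetermined charge")
  z_star <- if (!is.null(z_target)) as.integer(z_target) else min(zs)
  if (z_star < 1) stop("z_target must be a positive integer")
  mz_prime <- (molecule$neutral_mass + z_star * config$proton_mass) / z_star
  per <- lapply(molecule$chargites, function(ch) {
    d <- deisotope(ch)
    d[, c("scan_index", "rt", "intensity")]
  })
  all_rows <- do.call(rbind, per)
  agg <- aggregate(intensity ~ scan_index + rt, data = all_rows, FUN = sum)
  agg <- agg[order(agg$scan_index), , drop = FALSE]
  df <- data.frame(mz = mz_prime, rt = agg$rt, intensity = agg$intensity,
                   scan_index = agg$scan_index, isotope_index = NA_integer_)
  projected_entities(df, "molecular_distribution_trace",
                     c("deisotoped", "reduced"), molecule$molecule_id)
}
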