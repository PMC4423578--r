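# Profile-mode MS1 run simulator with ground truth, so every pipeline stage
# is testable without external data: per-molecule isotopic envelopes at one
# or more charge states, Gaussian chromatographic elution, Gaussian m/z peak
# shapes, additive baseline and optional counting (Poisson) noise.

#' Specify a simulated molecule
#'
#' @param neutral_mass Monoisotopic neutral mass (Da).
#' @param charges Integer vector of charge states at which the molecule is
#'   observed.
#' @param elution_apex Chromatographic apex (seconds).
#' @param elution_sigma Gaussian elution width (seconds).
#' @param peak_height Apex intensity of the most abundant isotope (counts).
#' @param isotope_abundances Optional relative-abundance vector for isotopes
#'   k = 0, 1, ... with max 1; when absent a Poisson envelope model is used
#'   (see [isotope_distribution()]).
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(neutral_mass, charges = 1L, elution_apex,
                          elution_sigma, peak_height,
                          isotope_abundances = NULL) {
  if (neutral_mass <= 0) stop("neutral_mass must be positive")
  if (elution_sigma <= 0) stop("elution_sigma must be positive")
  if (any(charges < 1)) stop("charges must be positive integers")
  if (!is.null(isotope_abundances)) {
    if (any(isotope_abundances <= 0) || any(isotope_abundances > 1))
      stop("isotope_abundances must lie in (0, 1]")
  }
  structure(list(neutral_mass = neutral_mass, charges = as.integer(charges),
                 elution_apex = elution_apex, elution_sigma = elution_sigma,
                 peak_height = peak_height,
                 isotope_abundances = isotope_abundances),
            class = "molecule_spec")
}

#' Simulation configuration
#'
#' @param molecules List of [molecule_spec()].
#' @param rt_range Run RT interval `c(start, end)` in seconds.
#' @param scan_interval Time between scans (seconds).
#' @param mz_range Acquisition m/z window `c(lo, hi)` (Th).
#' @param resolving_power FWHM-based resolving power R; the m/z peak width
#'   is FWHM = mz / R (default 60000).
#' @param baseline_level Additive baseline (counts) on emitted points
#'   (default 0).
#' @param noise_model `"none"` or `"poisson"` (counting noise on every
#'   emitted point).
#' @param seed Integer seed for the noise generator.
#' @param isotope_lambda_per_kda Poisson envelope rate per kDa of neutral
#'   mass, used when a molecule gives no explicit abundances (default 0.6).
#' @param isotope_spacing Isotopic mass spacing (Da, default 1.003355).
#' @param proton_mass Proton mass (Da).
#' @param elution_window_sigmas Elution profiles are evaluated within this
#'   many sigmas of the apex (default 4).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(molecules, rt_range = c(0, 300),
                              scan_interval = 1, mz_range = c(200, 2000),
                              resolving_power = 60000, baseline_level = 0,
                              noise_model = c("none", "poisson"), seed = 1L,
                              isotope_lambda_per_kda = 0.6,
                              isotope_spacing = 1.003355,
                              proton_mass = 1.007276466812,
                              elution_window_sigmas = 4) {
  if (scan_interval <= 0) stop("scan_interval must be positive")
  if (resolving_power <= 0) stop("resolving_power must be positive")
  structure(list(molecules = molecules, rt_range = rt_range,
                 scan_interval = scan_interval, mz_range = mz_range,
                 resolving_power = resolving_power,
                 baseline_level = baseline_level,
                 noise_model = match.arg(noise_model), seed = as.integer(seed),
                 isotope_lambda_per_kda = isotope_lambda_per_kda,
                 isotope_spacing = isotope_spacing, proton_mass = proton_mass,
                 elution_window_sigmas = elution_window_sigmas),
            class = "simulation_config")
}

#' Isotopic-envelope abundance model
#'
#' Explicit abundances are passed through unchanged. Otherwise a Poisson
#' envelope with rate lambda = `isotope_lambda_per_kda` * mass / 1000 is
#' used: abundances proportional to the Poisson pmf over isotope index k,
#' truncated where the pmf falls below 1e-3 of its maximum and normalized so
#' the most abundant isotope is 1. This coarse single-rate model stands in
#' for elemental fine structure; isotopic fine structure (isoneutromers) is
#' deliberately collapsed into a single m/z per neutromer.
#'
#' @param neutral_mass Neutral mass (Da).
#' @param abundances Optional explicit abundance vector (max 1).
#' @param lambda_per_kda Poisson rate per kDa (default 0.6).
#' @return Numeric abundance vector, max element 1.
#' @export
isotope_distribution <- function(neutral_mass, abundances = NULL,
                                 lambda_per_kda = 0.6) {
  if (neutral_mass <= 0) stop("neutral_mass must be positive")
  if (!is.null(abundances)) return(abundances)
  lambda <- lambda_per_kda * neutral_mass / 1000
  if (lambda == 0) return(1)
  kmax <- max(1, stats::qpois(1 - 1e-9, lambda))
  pmf <- stats::dpois(0:kmax, lambda)
  pmf <- pmf[seq_len(max(which(pmf >= 1e-3 * max(pmf))))]
  pmf / max(pmf)
}

#' Simulate a profile-mode MS1 run with ground truth
#'
#' For every molecule, charge and isotope, a Gaussian elution profile (apex,
#' sigma, height scaled by isotope abundance) is sampled at the scan times,
#' and within each scan a Gaussian m/z peak centered at the theoretical
#' m/z = (M + k * spacing + z * proton) / z with sigma = mz / (R * 2.3548)
#' is sampled on the run's uniform m/z grid (grid step = minimum FWHM / 4,
#' at least 4 points per peak). Contributions are summed, baseline is added
#' to emitted points, and Poisson noise is applied if configured. Emitted
#' scans contain only points in the neighborhood of simulated signal, with a
#' zero-intensity grid point flanking each contiguous segment so that peak
#' boundaries are explicit.
#'
#' @param config A [simulation_config()].
#' @return List with `run` (a [raw_run()]) and `truth` (the ground-truth
#'   `data.frame`: `molecule_id`, `z`, `isotope_index`, `mz`, `elution_apex`,
#'   `total_intensity`, one row per simulated neutromer trace;
#'   `total_intensity` is the summed emitted signal of the trace before
#'   baseline and noise).
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  scan_times <- seq(config$rt_range[1], config$rt_range[2],
                    by = config$scan_interval)
  step <- (config$mz_range[1] / config$resolving_power) / 4
  mz_lo <- config$mz_range[1]
  fwhm_factor <- 2 * sqrt(2 * log(2))   # 2.3548: FWHM = fwhm_factor * sigma

  # per-scan accumulators of (grid index, intensity)
  acc_idx <- vector("list", length(scan_times))
  acc_val <- vector("list", length(scan_times))
  truth <- list()

  offenders <- character(0)
  for (mi in seq_along(config$molecules)) {
    mol <- config$molecules[[mi]]
    ab <- isotope_distribution(mol$neutral_mass, mol$isotope_abundances,
                               config$isotope_lambda_per_kda)
    for (z in mol$charges) {
      for (k in seq_along(ab) - 1L) {
        mz0 <- (mol$neutral_mass + k * config$isotope_spacing +
                  z * config$proton_mass) / z
        if (mz0 < config$mz_range[1] || mz0 > config$mz_range[2]) {
          offenders <- c(offenders, sprintf(
            "molecule %d z=%d k=%d at m/z %.4f", mi, z, k, mz0))
          next
        }
        sig_mz <- mz0 / (config$resolving_power * fwhm_factor)
        gi <- seq(max(0L, ceiling((mz0 - 5 * sig_mz - mz_lo) / step)),
                  floor((mz0 + 5 * sig_mz - mz_lo) / step))
        gmz <- mz_lo + gi * step
        shape <- exp(-(gmz - mz0)^2 / (2 * sig_mz^2))
        in_win <- abs(scan_times - mol$elution_apex) <=
          config$elution_window_sigmas * mol$elution_sigma
        total <- 0
        for (si in which(in_win)) {
          amp <- mol$peak_height * ab[k + 1L] *
            exp(-(scan_times[si] - mol$elution_apex)^2 /
                  (2 * mol$elution_sigma^2))
          vals <- amp * shape
          acc_idx[[si]] <- c(acc_idx[[si]], gi)
          acc_val[[si]] <- c(acc_val[[si]], vals)
          total <- total + sum(vals)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          molecule_id = sprintf("SIM%03d", mi), z = z, isotope_index = k,
          mz = mz0, elution_apex = mol$elution_apex, total_intensity = total)
      }
    }
  }
  if (length(offenders) > 0)
    stop("simulated signals fall outside mz_range: ",
         paste(offenders, collapse = "; "))

  if (config$noise_model == "poisson") set.seed(config$seed)
  scans <- list()
  out_i <- 0L
  for (si in seq_along(scan_times)) {
    if (length(acc_idx[[si]]) == 0) {
      scans[[si]] <- ms_scan(si - 1L, scan_times[si], numeric(0), numeric(0))
      next
    }
    v <- tapply(acc_val[[si]], acc_idx[[si]], sum)
    gi <- as.integer(names(v))
    o <- order(gi)
    gi <- gi[o]; v <- as.numeric(v)[o]
    # flank each contiguous grid segment with an explicit zero point
    brk <- which(diff(gi) > 1L)
    starts <- gi[c(1L, brk + 1L)] - 1L
    ends <- gi[c(brk, length(gi))] + 1L
    flank <- setdiff(unique(c(starts, ends)), gi)
    flank <- flank[flank >= 0]
    gi <- c(gi, flank); v <- c(v, numeric(length(flank)))
    o <- order(gi)
    gi <- gi[o]; v <- v[o]
    v <- v + config$baseline_level
    if (config$noise_model == "poisson") v <- as.numeric(stats::rpois(length(v), v))
    keep <- rep(TRUE, length(v))
    scans[[si]] <- ms_scan(si - 1L, scan_times[si], mz_lo + gi[keep] * step,
                           v[keep])
  }
  truth <- if (length(truth) > 0)
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  else
    data.frame(molecule_id = character(0), z = integer(0),
               isotope_index = integer(0), mz = numeric(0),
               elution_apex = numeric(0), total_intensity = numeric(0))
  list(run = raw_run(scans, mode = "profile",
                     metadata = list(simulated = TRUE, seed = config$seed)),
       truth = truth)
}

#' Match detected traces against simulation ground truth
#'
#' Greedy nearest-m/z matching: candidate (truth row, detected trace) pairs
#' within `ppm_tol` in m/z and `rt_tol` in apex RT are assigned in ascending
#' ppm order, each truth row and each detection used at most once. Recall is
#' the matched fraction of truth rows; precision the matched fraction of
#' detections.
#'
#' @param traces List of detected [neutromer_trace()] objects.
#' @param truth Ground-truth `data.frame` from [simulate_run()].
#' @param ppm_tol m/z match tolerance in ppm (default 5).
#' @param rt_tol Apex RT match tolerance in seconds (default 10).
#' @return List of class `truth_match` with `report` (per truth row:
#'   `recovered`, `trace_id`, `mz_error_ppm`, `intensity_ratio`), `recall`,
#'   `precision`.
#' @export
truth_match <- function(traces, truth, ppm_tol = 5, rt_tol = 10) {
  nt <- nrow(truth)
  report <- data.frame(truth[, c("molecule_id", "z", "isotope_index", "mz")],
                       recovered = FALSE, trace_id = NA_character_,
                       mz_error_ppm = NA_real_, intensity_ratio = NA_real_)
  if (length(traces) > 0 && nt > 0) {
    dmz <- vapply(traces, trace_mz, numeric(1))
    drt <- vapply(traces, trace_apex_rt, numeric(1))
    dint <- vapply(traces, trace_intensity, numeric(1))
    cand <- expand.grid(t = seq_len(nt), d = seq_along(traces))
    cand$ppm <- ppm_diff(dmz[cand$d], truth$mz[cand$t])
    cand <- cand[cand$ppm <= ppm_tol &
                   abs(drt[cand$d] - truth$elution_apex[cand$t]) <= rt_tol, ,
                 drop = FALSE]
    cand <- cand[order(cand$ppm), , drop = FALSE]
    used_t <- logical(nt); used_d <- logical(length(traces))
    for (r in seq_len(nrow(cand))) {
      ti <- cand$t[r]; di <- cand$d[r]
      if (used_t[ti] || used_d[di]) next
      used_t[ti] <- TRUE; used_d[di] <- TRUE
      report$recovered[ti] <- TRUE
      report$trace_id[ti] <- traces[[di]]$trace_id
      report$mz_error_ppm[ti] <- (dmz[di] - truth$mz[ti]) / truth$mz[ti] * 1e6
      report$intensity_ratio[ti] <- dint[di] / truth$total_intensity[ti]
    }
  }
  matched <- sum(report$recovered)
  structure(list(report = report,
                 recall = if (nt > 0) matched / nt else NA_real_,
                 precision = if (length(traces) > 0)
                   matched / length(traces) else NA_real_),
            class = "truth_match")
}

#' @export
print.truth_match <- function(x, ...) {
  cat(sprintf("<truth_match> recall %.4f, precision %.4f (%d/%d truth rows)\n",
              x$recall, x$precision, sum(x$report$recovered),
              nrow(x$report)))
  invisible(x)
}
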