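# The package's reference validation scenario: a noise-free run whose
# ground truth the full pipeline must recover exactly.

#' Reference validation scenario
#'
#' A noise-free profile-mode run of `n_molecules` molecules with neutral
#' masses spread over 400-2000 Da (seeded jitter around an even grid),
#' each observed at charges 1 and 2 with three isotopes, Gaussian elution
#' apexes spaced 45 s apart (sigma 5 s) so that elution windows are
#' disjoint, at resolving power 60,000. Pairwise m/z gaps exceed 10 times
#' the instrument FWHM and RT gaps exceed 4 sigma, the regime in which
#' detection is expected to be exact.
#'
#' @param n_molecules Number of molecules (default 10).
#' @param seed Seed for the mass jitter and peak heights.
#' @return A [simulation_config()].
#' @export
reference_run_config <- function(n_molecules = 10, seed = 1L) {
  set.seed(seed)
  masses <- seq(410, 1850, length.out = n_molecules) +
    stats::runif(n_molecules, -5, 5)
  heights <- stats::runif(n_molecules, 5e4, 2e5)
  mols <- lapply(seq_len(n_molecules), function(i) {
    molecule_spec(neutral_mass = masses[i], charges = c(1L, 2L),
                  elution_apex = 50 + (i - 1) * 45, elution_sigma = 5,
                  peak_height = heights[i],
                  isotope_abundances = c(1, 0.55, 0.22))
  })
  simulation_config(molecules = mols,
                    rt_range = c(20, 50 + (n_molecules - 1) * 45 + 30),
                    scan_interval = 2, mz_range = c(150, 2100),
                    resolving_power = 60000, baseline_level = 0,
                    noise_model = "none", seed = as.integer(seed))
}
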