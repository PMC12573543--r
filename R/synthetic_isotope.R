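# Synthetic 15N2 microcosm measurements: the fixed-N mixing equation run in
# reverse, plus Gaussian measurement noise on the final atom%.

#' Generate synthetic isotope microcosm measurements with known rates
#'
#' For each design row with true fixation rate `r` (mg N per kg dry soil
#' per incubation), the post-incubation soil atom% is obtained by inverting
#' the isotope-mixing estimator:
#' `atom_final = atom_initial + r x (enrichment - atom_initial) / total_N`
#' (total N in mg kg-1), then adding Gaussian noise of SD `noise_sd`
#' (atom%). The default `noise_sd` of 0.001 atom% reflects the precision of
#' continuous-flow isotope-ratio mass spectrometry.
#'
#' @param design Data.frame of vials (one row each), e.g. from
#'   [generate_design()].
#' @param true_rates True fixation rates, length 1 or `nrow(design)`
#'   (mg-N kg-1 per incubation period); must be >= 0.
#' @param noise_sd Gaussian SD added to `atom_final` (atom%).
#' @param total_n_pct Soil total N (mass %), length 1 or `nrow(design)`.
#' @param atom_initial Baseline soil atom% 15N (default natural abundance).
#' @param spec A [microcosm_spec()]; supplies the headspace enrichment.
#' @param seed Integer RNG seed.
#' @return List with `measurements` (data.frame ready for
#'   [estimate_fixed_n()]) and `truth` (the per-vial true rates).
#' @export
#' @examples
#' d <- generate_design()
#' gen <- generate_isotope_dataset(d, true_rates = 7.42, noise_sd = 0)
#' estimate_fixed_n(gen$measurements)$fixed_n_mg_kg[1]  # 7.42
generate_isotope_dataset <- function(design, true_rates, noise_sd = 0.001,
                                     total_n_pct = 0.11,
                                     atom_initial = natural_15n_abundance(),
                                     spec = microcosm_spec(), seed = 1L) {
  n <- nrow(design)
  if (any(true_rates < 0)) .stop2("'true_rates' must be >= 0")
  .check_number(noise_sd, "noise_sd", 0)
  enrichment <- spec$headspace_atom_pct
  if (enrichment <= max(atom_initial))
    .stop2("headspace enrichment must exceed the baseline atom%")
  rates <- rep_len(true_rates, n)
  tn <- rep_len(total_n_pct, n)
  ai <- rep_len(atom_initial, n)
  set.seed(as.integer(seed))
  total_n_mg_kg <- tn / 100 * 1e6
  af <- ai + rates * (enrichment - ai) / total_n_mg_kg +
    stats::rnorm(n, 0, noise_sd)
  m <- data.frame(vial_id = sprintf("V%03d", seq_len(n)), design,
                  total_n_pct = tn, atom_initial = ai, atom_final = af,
                  enrichment = enrichment, stringsAsFactors = FALSE)
  m$vial_id <- make.unique(m$vial_id)
  list(measurements = m,
       truth = data.frame(vial_id = m$vial_id, true_rate = rates,
                          stringsAsFactors = FALSE))
}
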