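# 15N2 microcosm bookkeeping: nutrient loads of the farmyard-manure
# amendment, isotope-mixing estimation of biologically fixed N, and the
# experiment's group summaries.

#' Microcosm incubation constants
#'
#' The vial set-up of the aerobic 15N2 incubation: 2 g sieved air-dried
#' soil, 5 ml water, 8 mg farmyard manure (13% C, 0.98% N, 0.3% P) in the
#' +FYM treatment, headspace of 80% N2 at 25 atom% 15N plus 20% O2,
#' incubated 30 days at 25 degrees C.
#'
#' @param soil_mass_g Dry soil per vial (g).
#' @param water_ml Water per vial (ml).
#' @param fym_mass_mg FYM per vial (mg).
#' @param fym_composition Named mass fractions (`C`, `N`, `P`) of the FYM.
#' @param headspace_atom_pct Headspace 15N enrichment (atom% 15N).
#' @param n2_fraction Headspace N2 volume fraction.
#' @param incubation_days Incubation length (days).
#' @param temperature_c Incubation temperature (deg C).
#' @return A list of class `microcosm_spec`.
#' @export
microcosm_spec <- function(soil_mass_g = 2, water_ml = 5, fym_mass_mg = 8,
                           fym_composition = c(C = 0.13, N = 0.0098, P = 0.003),
                           headspace_atom_pct = 25, n2_fraction = 0.8,
                           incubation_days = 30, temperature_c = 25) {
  .check_number(soil_mass_g, "soil_mass_g", 1e-9)
  .check_number(fym_mass_mg, "fym_mass_mg", 0)
  .check_number(headspace_atom_pct, "headspace_atom_pct", 0, 100)
  if (any(fym_composition < 0) || any(fym_composition > 1))
    .stop2("'fym_composition' fractions must lie in [0, 1]")
  structure(list(soil_mass_g = soil_mass_g, water_ml = water_ml,
                 fym_mass_mg = fym_mass_mg, fym_composition = fym_composition,
                 headspace_atom_pct = headspace_atom_pct,
                 n2_fraction = n2_fraction,
                 incubation_days = incubation_days,
                 temperature_c = temperature_c),
            class = "microcosm_spec")
}

#' Natural 15N abundance (atom%)
#'
#' Default baseline when the pre-incubation soil atom% is not measured.
#' @return 0.3663 (atom% 15N).
#' @export
natural_15n_abundance <- function() 0.3663

#' Nutrient load delivered by the FYM amendment
#'
#' Element mass added per vial: `load = fym_mass x fraction`. With the
#' default 8 mg FYM at 13% C, 0.98% N and 0.3% P this is 1.04, 0.0784 and
#' 0.024 mg (printed at study precision: 1, 0.078 and 0.024 mg).
#'
#' @param fym_mass_mg FYM mass per vial (mg).
#' @param composition Named mass fractions, as in [microcosm_spec()].
#' @param digits Optional rounding of the report (default no rounding).
#' @return Named numeric vector (mg per vial) for each element.
#' @export
#' @examples
#' fym_nutrient_load()           # C 1.04, N 0.0784, P 0.024 mg per vial
#' fym_nutrient_load(digits = 2)
fym_nutrient_load <- function(fym_mass_mg = 8,
                              composition = c(C = 0.13, N = 0.0098, P = 0.003),
                              digits = NULL) {
  .check_number(fym_mass_mg, "fym_mass_mg", 0)
  if (any(composition < 0) || any(composition > 1))
    .stop2("composition fractions must lie in [0, 1]")
  out <- fym_mass_mg * composition
  if (!is.null(digits)) out <- signif(out, digits)
  out
}

#' Estimate biologically fixed N from 15N isotope mixing
#'
#' Two-pool mixing: newly fixed N entering the soil pool at the headspace
#' enrichment raises the soil atom% from its baseline, so
#' `fixed_N (mg kg-1) = total_N (mg kg-1) x
#'  (atom%_final - atom%_initial) / (atom%_headspace - atom%_initial)`.
#' Negative raw estimates (measurement noise below baseline) are clamped to
#' zero and flagged.
#'
#' @param measurements Data.frame with columns `vial_id`, `total_n_pct`
#'   (soil total N, mass %), `atom_initial` (atom% before incubation;
#'   if absent, [natural_15n_abundance()] is used), `atom_final` (atom%
#'   after incubation) and `enrichment` (headspace atom% 15N). Extra
#'   columns (design factors) are carried through.
#' @param baseline `"natural"` uses each row's `atom_initial` (or the
#'   natural-abundance default); `"control_vial"` subtracts the mean
#'   `atom_final` of rows flagged `control == TRUE` instead.
#' @return The input with `fixed_n_mg_kg` (mg N per kg dry soil per
#'   incubation period), `clamped` (logical) and a `units` attribute.
#' @export
estimate_fixed_n <- function(measurements, baseline = c("natural", "control_vial")) {
  baseline <- match.arg(baseline)
  m <- as.data.frame(measurements)
  need <- c("total_n_pct", "atom_final", "enrichment")
  miss <- setdiff(need, names(m))
  if (length(miss)) .stop2("measurements lack column(s): ",
                           paste(miss, collapse = ", "))
  if (!"atom_initial" %in% names(m)) m$atom_initial <- natural_15n_abundance()
  base <- switch(baseline,
    natural = m$atom_initial,
    control_vial = {
      if (!"control" %in% names(m) || !any(m$control))
        .stop2("baseline='control_vial' needs rows flagged control == TRUE")
      rep(mean(m$atom_final[m$control]), nrow(m))
    })
  if (any(m$enrichment <= base))
    .stop2("headspace enrichment must exceed the baseline atom%")
  total_n_mg_kg <- m$total_n_pct / 100 * 1e6
  raw <- total_n_mg_kg * (m$atom_final - base) / (m$enrichment - base)
  m$fixed_n_mg_kg <- pmax(raw, 0)
  m$clamped <- raw < 0
  attr(m, "units") <- "mg-N kg-1 dry soil per incubation period"
  attr(m, "baseline") <- baseline
  attr(m, "caveat") <- "no correction for headspace dilution by soil-emitted N gases"
  m
}

#' Group summaries of fixation estimates
#'
#' Cell means and standard errors over the factorial design, factor-level
#' means, and the study's headline ratio: within each field, the mean of
#' the enriched-soil `+FYM` cell relative to the mean of the remaining
#' cells of that field.
#'
#' @param results Output of [estimate_fixed_n()] joined with design factor
#'   columns (`field`, `soil_type`, `fym`).
#' @param factors Character vector of grouping columns (default
#'   `c("field","soil_type","fym")`).
#' @return List with `cells` (per-cell n, mean, se), `factor_means`
#'   (per-factor level means), and `fold_changes` (per field; `NA` with a
#'   flag when the comparison mean is zero).
#' @export
summarize_fixation <- function(results,
                               factors = c("field", "soil_type", "fym")) {
  r <- as.data.frame(results)
  miss <- setdiff(c(factors, "fixed_n_mg_kg"), names(r))
  if (length(miss)) .stop2("results lack column(s): ", paste(miss, collapse = ", "))

  key <- interaction(r[factors], drop = TRUE, lex.order = TRUE)
  cells <- do.call(rbind, lapply(split(r, key), function(g) {
    data.frame(g[1, factors, drop = FALSE], n = nrow(g),
               mean = mean(g$fixed_n_mg_kg),
               se = if (nrow(g) > 1) sd(g$fixed_n_mg_kg) / sqrt(nrow(g)) else 0,
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  factor_means <- lapply(setNames(factors, factors), function(f) {
    vapply(split(r$fixed_n_mg_kg, r[[f]]), mean, numeric(1))
  })

  fold_changes <- NULL
  if (all(c("field", "soil_type", "fym") %in% names(r))) {
    fold_changes <- do.call(rbind, lapply(split(r, r$field), function(g) {
      top <- g$soil_type == "enriched" & g$fym == "+FYM"
      if (!any(top) || all(top)) return(NULL)
      num <- mean(g$fixed_n_mg_kg[top])
      den <- mean(g$fixed_n_mg_kg[!top])
      data.frame(field = g$field[1], target_mean = num, others_mean = den,
                 fold_change = if (den > 0) num / den else NA_real_,
                 undefined = den <= 0, stringsAsFactors = FALSE,
                 row.names = NULL)
    }))
  }
  list(cells = cells, factor_means = factor_means, fold_changes = fold_changes)
}
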