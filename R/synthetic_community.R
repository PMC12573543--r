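# Factorial treatment designs and Dirichlet-multinomial community count
# tables with a planted fertiliser effect.

#' Build a complete factorial treatment design
#'
#' Crosses the requested factor levels into a balanced, complete design with
#' a uniform replicate count, mirroring the microcosm (field x soil x FYM)
#' and rhizosphere (FYM x mineral fertiliser) layouts with n = 3.
#'
#' @param fields Field identifiers (default `F1`--`F3`).
#' @param soil_types Soil history levels (default `poor`, `enriched`).
#' @param fym FYM incubation levels (default `-FYM`, `+FYM`).
#' @param mineral Mineral-fertiliser levels, or `NULL` to omit the factor
#'   (default `NULL`; the rhizosphere design uses
#'   `c("control","N","P","NP")`).
#' @param replicates Replicates per cell (default 3).
#' @return A data.frame with one row per sample: `sample_id`, the factor
#'   columns, and `replicate`.
#' @export
#' @examples
#' nrow(generate_design())  # 3 fields x 2 soils x 2 FYM x 3 reps = 36
generate_design <- function(fields = c("F1", "F2", "F3"),
                            soil_types = c("poor", "enriched"),
                            fym = c("-FYM", "+FYM"),
                            mineral = NULL,
                            replicates = 3L) {
  .check_number(replicates, "replicates", 1)
  cols <- list(field = fields, soil_type = soil_types, fym = fym)
  if (!is.null(mineral)) cols$mineral <- mineral
  cols$replicate <- seq_len(replicates)
  d <- expand.grid(cols, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d <- d[, c(setdiff(names(d), "replicate"), "replicate")]
  d <- data.frame(sample_id = sprintf("S%03d", seq_len(nrow(d))), d,
                  stringsAsFactors = FALSE)
  d
}

#' Baseline family-level profile of a paddy-soil diazotroph community
#'
#' Expected relative abundances used as the generator's default base
#' profile. The shape mirrors the rhizosphere nifH profiles of iron-rich
#' paddy soil: Geobacteraceae most abundant (~20%), Gallionellaceae (the
#' FYM-responsive family, ~5% before perturbation), several
#' Pseudomonadota families at a few percent each, and a pooled remainder.
#'
#' @return Named numeric vector of proportions summing to 1.
#' @export
paddy_family_profile <- function() {
  p <- c(Geobacteraceae = 0.20, Gallionellaceae = 0.05,
         Beijerinckiaceae = 0.08, Burkholderiaceae = 0.07,
         Xanthobacteraceae = 0.07, Methylococcaceae = 0.04,
         Desulfovibrionaceae = 0.10, other = 0.39)
  p / sum(p)
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a Dirichlet-multinomial abundance table with a planted effect
#'
#' Draws per-sample taxon counts from a Dirichlet-multinomial model: each
#' sample's taxon proportions are a Dirichlet draw around a base profile
#' (concentration `1/dispersion`; `dispersion -> 0` recovers the exact
#' multinomial), and counts are a multinomial draw of size `depth`. In
#' `+FYM` samples the base-profile entry of `effect_taxon` is multiplied by
#' `fold_change` and the profile renormalised, planting a known
#' organic-amendment response (the study's motif: one family elevated under
#' FYM).
#'
#' @param design Data.frame from [generate_design()]; must contain a `fym`
#'   column with `"+FYM"` marking treated samples.
#' @param base_profile Named non-negative numeric vector of expected taxon
#'   proportions (normalised internally).
#' @param effect_taxon Name (in `base_profile`) of the taxon carrying the
#'   planted effect.
#' @param fold_change Multiplicative effect on `effect_taxon` in `+FYM`
#'   samples; must be >= 1 (1 = no effect).
#' @param dispersion Overdispersion parameter (>= 0); Dirichlet
#'   concentration is `sum(profile)/dispersion`. 0 gives pure multinomial
#'   sampling.
#' @param depth Sequencing depth per sample (row sum of counts).
#' @param seed Integer RNG seed.
#' @return List with `counts` (integer matrix, samples x taxa), `design`,
#'   and `truth` (base and perturbed expected proportions, effect taxon and
#'   fold change).
#' @export
generate_abundance_table <- function(design, base_profile, effect_taxon,
                                     fold_change = 1, dispersion = 0.02,
                                     depth = 30000L, seed = 1L) {
  if (!"fym" %in% names(design)) .stop2("design must contain a 'fym' column")
  if (is.null(names(base_profile)) || any(base_profile < 0))
    .stop2("'base_profile' must be a named non-negative vector")
  if (!effect_taxon %in% names(base_profile))
    .stop2("'effect_taxon' not in base_profile")
  if (fold_change < 1) .stop2("'fold_change' must be >= 1")
  .check_number(dispersion, "dispersion", 0)
  .check_number(depth, "depth", 1)
  set.seed(as.integer(seed))

  p0 <- base_profile / sum(base_profile)
  p1 <- p0
  p1[effect_taxon] <- p1[effect_taxon] * fold_change
  p1 <- p1 / sum(p1)

  counts <- matrix(0L, nrow(design), length(p0),
                   dimnames = list(design$sample_id, names(p0)))
  for (i in seq_len(nrow(design))) {
    pr <- if (design$fym[i] == "+FYM") p1 else p0
    if (dispersion > 0) pr <- .rdirichlet1(pr / dispersion)
    counts[i, ] <- as.integer(stats::rmultinom(1L, size = depth, prob = pr))
  }
  list(counts = counts, design = design,
       truth = list(effect_taxon = effect_taxon, fold_change = fold_change,
                    base_profile = p0, fym_profile = p1))
}
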