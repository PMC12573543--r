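# The synthetic generators: determinism, ground-truth semantics, and the
# statistical contracts of the count and isotope models.

test_that("zero mutation reproduces the cluster anchors exactly", {
  cor <- generate_reference_corpus(corpus_spec(1, 0, 0, seed = 3))
  anchors <- nifh_anchor_proteins()
  expect_equal(unname(as.character(cor$proteins)),
               unname(as.character(anchors)))
  expect_equal(cor$truth$cluster, c("I", "II", "III", "IV"))
})

test_that("corpus and ASV generation are deterministic for a fixed seed", {
  a <- generate_reference_corpus(corpus_spec(3, 0.1, 5, seed = 7))
  b <- generate_reference_corpus(corpus_spec(3, 0.1, 5, seed = 7))
  expect_identical(as.character(a$proteins), as.character(b$proteins))
  expect_identical(a$truth, b$truth)
  ga <- generate_asv_set(a, 4, 2, 2, 2, seed = 7)
  gb <- generate_asv_set(b, 4, 2, 2, 2, seed = 7)
  expect_identical(as.character(ga$asvs), as.character(gb$asvs))
  # byte-identical FASTA output
  fa <- tempfile(fileext = ".faa"); fb <- tempfile(fileext = ".faa")
  write_fasta(a$proteins, fa); write_fasta(b$proteins, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("every decoy fails the motif filter and its violation is recorded", {
  cor <- generate_reference_corpus(corpus_spec(2, 0.1, 10, seed = 5))
  mf <- motif_filter(cor$proteins)
  is_decoy <- cor$truth$type == "decoy"
  expect_equal(sum(!mf$pass), 10)
  expect_true(all(!mf$pass[is_decoy]))
  expect_true(all(mf$pass[!is_decoy]))
  expect_true(all(!is.na(cor$truth$violated_rule[is_decoy])))
  expect_true(all(is.na(cor$truth$violated_rule[!is_decoy])))
})

test_that("generator parameter validation rejects out-of-range values", {
  expect_error(corpus_spec(mutation_rate = 0.5), "mutation_rate")
  expect_error(corpus_spec(n_refs_per_cluster = 0), "n_refs_per_cluster")
  expect_error(generate_abundance_table(generate_design(),
                                        paddy_family_profile(),
                                        "Gallionellaceae", fold_change = 0.5),
               "fold_change")
  d <- generate_design()
  expect_error(generate_isotope_dataset(d, true_rates = -1), "true_rates")
  expect_error(generate_isotope_dataset(d, 1, atom_initial = 30),
               "enrichment")
})

test_that("ASV generator handles the empty and no-reference edge cases", {
  cor <- small_corpus()
  empty <- generate_asv_set(cor, 0, 0, 0, 0, seed = 1)
  expect_length(empty$asvs, 0)
  expect_equal(nrow(empty$truth), 0)
  no_valid <- list(proteins = Biostrings::AAStringSet(),
                   truth = data.frame(id = character(0), type = character(0)))
  expect_error(generate_asv_set(no_valid, n_valid = 1), "valid reference")
})

test_that("abundance rows sum to the requested depth", {
  d <- generate_design(fields = "F3", soil_types = "enriched",
                       mineral = c("control", "N", "P", "NP"))
  ab <- generate_abundance_table(d, paddy_family_profile(),
                                 "Gallionellaceae", fold_change = 2,
                                 depth = 1000, seed = 2)
  expect_true(all(rowSums(ab$counts) == 1000))
  expect_equal(rownames(ab$counts), d$sample_id)
})

test_that("planted fold change matches the closed-form perturbed profile", {
  # dispersion -> 0: multinomial around the perturbed profile, so the
  # +FYM / -FYM mean-proportion ratio approaches p1/p0 from the truth
  d <- generate_design(fields = "F1", soil_types = "x", replicates = 30)
  ab <- generate_abundance_table(d, paddy_family_profile(),
                                 "Gallionellaceae", fold_change = 4,
                                 dispersion = 0, depth = 50000, seed = 4)
  ra <- relative_abundance(ab$counts)
  plus <- ab$design$fym == "+FYM"
  ratio <- mean(ra[plus, "Gallionellaceae"]) / mean(ra[!plus, "Gallionellaceae"])
  expected <- ab$truth$fym_profile[["Gallionellaceae"]] /
    ab$truth$base_profile[["Gallionellaceae"]]
  expect_lt(abs(ratio / expected - 1), 0.10)
})

test_that("fold change 1 leaves the target taxon unchanged within MC error", {
  d <- generate_design(fields = "F1", soil_types = "x", replicates = 100)
  ab <- generate_abundance_table(d, paddy_family_profile(),
                                 "Gallionellaceae", fold_change = 1,
                                 dispersion = 0.02, depth = 5000, seed = 6)
  ra <- relative_abundance(ab$counts)[, "Gallionellaceae"]
  plus <- ab$design$fym == "+FYM"
  diff <- mean(ra[plus]) - mean(ra[!plus])
  se <- sqrt(var(ra[plus]) / sum(plus) + var(ra[!plus]) / sum(!plus))
  expect_lt(abs(diff), 3 * se)
})

test_that("isotope generator inverts the mixing equation", {
  d <- generate_design()
  # zero rate, zero noise: final atom% equals the baseline exactly
  g0 <- generate_isotope_dataset(d, true_rates = 0, noise_sd = 0)
  expect_equal(g0$measurements$atom_final, g0$measurements$atom_initial)
  # noise-free round trip through the estimator
  g <- generate_isotope_dataset(d, true_rates = 7.42, noise_sd = 0)
  est <- estimate_fixed_n(g$measurements)
  expect_equal(est$fixed_n_mg_kg, rep(7.42, nrow(d)))
})

test_that("noisy isotope estimates recover the truth within Monte-Carlo error", {
  d <- generate_design(fields = "F1", soil_types = "x", fym = "y",
                       replicates = 500)
  g <- generate_isotope_dataset(d, true_rates = 2.7, noise_sd = 0.001,
                                seed = 9)
  est <- estimate_fixed_n(g$measurements)
  se <- sd(est$fixed_n_mg_kg) / sqrt(nrow(d))
  expect_lt(abs(mean(est$fixed_n_mg_kg) - 2.7), 3 * se)
})
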