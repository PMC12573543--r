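# Aggregation, relative abundance, diversity and the factorial statistics.

make_assignments <- function(asv_ids, clusters, families) {
  data.frame(asv_id = asv_ids, cluster = clusters,
             lineage = vapply(families, function(f)
               paste0("d__Bacteria;p__P;c__C;o__O;f__", f, ";g__G;s__S"),
               character(1)),
             stringsAsFactors = FALSE)
}

test_that("aggregation conserves per-sample totals and pools unassigned", {
  counts <- matrix(c(10, 0, 3, 7, 5, 5), nrow = 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("a1", "a2", "a3")))
  asg <- make_assignments(c("a1", "a2"), c("I", "III"),
                          c("Gallionellaceae", "Clostridiaceae"))
  # single cell survives intact
  one <- aggregate_counts(counts["s1", "a1", drop = FALSE], asg, "cluster")
  expect_equal(unname(one[1, "I"]), 10)
  agg <- aggregate_counts(counts, asg, "family")
  expect_equal(rowSums(agg), rowSums(counts))
  expect_true("unassigned" %in% colnames(agg))  # a3 has no assignment
  expect_equal(unname(agg[, "unassigned"]), c(3, 5))
  aggc <- aggregate_counts(counts, asg, "cluster")
  expect_equal(sort(colnames(aggc)), c("I", "III", "unassigned"))
})

test_that("relative abundance normalises rows and is scale invariant", {
  m <- matrix(c(1, 1, 2), nrow = 1, dimnames = list("s1", c("x", "y", "z")))
  expect_equal(unname(relative_abundance(m)[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(relative_abundance(7 * m), relative_abundance(m))
  expect_lt(max(abs(rowSums(relative_abundance(m)) - 1)), 1e-12)
  bad <- rbind(m, s2 = c(0, 0, 0))
  expect_error(relative_abundance(bad), "s2")
})

test_that("Shannon index matches closed forms and a hand-summed oracle", {
  expect_equal(shannon_index(rep(5, 4)), log(4))
  expect_equal(shannon_index(c(10, 0, 0)), 0)
  expect_equal(shannon_index(c(5, 3, 2)), oracle_shannon(c(5, 3, 2)))
  # invariant under relabeling / permutation
  expect_equal(shannon_index(c(2, 3, 5)), shannon_index(c(5, 3, 2)))
  expect_equal(shannon_index(c(5, 3, 2), base = 2),
               oracle_shannon(c(5, 3, 2)) / log(2))
})

test_that("single-factor ANOVA F equals the squared two-sample t statistic", {
  d <- data.frame(y = c(3.1, 2.8, 3.4, 5.0, 5.3, 4.6),
                  g = rep(c("ctl", "trt"), each = 3))
  an <- anova_factorial(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(an$table$F[1], unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(an$table$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("ANOVA partitions sums of squares and is order invariant", {
  d <- generate_design(fields = "F3", soil_types = "x",
                       mineral = c("control", "N", "P", "NP"))
  set.seed(12)
  d$y <- rnorm(nrow(d)) + 2 * (d$fym == "+FYM")
  a1 <- anova_factorial(d, "y", c("fym", "mineral"))$table
  a2 <- anova_factorial(d, "y", c("mineral", "fym"))$table
  expect_equal(sum(a1$sumsq), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  for (trm in c("fym", "mineral", "fym:mineral")) {
    expect_equal(a1$F[a1$term == trm],
                 a2$F[a2$term == sub("fym:mineral", "mineral:fym", trm)],
                 tolerance = 1e-10)
  }
  # constant response: all F are zero
  d$y <- 1
  a0 <- anova_factorial(d, "y", c("fym", "mineral"))$table
  expect_true(all(a0$F[a0$term != "Residuals"] == 0))
  # empty cells rejected
  expect_error(anova_factorial(d[d$fym == "+FYM" | d$mineral != "N", ],
                               "y", c("fym", "mineral")), "cells|unbalanced")
})

test_that("Tukey letters separate huge effects and merge identical cells", {
  d <- data.frame(y = rep(1, 12), g = rep(c("a", "b", "c", "d"), each = 3))
  tk <- tukey_hsd(d, "y", "g")
  expect_true(all(tk$letters == tk$letters[1]))
  set.seed(5)
  d2 <- data.frame(y = c(rnorm(6, 0, 0.5), rnorm(6, 50, 0.5)),
                   g = rep(c("lo", "hi"), each = 6))
  tk2 <- tukey_hsd(d2, "y", "g")
  expect_lt(tk2$pairwise$p_adj[1], 1e-6)
  expect_false(tk2$letters[["lo"]] == tk2$letters[["hi"]])
  # letters are consistent with pairwise significance on a 3-group case
  set.seed(6)
  d3 <- data.frame(y = c(rnorm(4, 0), rnorm(4, 0.2), rnorm(4, 30)),
                   g = rep(c("a", "b", "c"), each = 4))
  tk3 <- tukey_hsd(d3, "y", "g")
  share <- function(x, y) {
    lx <- strsplit(tk3$letters[[x]], "")[[1]]
    ly <- strsplit(tk3$letters[[y]], "")[[1]]
    length(intersect(lx, ly)) > 0
  }
  for (k in seq_len(nrow(tk3$pairwise))) {
    pr <- tk3$pairwise[k, ]
    expect_equal(share(pr$a, pr$b), pr$p_adj >= 0.05)
  }
})

test_that("the planted FYM effect propagates through aggregation to ANOVA", {
  d <- generate_design(fields = "F3", soil_types = "x",
                       mineral = c("control", "N", "P", "NP"))
  ab <- generate_abundance_table(d, paddy_family_profile(),
                                 "Gallionellaceae", fold_change = 4,
                                 dispersion = 0.02, depth = 30000, seed = 8)
  ra <- relative_abundance(ab$counts)
  plus <- ab$design$fym == "+FYM"
  expect_gt(mean(ra[plus, "Gallionellaceae"]),
            mean(ra[!plus, "Gallionellaceae"]))
  df <- data.frame(ab$design, y = ra[, "Gallionellaceae"])
  an <- anova_factorial(df, "y", c("fym", "mineral"))
  expect_lt(an$table$p[an$table$term == "fym"], 0.05)
})
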