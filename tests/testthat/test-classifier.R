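# Alignment scoring, database classification, neighbor-joining trees and
# bootstrap support.

test_that("alignment identities and symmetry behave as specified", {
  s <- as.character(nifh_anchor_proteins()[["anchor_II"]])
  al <- align_protein(s, s)
  expect_equal(al$identity, 100)
  set.seed(3)
  a <- random_protein(40); b <- random_protein(35)
  expect_equal(align_protein(a, b)$score, align_protein(b, a)$score)
  expect_error(align_protein("", s), "non-empty")
})

test_that("local alignment scores match an independent dynamic program", {
  set.seed(97)
  for (k in seq_len(50)) {
    a <- random_protein(sample(5:20, 1))
    b <- random_protein(sample(5:20, 1))
    expect_equal(align_protein(a, b, mode = "local")$score,
                 oracle_local_score(a, b))
  }
})

test_that("classification copies the hit and honours the ordering contract", {
  cor <- small_corpus(n = 3, rate = 0.1, seed = 61)
  db <- build_database(cor$proteins, nifh_anchor_proteins(),
                       nifh_anchor_proteins(),
                       taxonomy = setNames(cor$truth$lineage, cor$truth$id))
  q <- Biostrings::AAStringSet(setNames(
    as.character(db$proteins[["ref_I_001"]]), "q1"))
  res <- classify_asv(q, db, k = 3)
  a <- res$assignments
  expect_equal(a$best_hit, "ref_I_001")
  expect_equal(a$identity, 100)
  expect_equal(a$cluster, "I")
  expect_equal(parse_lineage(a$lineage)$family,
               cor$truth$family[cor$truth$id == "ref_I_001"])
  h <- res$hits[["q1"]]
  expect_equal(nrow(h), 3)
  expect_true(all(diff(h$score) <= 0))
  expect_error(classify_asv(q, list(proteins = Biostrings::AAStringSet())),
               "empty")
})

test_that("low-identity hits get their lineage truncated", {
  db <- list(proteins = Biostrings::AAStringSet(c(r1 = strrep("KDEAW", 20))),
             entries = data.frame(
               id = "r1",
               lineage = "d__Bacteria;p__Pseudomonadota;c__Gammaproteobacteria;o__Gallionellales;f__Gallionellaceae;g__Sideroxyarcus;s__Sideroxyarcus sp1",
               cluster = "I", stringsAsFactors = FALSE))
  # identical: full lineage kept
  full <- classify_asv(c(q = strrep("KDEAW", 20)), db)$assignments
  expect_equal(parse_lineage(full$lineage)$genus, "Sideroxyarcus")
  # ~96% identical: genus dropped, family kept
  q2 <- paste0(strrep("KDEAW", 16), strrep("KDEAY", 4))
  mid <- classify_asv(c(q = q2), db)$assignments
  expect_true(mid$identity < 97 && mid$identity >= 90)
  expect_equal(parse_lineage(mid$lineage)$genus, "")
  expect_equal(parse_lineage(mid$lineage)$family, "Gallionellaceae")
})

test_that("synthetic ASVs at low mutation rates recover family and cluster", {
  cor <- generate_reference_corpus(corpus_spec(5, 0.05, 0, seed = 71))
  db <- build_database(cor$proteins, nifh_anchor_proteins(),
                       nifh_anchor_proteins(),
                       taxonomy = setNames(cor$truth$lineage, cor$truth$id))
  gen <- generate_asv_set(cor, n_valid = 20, n_frameshift = 0, n_pseudo = 0,
                          n_offtarget = 0, seed = 71)
  qc <- qc_filter(gen$asvs)
  res <- classify_asv(qc$proteins, db)
  truth <- gen$truth[match(res$assignments$asv_id, gen$truth$asv_id), ]
  fam <- parse_lineage(res$assignments$lineage)$family
  expect_gte(mean(fam == truth$true_family), 0.95)
  expect_gte(mean(res$assignments$cluster == truth$true_cluster), 0.95)
})

test_that("neighbor joining reconstructs an additive 5-leaf metric exactly", {
  D <- additive_5leaf()
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, rownames(D))
  # patristic distances reproduce the generating metric, which pins down
  # both topology and branch lengths
  got <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(got, D, tolerance = 1e-10)
  expect_equal(attr(tr, "n_clamped"), 0)
})

test_that("identical ingroup sequences give a star with zero inner branches", {
  s <- as.character(nifh_anchor_proteins()[["anchor_I"]])
  prot <- Biostrings::AAStringSet(c(a = s, b = s, c = s, d = s,
    out = as.character(nifh_anchor_proteins()[["anchor_IV"]])))
  tr <- build_tree(prot, outgroup = "out", distance = "p_distance")
  expect_setequal(tr$tip.label, names(prot))
  d <- ape::cophenetic.phylo(tr)
  expect_true(all(d[c("a","b","c","d"), c("a","b","c","d")] == 0))
})

test_that("bootstrap gives full support to a fully congruent split", {
  # 20 constant columns + 10 diagnostic columns (K in A,B vs R in C,D,E):
  # every resample containing a diagnostic column supports AB|CDE
  diag_ab <- strrep("K", 10); diag_rest <- strrep("R", 10)
  const <- strrep("G", 20)
  prot <- Biostrings::AAStringSet(c(
    A = paste0(const, diag_ab), B = paste0(const, diag_ab),
    C = paste0(const, diag_rest), D = paste0(const, diag_rest),
    E = paste0(const, diag_rest)))
  tr <- build_tree(prot, outgroup = "E", distance = "p_distance")
  bs <- bootstrap_support(tr, n_reps = 50, seed = 2)
  pp <- ape::prop.part(bs)
  is_ab <- vapply(pp, function(x)
    setequal(bs$tip.label[x], c("A", "B")) ||
      setequal(bs$tip.label[x], c("C", "D", "E")), logical(1))
  sup <- attr(bs, "support")
  expect_true(any(is_ab))
  expect_true(all(sup[which(is_ab)] == 100, na.rm = TRUE))
  # single replicate quantises support to {0, 100}
  b1 <- bootstrap_support(tr, n_reps = 1, seed = 5)
  expect_true(all(attr(b1, "support") %in% c(0, 100) |
                    is.na(attr(b1, "support"))))
  # determinism
  b2 <- bootstrap_support(tr, n_reps = 20, seed = 9)
  b3 <- bootstrap_support(tr, n_reps = 20, seed = 9)
  expect_identical(attr(b2, "support"), attr(b3, "support"))
})

test_that("newick output round-trips to an isomorphic tree", {
  skip_if_not_installed("phangorn")
  cor <- small_corpus(n = 2, rate = 0.15, seed = 81)
  prot <- c(cor$proteins[cor$truth$type == "valid"][1:5],
            Biostrings::AAStringSet(c(
              out = as.character(nifh_anchor_proteins()[["anchor_IV"]]))))
  tr <- build_tree(prot, outgroup = "out")
  f <- tempfile(fileext = ".nwk")
  write_tree_file(tr, f)
  expect_match(readLines(f)[1], "method:NJ")
  back <- ape::read.tree(text = readLines(f)[2])
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(back)), 0)
})
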