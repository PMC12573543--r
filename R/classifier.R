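# Taxonomy and NifH-cluster classification of QC-passed ASVs: exhaustive
# protein alignment against the curated database, and distance-tree
# placement with bootstrap support. Trees are neighbor-joining on protein
# distances (Poisson-corrected by default) and carry a method tag so they
# are never mistaken for maximum-likelihood trees.

.truncate_lineage <- function(lineage, to_rank) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  keep <- seq_len(match(to_rank, ranks))
  parts <- parse_lineage(lineage)
  pre <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
  vapply(seq_along(lineage), function(i) {
    vals <- as.character(parts[i, ])
    vals[-keep] <- ""
    paste(paste0(pre, vals), collapse = ";")
  }, character(1))
}

#' Classify ASVs against the curated NifH database
#'
#' Exhaustive pairwise local alignment of each query against every database
#' entry. The best hit (highest score; ties broken by higher identity, then
#' lexicographic id) supplies the taxonomy lineage and cluster label. The
#' lineage is truncated to family when identity falls below the genus
#' threshold and to phylum below the family threshold.
#'
#' @param queries QC-passed protein translations
#'   ([Biostrings::AAStringSet] or named character).
#' @param db A `nifh_db` from [build_database()], or a list with
#'   `proteins` (AAStringSet) and `entries` (data.frame `id`, `lineage`,
#'   `cluster`).
#' @param k Number of ranked hits to keep per query.
#' @param genus_identity,family_identity Percent-identity thresholds below
#'   which the lineage is truncated (defaults 97 and 90).
#' @return List with `assignments` (data.frame `asv_id`, `best_hit`,
#'   `identity`, `lineage`, `cluster`, `support`) and `hits` (per-query
#'   data.frames of the top `k` hits with non-increasing scores).
#' @export
classify_asv <- function(queries, db, k = 1L, genus_identity = 97,
                         family_identity = 90) {
  queries <- .as_aastringset(queries, "queries")
  if (is.null(db$proteins) || length(db$proteins) == 0)
    .stop2("database is empty")
  ids <- names(db$proteins)
  ord0 <- order(ids)
  rows <- vector("list", length(queries))
  hits <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- as.character(queries[[i]])
    sc <- idn <- numeric(length(ids))
    for (j in seq_along(ids)) {
      al <- align_protein(q, as.character(db$proteins[[j]]), mode = "local")
      sc[j] <- al$score; idn[j] <- al$identity
    }
    ord <- order(-sc, -idn, ids)
    top <- ord[seq_len(min(k, length(ids)))]
    hits[[i]] <- data.frame(query = names(queries)[i], target = ids[top],
                            score = sc[top], identity = idn[top],
                            stringsAsFactors = FALSE)
    b <- ord[1]
    ent <- db$entries[match(ids[b], db$entries$id), ]
    lin <- ent$lineage
    if (!is.na(lin) && nzchar(lin)) {
      if (idn[b] < family_identity) lin <- .truncate_lineage(lin, "phylum")
      else if (idn[b] < genus_identity) lin <- .truncate_lineage(lin, "family")
    }
    rows[[i]] <- data.frame(asv_id = names(queries)[i], best_hit = ids[b],
                            identity = idn[b], lineage = lin,
                            cluster = ent$cluster, support = idn[b],
                            stringsAsFactors = FALSE)
  }
  names(hits) <- names(queries)
  list(assignments = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       hits = hits)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()] that clamps negative branch lengths to
#' zero (recording how many were clamped) and optionally roots the tree on
#' an outgroup.
#'
#' @param d A `dist` or symmetric matrix of pairwise distances.
#' @param outgroup Leaf name to root on, or `NULL` for an unrooted tree.
#' @return An [ape::phylo] with attributes `n_clamped` and `method = "NJ"`.
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (is.matrix(d)) d <- stats::as.dist(d)
  tr <- ape::nj(d)
  n_clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      .stop2("outgroup '", outgroup, "' not among leaves")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  attr(tr, "n_clamped") <- n_clamped
  attr(tr, "method") <- "NJ"
  tr
}

#' Build a protein distance tree of ASVs and references
#'
#' Aligns the sequences with [anchor_msa()], computes pairwise protein
#' distances (Poisson-corrected by default, p-distance for hand-checkable
#' work) and infers a neighbor-joining tree rooted on the outgroup.
#'
#' @param proteins Named [Biostrings::AAStringSet] (>= 4 sequences,
#'   including the outgroup).
#' @param outgroup Name of the outgroup leaf.
#' @param distance `"poisson"` or `"p_distance"`.
#' @return A rooted [ape::phylo] with attributes `method = "NJ"` and
#'   `distance`.
#' @export
build_tree <- function(proteins, outgroup,
                       distance = c("poisson", "p_distance")) {
  distance <- match.arg(distance)
  proteins <- .as_aastringset(proteins, "proteins")
  if (length(proteins) < 4) .stop2("need at least 4 sequences")
  if (!outgroup %in% names(proteins))
    .stop2("outgroup '", outgroup, "' not among input sequences")
  msa <- anchor_msa(proteins)
  tr <- nj_tree(.msa_dist(msa, distance), outgroup = outgroup)
  attr(tr, "distance") <- distance
  attr(tr, "msa") <- msa
  tr
}

#' Bootstrap support for the internal edges of a distance tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' neighbor-joining tree per replicate, and reports for each internal node
#' of the original tree the percentage of replicate trees containing the
#' same bipartition (branch lengths and rooting ignored). Deterministic
#' for a fixed seed.
#'
#' @param tree Tree from [build_tree()] (its stored alignment is reused).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer RNG seed.
#' @return The tree, unrooted (supports are properties of unrooted
#'   bipartitions; the outgroup attachment edge carries none), with
#'   `node.label` set to the support percentages and an attribute
#'   `support` (numeric vector, one entry per internal node).
#' @export
bootstrap_support <- function(tree, n_reps = 100L, seed = 1L) {
  .check_number(n_reps, "n_reps", 1)
  msa <- attr(tree, "msa")
  if (is.null(msa)) .stop2("tree carries no alignment; use build_tree()")
  if (ncol(msa) < 2) .stop2("alignment must have at least 2 columns")
  distance <- attr(tree, "distance") %||% "poisson"
  fun <- function(m) nj_tree(.msa_dist(m, distance))
  ut <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  set.seed(as.integer(seed))
  counts <- ape::boot.phylo(ut, msa, fun, B = n_reps, rooted = FALSE,
                            quiet = TRUE)
  support <- 100 * counts / n_reps
  ut$node.label <- support
  attr(ut, "support") <- support
  attr(ut, "msa") <- msa
  attr(ut, "distance") <- distance
  attr(ut, "method") <- attr(tree, "method")
  ut
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo].
#' @param path Output file; a `[method:NJ]` comment line is prepended so
#'   distance trees are never mistaken for maximum-likelihood trees.
#' @export
write_tree_file <- function(tree, path) {
  method <- attr(tree, "method") %||% "NJ"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("[method:%s]", method), ape::write.tree(tree)), con)
  invisible(path)
}
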