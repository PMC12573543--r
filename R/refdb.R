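# Curated NifH reference-database construction: homology screen against
# seed proteins, conserved-motif validation, dereplication and cluster
# labelling.

.as_aastringset <- function(x, what = "sequences") {
  if (is(x, "AAStringSet")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(Biostrings::AAStringSet(x))
  }
  .stop2("'", what, "' must be an AAStringSet or named character vector")
}

#' Screen candidate proteins against seed (characterised) proteins
#'
#' Exhaustive pairwise local alignment of every candidate against every
#' seed (BLOSUM62, affine gaps open 11 / extend 1). A candidate is retained
#' iff its best-scoring seed hit reaches both the identity and the coverage
#' threshold; coverage is the aligned fraction of the shorter sequence.
#'
#' @param candidates,seeds [Biostrings::AAStringSet] (or named character).
#' @param min_identity Minimum percent identity of the best hit (0--100).
#' @param min_coverage Minimum aligned fraction of the shorter sequence
#'   (0--1].
#' @return List with `retained` (AAStringSet subset of `candidates`) and
#'   `hits` (data.frame `query`, `target`, `identity`, `score`, `coverage`,
#'   best hit per query, sorted by score, ties broken by target id).
#' @export
screen_homologs <- function(candidates, seeds, min_identity = 40,
                            min_coverage = 0.5) {
  candidates <- .as_aastringset(candidates, "candidates")
  seeds <- .as_aastringset(seeds, "seeds")
  if (length(candidates) == 0 || length(seeds) == 0)
    .stop2("'candidates' and 'seeds' must be non-empty")
  .check_number(min_identity, "min_identity", 0, 100)
  .check_number(min_coverage, "min_coverage", 0, 1)

  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    q <- as.character(candidates[[i]])
    best <- NULL
    for (j in seq_along(seeds)) {
      t <- as.character(seeds[[j]])
      al <- align_protein(q, t, mode = "local")
      shorter <- min(nchar(q), nchar(t))
      span <- if (nchar(q) <= nchar(t)) al$query_range else al$target_range
      cov <- (span[2] - span[1] + 1) / shorter
      hit <- data.frame(query = names(candidates)[i],
                        target = names(seeds)[j],
                        identity = al$identity, score = al$score,
                        coverage = cov, stringsAsFactors = FALSE)
      if (is.null(best) || hit$score > best$score ||
          (hit$score == best$score && hit$target < best$target)) best <- hit
    }
    rows[[i]] <- best
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score, hits$target), , drop = FALSE]
  rownames(hits) <- NULL
  keep <- hits$query[hits$identity >= min_identity &
                       hits$coverage >= min_coverage]
  list(retained = candidates[names(candidates) %in% keep], hits = hits)
}

#' Conserved-motif filter for NifH candidates
#'
#' A sequence passes iff every motif in `motifs` matches within its
#' mismatch budget; the leftmost match position (1-based) is reported per
#' motif. Defaults to the three canonical cysteine-containing NifH motifs
#' ([nifh_motifs()]), matched exactly.
#'
#' @param sequences Amino-acid sequences ([Biostrings::AAStringSet] or
#'   named character).
#' @param motifs Data.frame as returned by [nifh_motifs()].
#' @return Data.frame with `id`, `pass`, and one position column per motif
#'   (`NA` when absent).
#' @export
#' @examples
#' motif_filter(nifh_anchor_proteins())$pass  # all TRUE
motif_filter <- function(sequences, motifs = nifh_motifs()) {
  sequences <- .as_aastringset(sequences)
  if (nrow(motifs) == 0) .stop2("'motifs' must be non-empty")
  .aa_check(sequences)
  out <- data.frame(id = names(sequences), pass = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(motifs))) {
    pos <- vapply(seq_along(sequences), function(i) {
      m <- Biostrings::matchPattern(motifs$pattern[k], sequences[[i]],
                                    max.mismatch = motifs$max_mismatches[k],
                                    with.indels = FALSE)
      if (length(m) == 0) NA_integer_ else IRanges::start(m)[1]
    }, integer(1))
    out[[motifs$name[k]]] <- pos
    out$pass <- out$pass & !is.na(pos)
  }
  out
}

.anchor_clusters <- function(anchors) {
  cl <- S4Vectors::mcols(anchors)$cluster
  if (is.null(cl)) {
    cl <- sub("^anchor_", "", names(anchors))
  }
  setNames(as.character(cl), names(anchors))
}

#' Assign a NifH cluster label to a query protein
#'
#' Either by best pairwise-alignment hit against the labelled anchors
#' (support = percent identity) or by nearest-leaf placement in a
#' neighbor-joining distance tree of query plus anchors (support = percent
#' of bootstrap trees whose nearest labelled leaf carries the same
#' cluster).
#'
#' @param query Amino-acid sequence (character or AAString).
#' @param anchors Labelled [Biostrings::AAStringSet]; cluster labels read
#'   from `mcols(anchors)$cluster` or from `anchor_<label>` names.
#' @param method `"best_hit"` (default) or `"nearest_leaf"`.
#' @param required_clusters Clusters that must each have at least one
#'   anchor; a missing one is a configuration error.
#' @param n_boot Bootstrap replicates for `nearest_leaf` support.
#' @param seed RNG seed for the bootstrap.
#' @return List with `cluster`, `support` (percent), `method` and
#'   `nearest` (anchor id).
#' @export
assign_cluster <- function(query, anchors,
                           method = c("best_hit", "nearest_leaf"),
                           required_clusters = c("I", "II", "III", "IV"),
                           n_boot = 100L, seed = 1L) {
  method <- match.arg(method)
  anchors <- .as_aastringset(anchors, "anchors")
  labels <- .anchor_clusters(anchors)
  miss <- setdiff(required_clusters, labels)
  if (length(miss))
    .stop2("no anchor for cluster(s): ", paste(miss, collapse = ", "))
  q <- as.character(query)

  if (method == "best_hit") {
    best <- NULL
    for (j in seq_along(anchors)) {
      al <- align_protein(q, as.character(anchors[[j]]), mode = "local")
      cand <- list(id = names(anchors)[j], score = al$score,
                   identity = al$identity)
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && cand$identity > best$identity) ||
          (cand$score == best$score && cand$identity == best$identity &&
             cand$id < best$id)) best <- cand
    }
    return(list(cluster = unname(labels[best$id]), support = best$identity,
                method = "best_hit", nearest = best$id))
  }

  seqs <- c(setNames(Biostrings::AAStringSet(q), "query"), anchors)
  msa <- anchor_msa(seqs)
  nearest_label <- function(m) {
    d <- as.matrix(.msa_dist(m, "poisson"))
    nn <- names(which.min(d["query", names(labels)]))
    unname(labels[nn])
  }
  lab <- nearest_label(msa)
  d <- as.matrix(.msa_dist(msa, "poisson"))
  nn <- names(which.min(d["query", names(labels)]))
  set.seed(as.integer(seed))
  agree <- vapply(seq_len(n_boot), function(b) {
    cols <- sample(ncol(msa), replace = TRUE)
    nearest_label(msa[, cols, drop = FALSE]) == lab
  }, logical(1))
  list(cluster = lab, support = 100 * mean(agree), method = "nearest_leaf",
       nearest = nn)
}

#' Build the curated NifH reference database
#'
#' The full curation pipeline: homology screen against the seeds, then the
#' conserved-motif filter, then dereplication of identical sequences (the
#' lexicographically smallest id is kept), then cluster labelling against
#' the anchors. Sequences failing the motif filter are excluded entirely
#' (cluster-IV paralogs lacking the motifs do not enter the database).
#'
#' @param candidates Candidate proteins (AAStringSet or named character).
#' @param seeds Seed (characterised) proteins for the homology screen.
#' @param anchors Cluster-labelled anchors for [assign_cluster()].
#' @param taxonomy Optional named character vector mapping candidate id to
#'   a 7-rank lineage string; unknown ids get an empty lineage.
#' @param motifs Motif table ([nifh_motifs()]).
#' @param min_identity,min_coverage Thresholds of [screen_homologs()].
#' @param method Cluster-assignment method (see [assign_cluster()]).
#' @return List of class `nifh_db` with `entries` (data.frame `id`,
#'   `lineage`, `cluster`, `support`, `provenance`), `proteins`
#'   (AAStringSet, same ids) and `report` (candidate counts after each
#'   stage).
#' @export
build_database <- function(candidates, seeds, anchors, taxonomy = NULL,
                           motifs = nifh_motifs(), min_identity = 40,
                           min_coverage = 0.5, method = "best_hit") {
  candidates <- .as_aastringset(candidates, "candidates")
  scr <- screen_homologs(candidates, seeds, min_identity, min_coverage)
  kept <- scr$retained

  mres <- if (length(kept)) motif_filter(kept, motifs) else
    data.frame(id = character(0), pass = logical(0))
  kept <- kept[names(kept) %in% mres$id[mres$pass]]

  # dereplicate identical sequences, keep smallest id
  if (length(kept)) {
    ord <- order(names(kept))
    kept <- kept[ord]
    kept <- kept[!duplicated(as.character(kept))]
  }

  report <- c(input = length(candidates),
              after_homology_screen = length(scr$retained),
              after_motif_filter = sum(mres$pass),
              after_dereplication = length(kept))

  if (length(kept) == 0) {
    warning("no candidates survived the curation pipeline; empty database")
    entries <- data.frame(id = character(0), lineage = character(0),
                          cluster = character(0), support = numeric(0),
                          provenance = character(0))
    return(structure(list(entries = entries,
                          proteins = Biostrings::AAStringSet(),
                          report = report), class = "nifh_db"))
  }

  asg <- lapply(seq_along(kept), function(i)
    assign_cluster(as.character(kept[[i]]), anchors, method = method))
  entries <- data.frame(
    id = names(kept),
    lineage = if (is.null(taxonomy)) "" else
      unname(ifelse(is.na(taxonomy[names(kept)]), "", taxonomy[names(kept)])),
    cluster = vapply(asg, `[[`, character(1), "cluster"),
    support = vapply(asg, `[[`, numeric(1), "support"),
    provenance = sprintf("screen(id>=%g%%,cov>=%g);motif;derep;cluster=%s",
                         min_identity, min_coverage, method),
    stringsAsFactors = FALSE)
  structure(list(entries = entries, proteins = kept, report = report),
            class = "nifh_db")
}

#' @export
print.nifh_db <- function(x, ...) {
  cat("NifH reference database:", nrow(x$entries), "entries\n")
  if (nrow(x$entries)) print(table(cluster = x$entries$cluster))
  cat("pipeline:", paste(names(x$report), x$report, sep = "=",
                         collapse = " -> "), "\n")
  invisible(x)
}
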