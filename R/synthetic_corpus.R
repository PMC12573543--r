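# Synthetic NifH corpus generator: emulates a curated homolog collection
# (valid cluster-labelled proteins with intact motifs) plus motif-violating
# decoys, with a truth table so downstream filters can be scored exactly.

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

#' Specification of a synthetic NifH reference corpus
#'
#' @param n_refs_per_cluster Number of valid references generated per NifH
#'   cluster (I--IV); at least 1 each.
#' @param mutation_rate Substitutions per site applied to the cluster anchor
#'   outside the protected motif windows; in `[0, 0.3]`.
#' @param n_decoys Number of motif-violating decoy proteins.
#' @param seed Integer RNG seed; the whole corpus is a deterministic
#'   function of this spec.
#' @return A list of class `corpus_spec`.
#' @export
corpus_spec <- function(n_refs_per_cluster = 10L, mutation_rate = 0.1,
                        n_decoys = 10L, seed = 1L) {
  .check_number(n_refs_per_cluster, "n_refs_per_cluster", 1)
  .check_number(mutation_rate, "mutation_rate", 0, 0.3)
  .check_number(n_decoys, "n_decoys", 0)
  .check_number(seed, "seed")
  structure(list(n_refs_per_cluster = as.integer(n_refs_per_cluster),
                 mutation_rate = mutation_rate,
                 n_decoys = as.integer(n_decoys),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# mutate a protein at non-protected sites with per-site probability `rate`
.mutate_protein <- function(chars, rate, protected) {
  free <- setdiff(seq_along(chars), protected)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  chars
}

.random_protein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

#' Generate a labelled synthetic NifH reference corpus
#'
#' Produces, per cluster, `n_refs_per_cluster` descendants of the cluster
#' anchor mutated at `mutation_rate` substitutions per site outside the
#' protected motif windows (so every valid record retains the MgATP-binding
#' motif and both 4Fe-4S ligand motifs), plus `n_decoys` motif-violating
#' proteins. Decoys cycle through four violation modes: a substitution
#' inside the MgATP motif, loss of the ligating cysteine of either 4Fe-4S
#' motif, and fully random off-target proteins (verified to contain none of
#' the motifs). Each record carries a synthetic GTDB-style lineage.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `proteins` ([Biostrings::AAStringSet]) and `truth`
#'   (data.frame: `id`, `type` (`valid`/`decoy`), `cluster`, `lineage`,
#'   `family`, `violated_rule`).
#' @export
#' @examples
#' cor <- generate_reference_corpus(corpus_spec(2, 0.05, 4, seed = 7))
#' table(cor$truth$type)
generate_reference_corpus <- function(spec) {
  if (!inherits(spec, "corpus_spec")) spec <- do.call(corpus_spec, spec)
  set.seed(spec$seed)
  anchors <- .NIFH_ANCHOR_SEQS
  protected <- .motif_positions()
  seqs <- character(0); rows <- list()

  for (cl in names(anchors)) {
    pool <- .NIFH_FAMILY_POOL[[cl]]
    base <- strsplit(anchors[[cl]], "")[[1]]
    for (k in seq_len(spec$n_refs_per_cluster)) {
      id <- sprintf("ref_%s_%03d", cl, k)
      mut <- .mutate_protein(base, spec$mutation_rate, protected)
      fam <- pool[((k - 1L) %% nrow(pool)) + 1L, ]
      lin <- .make_lineage("Bacteria", fam$phylum, fam$class, fam$order,
                           fam$family, fam$genus,
                           paste0(fam$genus, " sp", k))
      seqs[[id]] <- paste(mut, collapse = "")
      rows[[id]] <- data.frame(id = id, type = "valid", cluster = cl,
                               lineage = lin, family = fam$family,
                               violated_rule = NA_character_,
                               stringsAsFactors = FALSE)
    }
  }

  modes <- c("MgATP_mutated", "FeS_ligand_1_cys_lost",
             "FeS_ligand_2_cys_lost", "offtarget_random")
  for (k in seq_len(spec$n_decoys)) {
    id <- sprintf("decoy_%03d", k)
    mode <- modes[((k - 1L) %% length(modes)) + 1L]
    if (mode == "offtarget_random") {
      repeat {
        s <- .random_protein(nchar(anchors[[1]]))
        if (!.contains_any_motif(s)) break
      }
    } else {
      base <- strsplit(anchors[[sample(names(anchors), 1L)]], "")[[1]]
      s <- .mutate_protein(base, spec$mutation_rate, protected)
      pos <- switch(mode,
        MgATP_mutated = sample(9:17, 1L),
        FeS_ligand_1_cys_lost = 97L,
        FeS_ligand_2_cys_lost = 132L)
      s[pos] <- sample(setdiff(.AA20, c(s[pos], "C")), 1L)
      s <- paste(s, collapse = "")
    }
    seqs[[id]] <- s
    rows[[id]] <- data.frame(id = id, type = "decoy", cluster = NA_character_,
                             lineage = NA_character_, family = NA_character_,
                             violated_rule = mode, stringsAsFactors = FALSE)
  }

  proteins <- Biostrings::AAStringSet(unlist(seqs))
  list(proteins = proteins, truth = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

.contains_any_motif <- function(s) {
  any(vapply(nifh_motifs()$pattern, function(p) grepl(p, s, fixed = TRUE),
             logical(1)))
}
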