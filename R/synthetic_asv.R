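# Synthetic nifH amplicon (ASV) generator. Valid ASVs reverse-translate a
# contiguous window of a valid reference protein covering the two ligating
# cysteines; failure classes plant the artefacts the QC filter removes:
# frameshifts (1-2 nt indel), pseudogenes (ligating Cys substituted) and
# off-target sequences (random composition).

# codon table for reverse translation: uniform synonymous choice
.codons_for <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

.reverse_translate <- function(protein) {
  tab <- .codons_for()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- tab[[a]]
    if (is.null(cs)) .stop2("cannot reverse-translate residue '", a, "'")
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, character(1)), collapse = "")
}

# does any reading frame (both orientations) translate without an internal
# stop? Used to certify that planted frameshift/off-target ASVs cannot be
# rescued by frame selection.
.any_stop_free_frame <- function(nt) {
  for (s in c(nt, .revcomp(nt))) {
    for (f in 0:2) {
      aa <- .translate_frame(s, f)
      if (!grepl("*", aa, fixed = TRUE)) return(TRUE)
    }
  }
  FALSE
}

.revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

.translate_frame <- function(nt, frame) {
  sub <- substring(nt, frame + 1L)
  sub <- substring(sub, 1L, nchar(sub) %/% 3L * 3L)
  if (nchar(sub) < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}

#' Generate synthetic nifH ASVs with a ground-truth class table
#'
#' Emulates primer-trimmed PolF/PolR interior amplicons. Valid ASVs are
#' uniform-synonymous reverse translations of the reference window
#' `aa_window` (default residues 85--204, i.e. 360 nt, spanning ligating
#' cysteines 97 and 132) of randomly chosen valid corpus references.
#' Frameshift ASVs carry one internal indel of length 1 or 2 placed between
#' the two cysteine codons, and are certified (by exhaustive six-frame
#' translation) to have no stop-free reading frame, the typical fate of
#' frameshifted pseudogenes. Pseudogene ASVs substitute the codon of Cys 97
#' or Cys 132 with a non-cysteine codon. Off-target ASVs are random
#' nucleotide strings with no stop-free frame.
#'
#' @param corpus Output of [generate_reference_corpus()].
#' @param n_valid,n_frameshift,n_pseudo,n_offtarget Class counts (>= 0).
#' @param seed Integer RNG seed.
#' @param aa_window Length-2 integer vector: first and last reference
#'   residue of the amplicon window; must bracket positions 97 and 132.
#' @return List with `asvs` ([Biostrings::DNAStringSet]) and `truth`
#'   (data.frame: `asv_id`, `class`, `source_ref_id`, `true_cluster`,
#'   `true_family`).
#' @export
generate_asv_set <- function(corpus, n_valid = 20L, n_frameshift = 20L,
                             n_pseudo = 20L, n_offtarget = 20L, seed = 1L,
                             aa_window = c(85L, 204L)) {
  for (n in c(n_valid, n_frameshift, n_pseudo, n_offtarget))
    .check_number(n, "class count", 0)
  if (aa_window[1] > 97 - 4 || aa_window[2] < 132 + 4)
    .stop2("'aa_window' must bracket reference positions 97 and 132")
  valid_ids <- corpus$truth$id[corpus$truth$type == "valid"]
  if (n_valid + n_frameshift + n_pseudo > 0 && length(valid_ids) == 0)
    .stop2("corpus has no valid references")
  set.seed(as.integer(seed))

  win <- seq.int(aa_window[1], aa_window[2])
  cys_codon <- function(refpos) {
    # codon span (1-based, within the amplicon) encoding reference position
    a <- (refpos - aa_window[1]) * 3L + 1L
    c(a, a + 2L)
  }

  draw_valid_nt <- function() {
    src <- sample(valid_ids, 1L)
    prot <- as.character(corpus$proteins[[src]])
    list(src = src, nt = .reverse_translate(paste(
      strsplit(prot, "")[[1]][win], collapse = "")))
  }

  seqs <- character(0); rows <- list()
  add <- function(id, nt, class, src) {
    tr <- corpus$truth[match(src, corpus$truth$id), ]
    seqs[[id]] <<- nt
    rows[[id]] <<- data.frame(
      asv_id = id, class = class, source_ref_id = src %||% NA_character_,
      true_cluster = if (is.na(src)) NA_character_ else tr$cluster,
      true_family = if (is.na(src)) NA_character_ else tr$family,
      stringsAsFactors = FALSE)
  }

  for (k in seq_len(n_valid)) {
    v <- draw_valid_nt()
    add(sprintf("asv_valid_%03d", k), v$nt, "valid", v$src)
  }

  for (k in seq_len(n_frameshift)) {
    ok <- FALSE
    for (try in 1:100) {
      v <- draw_valid_nt()
      len <- sample(1:2, 1L)
      lo <- cys_codon(97L)[2] + 1L
      hi <- cys_codon(132L)[1] - 1L - len
      pos <- sample(seq.int(lo, hi), 1L)
      nt <- if (stats::runif(1) < 0.5) {
        paste0(substring(v$nt, 1L, pos - 1L), substring(v$nt, pos + len))
      } else {
        paste0(substring(v$nt, 1L, pos),
               paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                     collapse = ""),
               substring(v$nt, pos + 1L))
      }
      if (!.any_stop_free_frame(nt)) { ok <- TRUE; break }
    }
    if (!ok) .stop2("could not realise a frameshift decoy; widen the window")
    add(sprintf("asv_frameshift_%03d", k), nt, "frameshift", v$src)
  }

  for (k in seq_len(n_pseudo)) {
    v <- draw_valid_nt()
    target <- sample(c(97L, 132L), 1L)
    cc <- cys_codon(target)
    newaa <- sample(setdiff(.AA20, "C"), 1L)
    newcodon <- sample(.codons_for()[[newaa]], 1L)
    nt <- paste0(substring(v$nt, 1L, cc[1] - 1L), newcodon,
                 substring(v$nt, cc[2] + 1L))
    add(sprintf("asv_pseudo_%03d", k), nt, "pseudogene", v$src)
  }

  ntlen <- length(win) * 3L
  for (k in seq_len(n_offtarget)) {
    repeat {
      nt <- paste(sample(c("A", "C", "G", "T"), ntlen, replace = TRUE),
                  collapse = "")
      if (!.any_stop_free_frame(nt)) break
    }
    add(sprintf("asv_offtarget_%03d", k), nt, "offtarget", NA_character_)
  }

  truth <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
           else data.frame(asv_id = character(0), class = character(0),
                           source_ref_id = character(0),
                           true_cluster = character(0),
                           true_family = character(0))
  list(asvs = Biostrings::DNAStringSet(unlist(seqs)), truth = truth)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
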