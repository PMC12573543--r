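# Pairwise protein alignment layer. All alignment in the package funnels
# through align_protein() so scoring conventions are set in one place:
# BLOSUM62, affine gaps (open 11, extend 1), identity = matches / aligned
# columns after stripping terminal-gap columns.

.aa_check <- function(x, what = "sequence") {
  s <- as.character(x)
  if (any(nchar(s) == 0)) .stop2(what, " must be non-empty")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYXBZJUO*\\-]", toupper(s))))
    .stop2(what, " does not look like an amino-acid sequence")
  # reject obvious nucleotide input: composition almost entirely ACGTN
  frac_nt <- vapply(s, function(z) {
    z <- toupper(z)
    mean(strsplit(z, "")[[1]] %in% c("A", "C", "G", "T", "U", "N"))
  }, numeric(1))
  if (any(frac_nt > 0.95 & nchar(s) >= 30))
    .stop2(what, " looks like nucleotide sequence; translate before calling")
  invisible(s)
}

.align_params <- function() {
  list(matrix = "BLOSUM62", gap_open = 11, gap_ext = 1)
}

.load_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# identity/coverage from an aligned string pair, dropping terminal-gap columns
.aln_identity <- function(p, s) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  gap <- pc == "-" & sc == "-"
  pc <- pc[!gap]; sc <- sc[!gap]
  n <- length(pc)
  lead <- 0L
  while (lead < n && (pc[lead + 1L] == "-" || sc[lead + 1L] == "-")) lead <- lead + 1L
  trail <- 0L
  while (trail < n - lead && (pc[n - trail] == "-" || sc[n - trail] == "-")) trail <- trail + 1L
  keep <- seq.int(lead + 1L, n - trail)
  if (length(keep) == 0L) return(c(identity = 0, ncol = 0))
  c(identity = 100 * sum(pc[keep] == sc[keep]) / length(keep), ncol = length(keep))
}

#' Pairwise protein alignment
#'
#' Optimal pairwise alignment of two amino-acid sequences under BLOSUM62
#' with affine gap penalties (open 11, extend 1), the same conventions used
#' throughout the homology screen, the classifier and the QC position map.
#'
#' @param query,target Amino-acid sequences (character or
#'   [Biostrings::AAString]).
#' @param mode `"local"` (Smith-Waterman) or `"global_free_ends"`
#'   (Needleman-Wunsch with cost-free terminal gaps; alias `"overlap"`).
#' @return A list with `score`, `identity` (percent over aligned columns,
#'   terminal-gap columns excluded), `aligned_query`, `aligned_target`
#'   (gapped strings), and `query_range`/`target_range` (1-based aligned
#'   coordinate spans).
#' @export
#' @examples
#' align_protein("PGVGCVF", "PGVGCVF")$identity
align_protein <- function(query, target,
                          mode = c("local", "global_free_ends", "overlap")) {
  mode <- match.arg(mode)
  .aa_check(query, "query"); .aa_check(target, "target")
  type <- if (mode == "local") "local" else "overlap"
  par <- .align_params()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as.character(query)),
    Biostrings::AAString(as.character(target)),
    substitutionMatrix = .load_submat(),
    gapOpening = par$gap_open, gapExtension = par$gap_ext,
    type = type
  )
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  idn <- .aln_identity(p, s)
  list(
    score = Biostrings::score(aln),
    identity = unname(idn["identity"]),
    aligned_query = p,
    aligned_target = s,
    query_range = c(IRanges::start(Biostrings::pattern(aln)),
                    IRanges::end(Biostrings::pattern(aln))),
    target_range = c(IRanges::start(Biostrings::subject(aln)),
                     IRanges::end(Biostrings::subject(aln)))
  )
}

# reference-anchored multiple alignment: each sequence is aligned to the
# anchor (free end gaps) and projected onto anchor columns; insertions
# relative to the anchor are dropped. Exact for the package's scaffold-based
# sequences, which are homologous without indels.
#' Reference-anchored protein alignment matrix
#'
#' Builds an alignment matrix by aligning every sequence to one anchor
#' sequence (the longest, by default) with free terminal gaps and projecting
#' residues onto the anchor's columns. Insertions relative to the anchor are
#' discarded, so the result has exactly `nchar(anchor)` columns.
#'
#' @param proteins Named [Biostrings::AAStringSet] (or named character).
#' @param anchor Anchor id (name in `proteins`); default the longest entry.
#' @return Character matrix (rows = sequences, columns = anchor positions),
#'   gaps as `"-"`.
#' @export
anchor_msa <- function(proteins, anchor = NULL) {
  seqs <- as.character(proteins)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    .stop2("'proteins' must have unique names")
  if (is.null(anchor)) anchor <- names(seqs)[which.max(nchar(seqs))]
  if (!anchor %in% names(seqs)) .stop2("anchor '", anchor, "' not in input")
  ref <- seqs[[anchor]]
  L <- nchar(ref)
  out <- matrix("-", nrow = length(seqs), ncol = L,
                dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    if (names(seqs)[i] == anchor) {
      out[i, ] <- strsplit(ref, "")[[1]]
      next
    }
    al <- align_protein(seqs[[i]], ref, mode = "global_free_ends")
    qc <- strsplit(al$aligned_query, "")[[1]]
    tc <- strsplit(al$aligned_target, "")[[1]]
    refpos <- al$target_range[1] - 1L
    for (k in seq_along(tc)) {
      if (tc[k] != "-") {
        refpos <- refpos + 1L
        out[i, refpos] <- qc[k]
      }
    }
  }
  out
}

# p-distance / Poisson-corrected distance from an alignment matrix
.msa_dist <- function(msa, distance = c("poisson", "p_distance")) {
  distance <- match.arg(distance)
  n <- nrow(msa)
  d <- matrix(0, n, n, dimnames = list(rownames(msa), rownames(msa)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- msa[i, ] != "-" & msa[j, ] != "-"
    if (!any(ok))
      .stop2("no shared aligned columns between '", rownames(msa)[i],
             "' and '", rownames(msa)[j], "'")
    p <- mean(msa[i, ok] != msa[j, ok])
    if (distance == "poisson") {
      if (p >= 1) .stop2("saturated distance between '", rownames(msa)[i],
                         "' and '", rownames(msa)[j], "'")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  stats::as.dist(d)
}
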