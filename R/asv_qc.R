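# Translation-based ASV quality control: find the reading frame, map the
# translation onto the numbering reference, and require the two 4Fe-4S
# ligating cysteines (reference positions 97 and 132). Sequences failing
# any step are removed (not repaired), with a per-ASV reason code.

#' Ligating-cysteine QC rule
#'
#' @param positions Reference positions that must be cysteine (1-based on
#'   the full-length numbering reference).
#' @param residue Required residue (default `"C"`).
#' @param reference Numbering reference protein
#'   ([nifh_reference_protein()]).
#' @return List of class `qc_rule`.
#' @export
qc_rule <- function(positions = c(97L, 132L), residue = "C",
                    reference = nifh_reference_protein()) {
  structure(list(positions = as.integer(positions), residue = residue,
                 reference = Biostrings::AAString(as.character(reference))),
            class = "qc_rule")
}

#' Find the reading frame of a nifH amplicon
#'
#' Translates the three forward frames; frames containing an internal stop
#' are disqualified. Among stop-free frames the one with the highest local
#' alignment score to the reference protein wins (ties: lowest frame
#' index). If no forward frame is stop-free, or the best forward score
#' falls below `score_floor`, the reverse complement is tried the same way
#' (merged-read orientation can flip even though the protocol fixes
#' amplicon orientation). Ambiguous bases translate to `X`.
#'
#' @param nt_sequence Nucleotide sequence (character or DNAString), >= 60 nt.
#' @param reference Reference protein for scoring.
#' @param score_floor Forward score below which the reverse complement is
#'   also attempted.
#' @return List with `frame` (0/1/2 or `NA` if no stop-free frame),
#'   `orientation` (`"forward"`/`"reverse"`), `translation`, `score`.
#' @export
find_reading_frame <- function(nt_sequence,
                               reference = nifh_reference_protein(),
                               score_floor = 50) {
  nt <- toupper(as.character(nt_sequence))
  if (nchar(nt) < 60) .stop2("sequence shorter than 60 nt")
  ref <- as.character(reference)

  scan <- function(s) {
    best <- NULL
    for (f in 0:2) {
      aa <- .translate_frame(s, f)
      if (nchar(aa) == 0 || grepl("*", aa, fixed = TRUE)) next
      sc <- align_protein(aa, ref, mode = "local")$score
      if (is.null(best) || sc > best$score)
        best <- list(frame = f, translation = aa, score = sc)
    }
    best
  }

  fwd <- scan(nt)
  if (is.null(fwd) || fwd$score < score_floor) {
    rev <- scan(.revcomp(nt))
    if (!is.null(rev) && (is.null(fwd) || rev$score > fwd$score))
      return(c(rev, orientation = "reverse"))
  }
  if (is.null(fwd))
    return(list(frame = NA_integer_, translation = NA_character_,
                score = NA_real_, orientation = "forward"))
  c(fwd, orientation = "forward")
}

#' Map a translation onto reference protein numbering
#'
#' Global alignment with cost-free terminal gaps; every reference position
#' covered by the alignment is reported with the aligned query residue
#' (`"-"` for a deletion). The map is monotone in both coordinates.
#'
#' @param translation Amino-acid sequence (query).
#' @param reference Numbering reference protein.
#' @return Data.frame `ref_pos`, `query_pos` (`NA` at deletions),
#'   `residue`.
#' @export
map_to_reference_numbering <- function(translation,
                                       reference = nifh_reference_protein()) {
  q <- as.character(translation)
  if (nchar(q) == 0) .stop2("empty translation")
  al <- align_protein(q, as.character(reference), mode = "global_free_ends")
  qc <- strsplit(al$aligned_query, "")[[1]]
  tc <- strsplit(al$aligned_target, "")[[1]]
  ref_pos <- al$target_range[1] - 1L
  q_pos <- al$query_range[1] - 1L
  rows <- vector("list", length(tc))
  for (k in seq_along(tc)) {
    if (qc[k] != "-") q_pos <- q_pos + 1L
    if (tc[k] != "-") {
      ref_pos <- ref_pos + 1L
      rows[[k]] <- data.frame(ref_pos = ref_pos,
                              query_pos = if (qc[k] == "-") NA_integer_ else q_pos,
                              residue = qc[k], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Check the 4Fe-4S ligating cysteines
#'
#' @param position_map Data.frame from [map_to_reference_numbering()].
#' @param rule A [qc_rule()].
#' @return List with `pass`, `covered` (all rule positions inside the
#'   aligned span) and `residues` (named by reference position; `NA` when
#'   not covered).
#' @export
check_ligating_cysteines <- function(position_map, rule = qc_rule()) {
  res <- setNames(position_map$residue[match(rule$positions,
                                             position_map$ref_pos)],
                  rule$positions)
  covered <- !any(is.na(res))
  list(pass = covered && all(res == rule$residue),
       covered = covered, residues = res)
}

#' Filter an ASV set on translatability and ligating cysteines
#'
#' Applies [find_reading_frame()], [map_to_reference_numbering()] and
#' [check_ligating_cysteines()] to every ASV. An ASV is retained iff a
#' stop-free frame exists, the alignment covers both required positions,
#' and both carry cysteine. Reason codes: `no_frame`,
#' `region_not_covered`, `cys_absent`.
#'
#' @param asvs Nucleotide sequences ([Biostrings::DNAStringSet] or named
#'   character).
#' @param rule A [qc_rule()].
#' @param score_floor Passed to [find_reading_frame()].
#' @return List with `retained` (DNAStringSet), `proteins` (AAStringSet of
#'   retained translations) and `report` (data.frame `asv_id`, `status`,
#'   `reason`, `frame`, `orientation`, and the residue observed at each
#'   rule position).
#' @export
#' @examples
#' cor <- generate_reference_corpus(corpus_spec(2, 0.05, 0, seed = 1))
#' gen <- generate_asv_set(cor, n_valid = 3, n_frameshift = 0,
#'                         n_pseudo = 2, n_offtarget = 0, seed = 1)
#' qc <- qc_filter(gen$asvs)
#' table(qc$report$reason)
qc_filter <- function(asvs, rule = qc_rule(), score_floor = 50) {
  if (is.character(asvs)) asvs <- Biostrings::DNAStringSet(asvs)
  n <- length(asvs)
  if (n > 0 && is.null(names(asvs))) names(asvs) <- paste0("asv", seq_len(n))
  rescols <- paste0("residue_", rule$positions)
  report <- data.frame(asv_id = if (n) names(asvs) else character(0),
                       status = character(n), reason = character(n),
                       frame = rep(NA_integer_, n),
                       orientation = rep(NA_character_, n),
                       stringsAsFactors = FALSE)
  for (rc in rescols) report[[rc]] <- rep(NA_character_, n)
  if (n == 0)
    return(list(retained = asvs, proteins = Biostrings::AAStringSet(),
                report = report))

  keep <- logical(n)
  prots <- character(n)
  for (i in seq_len(n)) {
    fr <- find_reading_frame(asvs[[i]], rule$reference, score_floor)
    report$frame[i] <- fr$frame
    report$orientation[i] <- fr$orientation
    if (is.na(fr$frame)) {
      report$status[i] <- "removed"; report$reason[i] <- "no_frame"
      next
    }
    map <- map_to_reference_numbering(fr$translation, rule$reference)
    chk <- check_ligating_cysteines(map, rule)
    report[i, rescols] <- unname(chk$residues)
    if (!chk$covered) {
      report$status[i] <- "removed"; report$reason[i] <- "region_not_covered"
    } else if (!chk$pass) {
      report$status[i] <- "removed"; report$reason[i] <- "cys_absent"
    } else {
      report$status[i] <- "retained"; report$reason[i] <- "pass"
      keep[i] <- TRUE
      prots[i] <- fr$translation
    }
  }
  proteins <- Biostrings::AAStringSet(setNames(prots[keep], names(asvs)[keep]))
  list(retained = asvs[keep], proteins = proteins, report = report)
}
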