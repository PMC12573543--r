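# Hand-built NifH-like protein scaffolds (~290 aa) used as cluster anchors
# and as the numbering reference. All five share one architecture:
#   MgATP-binding motif YGKGGGIGK at positions 9-17,
#   4Fe-4S ligand motif PGVGC at 93-97  (ligating Cys at 97),
#   4Fe-4S ligand motif VVCGG at 130-134 (ligating Cys at 132).
# Outside the motif windows the anchors diverge (~50% pairwise identity),
# giving four well-separated clusters. These are SYNTHETIC sequences: they
# reproduce the canonical NifH motif placement and Azotobacter vinelandii
# Cys numbering but are not database accessions.

.NIFH_ANCHOR_SEQS <- c(
  I   = "MAADQTHMYGKGGGIGKEGLFVIEKLPHGKAEMAKVDGDGVELVKAALSKNPSLLAEDKDTGLKTTESKSVPFLGDPVEGSSNINWDQFAFRPGVGCVFVIKDSMATFVALMGGRGGVSIRNRRRSGDEVVCGGILFTLMEQTKGLHFKCIQPECTTLASYLDRIDSPKGSELVDIVDSHVAESLIQWLMRRLDRCWVKDCARPPADNIPGGLAAEAIIHIVPLFLFDLFEIRTMAVQCLPAEEKMKQSGATTQFVASPEKIAIRTYDAGLFQGAPGAGAAANKYMIRDM",
  II  = "MFLQRLQEYGKGGGIGKSGLGIAEYVPNGYAESAHVEGDGVLGLGASLLKNPSQLQVDKKVALKTMCSKSVPFQISRREKLRSINSETIEFRPGVGCVFNILEMQAQFNVLMNFCVHVSIVEIRGVRDEVVCGGILFTDMEKEYQLMFKSILVKYPQLASYNLSINSPIGLEYEDYSDSHVAESPPEWAMRRLDRCWVHVDARTPNTLIHKRAFAEAIDHEVEKGAFYLVLIRTQSTQKTAALEAVKASGELPQAYMEMILINFALLCYAHFISAPGACDGAPFALDRDM",
  III = "MVLDQLQMYGKGGGIGKIEKFVAGQMPEGEAESNKVEHKGSHGDPELLLKNVSVELTLKLVGLKVTESKSNPGLGIDREGQSNINSIFFAFEPGVGCVFNILDAQEAFNKDMVSGAHVVNVETMRLRREVVCGGLLFTDMEEAKQLHQLVLQVKCTTLASYHDSINSPIAPEKPKYVDSHSTEAPNEWRYIRLSRCWVKPCARIYNPRIRDSTFAEAIDHPVSKFHEYLFLGRTQATQKGEAEEKVKINKRPVNAVTSDKLQNMNGIIRAHEIGAPTVCDGEMTYSLRDM",
  IV  = "MALDQLNGYGKGGGIGKTLLFVTEKLPNGEAELARGETQGKSGLKASLEKNPSIAEVEKLALLGTTESKSVPHEGDDNELLSNINYYFVAEIPGVGCVFCALDVSAYVNPLMVEIPHVSIVEGRRVRDVVVCGGILFNDMEKEKQEHFKVIQVKRATLASYQDQQNSPIGKRLWAYVPGTQAESPLEWRMRRLENCWVALCMLEPVNIIRDRDFFERIDMIVEKFLFYLFEIQDQNKQSGYAQEKVKTTGELAIAVPSPEIINFLTIFAAHTIYTPGAIDTLNPGMDADM"
)

.NIFH_REFERENCE_SEQ <-
  "MAADQTLMYGKGGGIGKEELFVIEKLPHGKALMAKVDGDPVELVKADLSKNPSLSIEYFDTSLKTTESKSVAFDGDPVEGSLNINWDQFAFRPGVGCVFVIKDSMATFVALMGERGGVSIRNRRRSGDEVVCGGILATLEEQTKILHFKSIQPGCTTLASTLDRIDSPGGSELVDIVDSHAAESLIWALMRRLQDCWVKDCVEPPGDNIPGGLAAEFIIHIVLLFLFDLLEIRTMAVQCLPAEEKMSQKGATTWFVASDEKIAHRAYVAGLFQGAPGAGAAANKYMIRDM"

# synthetic GTDB-style family pools per cluster, mirroring the taxa a
# paddy-soil diazotroph survey recovers (iron oxidisers and reducers in
# cluster I, anaerobes in cluster III)
.NIFH_FAMILY_POOL <- list(
  I = data.frame(
    phylum = c("Pseudomonadota", "Desulfobacterota", "Pseudomonadota",
               "Pseudomonadota", "Pseudomonadota", "Pseudomonadota"),
    class  = c("Gammaproteobacteria", "Desulfuromonadia", "Alphaproteobacteria",
               "Gammaproteobacteria", "Alphaproteobacteria", "Gammaproteobacteria"),
    order  = c("Gallionellales", "Geobacterales", "Rhizobiales",
               "Burkholderiales", "Rhizobiales", "Methylococcales"),
    family = c("Gallionellaceae", "Geobacteraceae", "Beijerinckiaceae",
               "Burkholderiaceae", "Xanthobacteraceae", "Methylococcaceae"),
    genus  = c("Sideroxyarcus", "Geobacter", "Methylocella",
               "Paraburkholderia", "Azorhizobium", "Methylomonas"),
    stringsAsFactors = FALSE),
  II = data.frame(
    phylum = "Myxococcota", class = "Myxococcia", order = "Anaeromyxobacterales",
    family = "Anaeromyxobacteraceae", genus = "Anaeromyxobacter",
    stringsAsFactors = FALSE),
  III = data.frame(
    phylum = c("Desulfobacterota", "Halobacteriota", "Bacillota"),
    class  = c("Desulfovibrionia", "Methanosarcinia", "Clostridia"),
    order  = c("Desulfovibrionales", "Methanosarcinales", "Clostridiales"),
    family = c("Desulfovibrionaceae", "Methanosarcinaceae", "Clostridiaceae"),
    genus  = c("Desulfovibrio", "Methanosarcina", "Clostridium"),
    stringsAsFactors = FALSE),
  IV = data.frame(
    phylum = "Chloroflexota", class = "Chloroflexia", order = "Chloroflexales",
    family = "Roseiflexaceae", genus = "Roseiflexus",
    stringsAsFactors = FALSE)
)

#' NifH cluster anchor proteins
#'
#' Four synthetic ~290-residue NifH-like proteins, one per canonical NifH
#' cluster (I--IV), sharing the conserved MgATP-binding and 4Fe-4S ligand
#' motifs at fixed offsets and diverging elsewhere. They serve as cluster
#' labels for classification and as the mutational scaffolds of the
#' synthetic corpus generator.
#'
#' @return An [Biostrings::AAStringSet] of length 4 named `anchor_I` ..
#'   `anchor_IV`, with a `cluster` entry in its metadata columns.
#' @export
#' @examples
#' nifh_anchor_proteins()
nifh_anchor_proteins <- function() {
  x <- Biostrings::AAStringSet(.NIFH_ANCHOR_SEQS)
  names(x) <- paste0("anchor_", names(.NIFH_ANCHOR_SEQS))
  S4Vectors::mcols(x)$cluster <- names(.NIFH_ANCHOR_SEQS)
  x
}

#' Numbering reference protein for ligating-cysteine QC
#'
#' The single full-length protein onto which ASV translations are mapped so
#' that residue positions can be reported in the conventional Azotobacter
#' vinelandii NifH numbering. It is a synthetic cluster-I-like scaffold
#' (87% identical to the cluster-I anchor) carrying the canonical motif
#' architecture: the 4Fe-4S ligating cysteines sit at positions 97 and 132,
#' inside the `PGVGC` and `VVCGG` motifs.
#'
#' @return A single [Biostrings::AAString].
#' @export
nifh_reference_protein <- function() {
  Biostrings::AAString(.NIFH_REFERENCE_SEQ)
}

#' Conserved NifH motif definitions
#'
#' The three cysteine-containing conserved motifs used to validate NifH
#' homologs: the MgATP binding site `YGKGGGIGK` and the two 4Fe-4S ligand
#' motifs `PGVGC` and `VVCGG`. Matching is exact by default; a per-motif
#' mismatch budget can be granted because the canonical motif list is
#' representative rather than exhaustive.
#'
#' @param max_mismatches Integer vector (length 1 or 3) of allowed
#'   mismatches per motif. Default 0 (exact).
#' @return A data.frame with columns `name`, `pattern`, `max_mismatches`.
#' @export
nifh_motifs <- function(max_mismatches = 0L) {
  if (any(max_mismatches < 0)) .stop2("'max_mismatches' must be >= 0")
  data.frame(
    name = c("MgATP_binding", "FeS_ligand_1", "FeS_ligand_2"),
    pattern = c("YGKGGGIGK", "PGVGC", "VVCGG"),
    max_mismatches = as.integer(rep_len(max_mismatches, 3L)),
    stringsAsFactors = FALSE
  )
}

#' PolF/PolR nifH primer pair
#'
#' The degenerate primer pair whose interior the amplicons emulate.
#'
#' @return Named character vector with `forward` and `reverse` primers
#'   (IUPAC degenerate nucleotide codes).
#' @export
nifh_primers <- function() {
  c(forward = "TGCGAYCCSAARGCBGACTC", reverse = "ATSGCCATCATYTCRCCGGA")
}

# positions protected from mutation in valid references (motif windows)
.motif_positions <- function() {
  m <- nifh_motifs()
  starts <- c(MgATP_binding = 9L, FeS_ligand_1 = 93L, FeS_ligand_2 = 130L)
  unlist(lapply(seq_len(nrow(m)), function(i)
    seq(starts[[m$name[i]]], length.out = nchar(m$pattern[i]))))
}

# GTDB-style 7-rank semicolon lineage
.make_lineage <- function(domain, phylum, class, order, family, genus, species) {
  paste(paste0(c("d__", "p__", "c__", "o__", "f__", "g__", "s__"),
               c(domain, phylum, class, order, family, genus, species)),
        collapse = ";")
}

#' Split a 7-rank lineage string into rank columns
#'
#' @param lineage Character vector of semicolon-delimited lineages with
#'   `d__`/`p__`/.../`s__` prefixes (missing ranks may be empty).
#' @return A data.frame with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`, `species`.
#' @export
parse_lineage <- function(lineage) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus", "species")
  parts <- strsplit(lineage, ";", fixed = TRUE)
  out <- lapply(seq_along(ranks), function(i) {
    vapply(parts, function(p) {
      if (length(p) >= i) sub("^[a-z]__", "", p[i]) else ""
    }, character(1))
  })
  names(out) <- ranks
  as.data.frame(out, stringsAsFactors = FALSE)
}
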