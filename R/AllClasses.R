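#' @import methods
NULL

AA_STANDARD20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")
AA_AMBIGUOUS  <- c("B","X","Z","U","O")

#' Proteolytic digestion parameters
#'
#' Holds the cleavage rule and filters used throughout digestion,
#' shared-peptide detection and trimming. The defaults (no missed
#' cleavages, minimum peptide length 7, trypsin with the proline
#' exception) are the settings the trimming workflow is designed
#' around: peptides shorter than seven residues are generally not
#' identifiable by shotgun MS and are never considered shared.
#'
#' @slot rule Cleavage rule, one of \code{"trypsin_strict"} (cleave
#'   C-terminal to K or R, but not when the next residue is P) or
#'   \code{"trypsin_p"} (cleave after every K or R).
#' @slot missedCleavages Non-negative integer; maximum number of
#'   internal uncut sites a reported peptide may span.
#' @slot minLen Minimum peptide length retained in a [PeptideIndex].
#' @export
setClass("DigestParams", representation(
  rule = "character",
  missedCleavages = "integer",
  minLen = "integer"
))

setValidity("DigestParams", function(object) {
  msg <- character()
  if (length(object@rule) != 1L ||
      !object@rule %in% c("trypsin_strict", "trypsin_p"))
    msg <- c(msg, "rule must be 'trypsin_strict' or 'trypsin_p'")
  if (length(object@missedCleavages) != 1L || is.na(object@missedCleavages) ||
      object@missedCleavages < 0L)
    msg <- c(msg, "missedCleavages must be a single integer >= 0")
  if (length(object@minLen) != 1L || is.na(object@minLen) ||
      object@minLen < 1L)
    msg <- c(msg, "minLen must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname DigestParams-class
#' @param rule,missedCleavages,minLen See slot descriptions.
#' @return A \code{DigestParams} object.
#' @examples
#' DigestParams()                       # workflow defaults
#' DigestParams("trypsin_p", missedCleavages = 2)
#' @export
DigestParams <- function(rule = c("trypsin_strict", "trypsin_p"),
                         missedCleavages = 0L, minLen = 7L) {
  rule <- match.arg(rule)
  new("DigestParams", rule = rule,
      missedCleavages = as.integer(missedCleavages),
      minLen = as.integer(minLen))
}

#' Species-labelled protein collection
#'
#' A set of protein sequences from one community member species: the
#' unit that is digested, compared against the other members, and
#' trimmed. Record order is preserved from input to output.
#'
#' @slot species Single species label (supplied by the caller, never
#'   parsed from FASTA headers).
#' @slot sequences An [Biostrings::AAStringSet] whose names are the
#'   protein identifiers (unique, no whitespace).
#' @slot descriptions Free-text description per record (may be "").
#' @export
setClass("Proteome", representation(
  species = "character",
  sequences = "AAStringSet",
  descriptions = "character"
))

setValidity("Proteome", function(object) {
  msg <- character()
  ids <- names(object@sequences)
  if (length(object@species) != 1L || is.na(object@species) ||
      !nzchar(object@species))
    msg <- c(msg, "species must be a single non-empty string")
  if (is.null(ids) && length(object@sequences))
    msg <- c(msg, "sequences must be named by protein_id")
  if (!is.null(ids)) {
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate protein_id: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(grepl("\\s", ids)))
      msg <- c(msg, "protein_id must not contain whitespace")
  }
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "empty sequences are not allowed in a Proteome")
  if (length(object@descriptions) != length(object@sequences))
    msg <- c(msg, "descriptions must have one entry per record")
  if (length(msg)) msg else TRUE
})

#' @rdname Proteome-class
#' @param species Species label for every record.
#' @param sequences Named character vector or \code{AAStringSet} of
#'   amino-acid sequences; names are protein identifiers.
#' @param descriptions Optional per-record description.
#' @param onNonstandard What to do with residues outside the 20
#'   standard amino acids plus ambiguity codes B, X, Z, U, O:
#'   \code{"error"} (default) or \code{"warn"} and keep.
#' @return A \code{Proteome}.
#' @examples
#' Proteome("A", c(p1 = "MKRAAAK", p2 = "SSSSSSSK"))
#' @export
Proteome <- function(species, sequences,
                     descriptions = NULL,
                     onNonstandard = c("error", "warn")) {
  onNonstandard <- match.arg(onNonstandard)
  if (is(sequences, "AAStringSet")) {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
  } else {
    seqs <- as.character(sequences)
    names(seqs) <- names(sequences)
  }
  seqs <- toupper(gsub("\\s", "", seqs))
  seqs <- sub("\\*+$", "", seqs)          # terminal stop codons only
  if (any(grepl("*", seqs, fixed = TRUE)))
    stop("internal '*' in sequence(s): ",
         paste(names(seqs)[grepl("*", seqs, fixed = TRUE)], collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence(s): ",
         paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  ok <- paste0("^[", paste(c(AA_STANDARD20, AA_AMBIGUOUS), collapse = ""), "]*$")
  bad <- !grepl(ok, seqs)
  if (any(bad)) {
    txt <- sprintf("sequence(s) with residues outside %s: %s",
                   "ACDEFGHIKLMNPQRSTVWY+BXZUO",
                   paste(names(seqs)[bad], collapse = ", "))
    if (onNonstandard == "error") stop(txt) else warning(txt)
  }
  amb <- grepl(paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]"), seqs)
  if (any(amb))
    message(sum(amb), " record(s) contain ambiguity codes (B/X/Z/U/O)")
  if (is.null(descriptions)) descriptions <- rep("", length(seqs))
  new("Proteome", species = as.character(species),
      sequences = Biostrings::AAStringSet(seqs),
      descriptions = as.character(descriptions))
}

#' Digested-peptide index for one species
#'
#' All tryptic peptides of one proteome that pass the minimum-length
#' filter, with 0-based half-open coordinates on their parent protein.
#' Peptides containing an ambiguity code (B/X/Z/U/O) cannot be matched
#' confidently between species and are excluded (but tallied).
#'
#' @slot species Species label.
#' @slot table data.frame with columns \code{peptide}, \code{protein_id},
#'   \code{start}, \code{end}, \code{n_missed}, sorted by
#'   (peptide, protein_id, start).
#' @slot params The [DigestParams] used.
#' @slot nAmbiguous Number of length-passing peptides excluded for
#'   containing ambiguity codes.
#' @export
setClass("PeptideIndex", representation(
  species = "character",
  table = "data.frame",
  params = "DigestParams",
  nAmbiguous = "integer"
))

setValidity("PeptideIndex", function(object) {
  msg <- character()
  need <- c("peptide", "protein_id", "start", "end", "n_missed")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns", paste(need, collapse = ", ")))
  else {
    tb <- object@table
    if (nrow(tb)) {
      if (any(nchar(tb$peptide) < object@params@minLen))
        msg <- c(msg, "indexed peptide shorter than minLen")
      if (any(tb$end - tb$start != nchar(tb$peptide)))
        msg <- c(msg, "coordinates inconsistent with peptide length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Peptides shared between two or more species
#'
#' @slot peptides Character vector of shared peptide strings (after
#'   optional I/L collapsing).
#' @slot membership Long-format data.frame (\code{peptide},
#'   \code{species}) recording which species contain each peptide.
#' @slot ilEquivalent Whether I and L were collapsed before matching.
#' @export
setClass("SharedPeptideSet", representation(
  peptides = "character",
  membership = "data.frame",
  ilEquivalent = "logical"
))

#' Pairwise proteome overlap
#'
#' Symmetric counts of distinct digested peptides shared between each
#' species pair, plus row-normalised percentages: the same shared count
#' is a different percentage of each species' peptide universe, which
#' is why the percentage matrix is asymmetric.
#'
#' @slot counts Symmetric integer matrix; the diagonal holds each
#'   species' own distinct-peptide total.
#' @slot totals Named distinct-peptide totals per species.
#' @slot percentages \code{100 * counts[a,b] / totals[a]}.
#' @export
setClass("OverlapMatrix", representation(
  counts = "matrix",
  totals = "numeric",
  percentages = "matrix"
))

#' Result of shared-peptide trimming
#'
#' @slot trimmedProteomes Named list of [Proteome] objects (records
#'   trimmed to zero length are dropped from the proteome but retained
#'   in \code{records}).
#' @slot records Per-protein data.frame: species, protein_id,
#'   n_peptides_removed, n_residues_removed, original_length,
#'   trimmed_length, became_empty.
#' @slot spans Removed spans on the ORIGINAL sequences: species,
#'   protein_id, start, end (0-based half-open), peptide, round.
#' @slot shared The [SharedPeptideSet] detected on the input proteomes.
#' @slot residualShared Shared peptides still present after trimming,
#'   found by a verification re-digest (empty in fixpoint mode).
#' @slot params [DigestParams] used.
#' @slot mode "single_pass" or "fixpoint".
#' @slot nRounds Number of trim rounds executed.
#' @export
setClass("TrimResult", representation(
  trimmedProteomes = "list",
  records = "data.frame",
  spans = "data.frame",
  shared = "SharedPeptideSet",
  residualShared = "SharedPeptideSet",
  params = "DigestParams",
  mode = "character",
  nRounds = "integer"
))

setValidity("TrimResult", function(object) {
  msg <- character()
  rec <- object@records
  if (nrow(rec)) {
    if (any(rec$trimmed_length !=
            rec$original_length - rec$n_residues_removed))
      msg <- c(msg, "trimmed_length must equal original_length - n_residues_removed")
  }
  if (object@mode == "fixpoint" && length(object@residualShared@peptides))
    msg <- c(msg, "fixpoint mode must leave no residual shared peptides")
  if (length(msg)) msg else TRUE
})

#' Two-group differential abundance result
#'
#' @slot table Per-protein data.frame: protein_id, n1, n2, mean1,
#'   mean2, log2_difference (group1 - group2), d (S0-moderated Welch
#'   statistic), significant.
#' @slot cutoff Chosen |d| cutoff (Inf when nothing reaches the FDR
#'   threshold).
#' @slot fdrAtCutoff Estimated FDR at the chosen cutoff.
#' @slot nSignificant Number of flagged proteins.
#' @slot fdrCurve data.frame of candidate cutoffs and their (monotone)
#'   estimated FDR.
#' @slot s0,alpha,nPermutations Test configuration actually used.
#' @slot exhaustive TRUE when all distinct relabelings were enumerated.
#' @export
setClass("DiffResult", representation(
  table = "data.frame",
  cutoff = "numeric",
  fdrAtCutoff = "numeric",
  nSignificant = "integer",
  fdrCurve = "data.frame",
  s0 = "numeric",
  alpha = "numeric",
  nPermutations = "integer",
  exhaustive = "logical"
))

setValidity("DiffResult", function(object) {
  tb <- object@table
  if (nrow(tb) && is.finite(object@cutoff) &&
      any(tb$significant & abs(tb$d) < object@cutoff))
    return("significant proteins must satisfy |d| >= cutoff")
  TRUE
})

#' Pathway over-representation result
#'
#' One row per (pathway, direction): the 2x2 table counts a
#' (changed-in-pathway), b (changed-not-in-pathway), c
#' (unchanged-in-pathway), g (unchanged-not-in-pathway), odds ratio,
#' raw and BH-adjusted one-sided p, the pathway's share of the
#' annotated proteome and the pathway's share of the changed set.
#'
#' @slot table data.frame sorted by adjusted p within direction.
#' @slot universeSize Number of proteins in the annotation universe.
#' @slot nUnannotated Named count of changed proteins per direction
#'   that had no pathway annotation (tested sets are intersected with
#'   the universe first).
#' @export
setClass("EnrichmentResult", representation(
  table = "data.frame",
  universeSize = "integer",
  nUnannotated = "integer"
))
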