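#' Accessors
#'
#' Small accessor generics for the package's S4 classes.
#'
#' @param x An object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))

#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname accessors
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname accessors
#' @export
setGeneric("occurrences", function(x) standardGeneric("occurrences"))

#' @rdname accessors
#' @export
setGeneric("digestParams", function(x) standardGeneric("digestParams"))

#' @rdname accessors
#' @export
setGeneric("sharedPeptides", function(x) standardGeneric("sharedPeptides"))

#' @rdname accessors
#' @export
setGeneric("trimmedProteomes", function(x) standardGeneric("trimmedProteomes"))

#' @rdname accessors
#' @export
setGeneric("trimRecords", function(x) standardGeneric("trimRecords"))

#' @rdname accessors
#' @export
setGeneric("removedSpans", function(x) standardGeneric("removedSpans"))

#' @rdname accessors
#' @export
setGeneric("residualShared", function(x) standardGeneric("residualShared"))

#' @rdname accessors
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))

#' @rdname accessors
#' @export
setGeneric("overlapPercentages", function(x) standardGeneric("overlapPercentages"))

#' @rdname accessors
#' @export
setGeneric("resultTable", function(x) standardGeneric("resultTable"))

setMethod("speciesName", "Proteome", function(x) x@species)
setMethod("speciesName", "PeptideIndex", function(x) x@species)
setMethod("proteinIds", "Proteome", function(x) names(x@sequences))
setMethod("nProteins", "Proteome", function(x) length(x@sequences))
setMethod("peptides", "PeptideIndex", function(x) unique(x@table$peptide))
setMethod("peptides", "SharedPeptideSet", function(x) x@peptides)
setMethod("occurrences", "PeptideIndex", function(x) x@table)
setMethod("digestParams", "PeptideIndex", function(x) x@params)
setMethod("digestParams", "TrimResult", function(x) x@params)
setMethod("sharedPeptides", "TrimResult", function(x) x@shared)
setMethod("trimmedProteomes", "TrimResult", function(x) x@trimmedProteomes)
setMethod("trimRecords", "TrimResult", function(x) x@records)
setMethod("removedSpans", "TrimResult", function(x) x@spans)
setMethod("residualShared", "TrimResult", function(x) x@residualShared)
setMethod("overlapCounts", "OverlapMatrix", function(x) x@counts)
setMethod("overlapPercentages", "OverlapMatrix", function(x) x@percentages)
setMethod("resultTable", "DiffResult", function(x) x@table)
setMethod("resultTable", "EnrichmentResult", function(x) x@table)

#' Extract protein sequences as a character vector
#'
#' @param x A [Proteome].
#' @return Named character vector of sequences.
#' @export
setGeneric("proteinSequences", function(x) standardGeneric("proteinSequences"))

setMethod("proteinSequences", "Proteome", function(x) {
  s <- as.character(x@sequences)
  names(s) <- names(x@sequences)
  s
})

setMethod("show", "Proteome", function(object) {
  cat("Proteome of species '", object@species, "': ",
      length(object@sequences), " protein(s), ",
      sum(Biostrings::width(object@sequences)), " residues\n", sep = "")
})

setMethod("show", "DigestParams", function(object) {
  cat("DigestParams: rule=", object@rule,
      ", missedCleavages=", object@missedCleavages,
      ", minLen=", object@minLen, "\n", sep = "")
})

setMethod("show", "PeptideIndex", function(object) {
  cat("PeptideIndex for species '", object@species, "': ",
      length(unique(object@table$peptide)), " distinct peptide(s), ",
      nrow(object@table), " occurrence(s); ",
      object@nAmbiguous, " excluded for ambiguity codes\n", sep = "")
})

setMethod("show", "SharedPeptideSet", function(object) {
  cat("SharedPeptideSet: ", length(object@peptides),
      " peptide(s) shared between >= 2 species",
      if (isTRUE(object@ilEquivalent)) " (I/L collapsed)" else "",
      "\n", sep = "")
})

setMethod("show", "OverlapMatrix", function(object) {
  cat("OverlapMatrix over", nrow(object@counts), "species\n")
  cat("counts (diagonal = distinct-peptide totals):\n")
  print(object@counts)
  cat("percentages of row species' peptides:\n")
  print(round(object@percentages, 2))
})

setMethod("show", "TrimResult", function(object) {
  cat("TrimResult (", object@mode, ", ", object@nRounds, " round(s))\n", sep = "")
  cat("  shared peptides removed: ", length(object@shared@peptides), "\n", sep = "")
  cat("  proteins touched: ", sum(object@records$n_peptides_removed > 0),
      " of ", nrow(object@records), "\n", sep = "")
  cat("  residual shared after verification: ",
      length(object@residualShared@peptides), "\n", sep = "")
})

setMethod("show", "DiffResult", function(object) {
  cat("DiffResult: ", nrow(object@table), " protein(s) tested, ",
      object@nSignificant, " significant at FDR <= ", object@alpha,
      " (s0=", object@s0, ", ", object@nPermutations, " permutation(s)",
      if (object@exhaustive) ", exhaustive" else "", ")\n", sep = "")
  if (is.finite(object@cutoff))
    cat("  |d| cutoff ", signif(object@cutoff, 4), ", estimated FDR ",
        signif(object@fdrAtCutoff, 3), "\n", sep = "")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult: ", nrow(object@table), " (pathway, direction) test(s), ",
      "universe ", object@universeSize, " annotated protein(s)\n", sep = "")
  if (nrow(object@table))
    print(head(object@table[, c("pathway_id", "direction", "a", "p_raw", "p_adj")], 5))
})
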