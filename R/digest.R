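ambiguityPattern <- paste0("[", paste(AA_AMBIGUOUS, collapse = ""), "]")

# 1-based positions after which the protease cuts (never includes the
# final residue: the chain end is always a boundary).
cleavageSites <- function(sequence, rule) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 2L) return(integer())
  pos <- which(chars == "K" | chars == "R")
  pos <- pos[pos < n]
  if (rule == "trypsin_strict") pos <- pos[chars[pos + 1L] != "P"]
  pos
}

#' In-silico proteolytic cleavage of one sequence
#'
#' Cuts a protein sequence at tryptic sites (C-terminal to K or R;
#' under \code{trypsin_strict} not when the next residue is proline)
#' and reports every peptide spanning at most
#' \code{missedCleavages} uncut internal sites, with 0-based half-open
#' coordinates on the parent sequence. No length filter is applied
#' here; with zero missed cleavages the peptides partition the
#' sequence exactly.
#'
#' @param sequence Non-empty amino-acid string.
#' @param params A [DigestParams].
#' @return data.frame with columns \code{peptide}, \code{start},
#'   \code{end}, \code{n_missed}, ordered by start then n_missed.
#' @examples
#' cleave("MKRAAAK", DigestParams("trypsin_p"))
#' cleave("AKPR", DigestParams("trypsin_strict"))  # K|P does not cut
#' @export
cleave <- function(sequence, params = DigestParams()) {
  stopifnot(is(params, "DigestParams"))
  sequence <- as.character(sequence)
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  n <- nchar(sequence)
  cuts <- cleavageSites(sequence, params@rule)
  bstart <- c(0L, cuts)              # 0-based fragment starts
  bend <- c(cuts, n)                 # 0-based half-open fragment ends
  nf <- length(bstart)
  k <- min(params@missedCleavages, nf - 1L)
  pieces <- vector("list", k + 1L)
  for (m in 0:k) {
    i <- seq_len(nf - m)
    pieces[[m + 1L]] <- data.frame(start = bstart[i], end = bend[i + m],
                                   n_missed = m)
  }
  out <- do.call(rbind, pieces)
  out$peptide <- substring(sequence, out$start + 1L, out$end)
  out <- out[order(out$start, out$n_missed), c("peptide", "start", "end", "n_missed")]
  rownames(out) <- NULL
  out
}

#' Digest a whole proteome into a peptide index
#'
#' Applies [cleave()] to every record, keeps peptides of at least
#' \code{minLen} residues, and drops peptides containing an ambiguity
#' code (B, X, Z, U, O) — an "identical string match" on an unknown
#' residue is meaningless, so such peptides can never be called shared.
#' The number of excluded peptides is tallied on the index.
#'
#' @param proteome A [Proteome].
#' @param params A [DigestParams]; the defaults (no missed cleavages,
#'   minimum length 7) are the standard trimming settings.
#' @return A [PeptideIndex].
#' @examples
#' p <- Proteome("A", c(p1 = "MKAAAAAAK"))
#' digestProteome(p)   # only the 7-mer survives the length filter
#' @export
digestProteome <- function(proteome, params = DigestParams()) {
  stopifnot(is(proteome, "Proteome"), is(params, "DigestParams"))
  seqs <- proteinSequences(proteome)
  tabs <- lapply(seq_along(seqs), function(i) {
    d <- cleave(seqs[[i]], params)
    d <- d[nchar(d$peptide) >= params@minLen, , drop = FALSE]
    if (nrow(d)) d$protein_id <- names(seqs)[i]
    d
  })
  tab <- do.call(rbind, tabs[vapply(tabs, nrow, 0L) > 0L])
  if (is.null(tab))
    tab <- data.frame(peptide = character(), start = integer(),
                      end = integer(), n_missed = integer(),
                      protein_id = character())
  amb <- grepl(ambiguityPattern, tab$peptide)
  nAmb <- sum(amb)
  tab <- tab[!amb, , drop = FALSE]
  tab <- tab[order(tab$peptide, tab$protein_id, tab$start),
             c("peptide", "protein_id", "start", "end", "n_missed")]
  rownames(tab) <- NULL
  new("PeptideIndex", species = proteome@species, table = tab,
      params = params, nAmbiguous = as.integer(nAmb))
}

#' Summary counts for a peptide index
#'
#' @param index A [PeptideIndex].
#' @return List with \code{n_distinct_peptides}, \code{n_occurrences},
#'   and \code{per_protein} (named occurrence counts).
#' @export
peptideCounts <- function(index) {
  stopifnot(is(index, "PeptideIndex"))
  tab <- index@table
  per <- if (nrow(tab)) table(tab$protein_id) else table(character())
  list(n_distinct_peptides = length(unique(tab$peptide)),
       n_occurrences = nrow(tab),
       per_protein = stats::setNames(as.integer(per), names(per)))
}

#' Dump a peptide index as a TSV report
#'
#' Columns: species, peptide, protein_id, start, end, n_missed
#' (coordinates 0-based half-open, as everywhere in this package).
#'
#' @param index A [PeptideIndex].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writePeptideIndex <- function(index, path) {
  stopifnot(is(index, "PeptideIndex"))
  tab <- index@table
  tab <- cbind(species = rep(index@species, nrow(tab)), tab)
  writeTable(tab, path)
}
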