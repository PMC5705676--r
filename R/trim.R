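# Digest a named character vector of sequences (empty ones skipped)
# into a PeptideIndex without going through Proteome validity.
.digestSeqs <- function(seqs, species, params) {
  keep <- nzchar(seqs)
  tabs <- lapply(which(keep), function(i) {
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
  tab <- tab[!amb, c("peptide", "protein_id", "start", "end", "n_missed")]
  tab <- tab[order(tab$peptide, tab$protein_id, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  new("PeptideIndex", species = species, table = tab, params = params,
      nAmbiguous = as.integer(sum(amb)))
}

.checkIndexes <- function(indexes) {
  if (length(indexes) < 2L)
    stop("shared-peptide detection needs indexes from at least 2 species")
  if (!all(vapply(indexes, is, TRUE, "PeptideIndex")))
    stop("all inputs must be PeptideIndex objects")
  sp <- vapply(indexes, speciesName, "")
  if (anyDuplicated(sp)) stop("species labels must be distinct")
  p <- lapply(indexes, digestParams)
  same <- vapply(p, function(q)
    q@rule == p[[1L]]@rule &&
      q@missedCleavages == p[[1L]]@missedCleavages &&
      q@minLen == p[[1L]]@minLen, TRUE)
  if (!all(same)) stop("all indexes must be built with identical DigestParams")
  sp
}

#' Find peptides shared between species
#'
#' A peptide is shared when its exact string occurs in the digested
#' peptide index of two or more distinct species. Matching is
#' case-sensitive on uppercase sequences; with
#' \code{ilEquivalent = TRUE}, isoleucine and leucine (isobaric, hence
#' indistinguishable by MS1/most MS2) are collapsed to L before
#' matching.
#'
#' @param indexes List of [PeptideIndex] objects, one per species,
#'   built with identical [DigestParams].
#' @param ilEquivalent Collapse I/L before matching (default FALSE:
#'   strict identical string matches).
#' @return A [SharedPeptideSet].
#' @examples
#' a <- digestProteome(Proteome("A", c(p = "AAAAAAAKSSSSSSSK")))
#' b <- digestProteome(Proteome("B", c(q = "SSSSSSSKTTTTTTTK")))
#' peptides(findShared(list(a, b)))   # "SSSSSSSK"
#' @export
findShared <- function(indexes, ilEquivalent = FALSE) {
  sp <- .checkIndexes(indexes)
  per <- lapply(seq_along(indexes), function(i) {
    pep <- unique(indexes[[i]]@table$peptide)
    if (ilEquivalent) pep <- unique(chartr("I", "L", pep))
    data.frame(peptide = pep,
               species = rep(sp[i], length(pep)))
  })
  long <- do.call(rbind, per)
  nsp <- table(long$peptide)
  shared <- as.character(names(nsp)[nsp >= 2L])   # NULL-safe when empty
  membership <- long[long$peptide %in% shared, , drop = FALSE]
  membership <- membership[order(membership$peptide, membership$species), ]
  rownames(membership) <- NULL
  new("SharedPeptideSet", peptides = sort(shared), membership = membership,
      ilEquivalent = ilEquivalent)
}

#' Pairwise proteome overlap matrix
#'
#' Counts of distinct digested peptides shared between every species
#' pair. The count matrix is symmetric with each species' own
#' distinct-peptide total on the diagonal; the percentage matrix
#' divides each row by that species' total, so the same shared count
#' reads as a different percentage from each side (a large proteome
#' shares a smaller fraction of itself than a small one does).
#'
#' @inheritParams findShared
#' @return An [OverlapMatrix].
#' @export
overlapMatrix <- function(indexes, ilEquivalent = FALSE) {
  sp <- .checkIndexes(indexes)
  sets <- lapply(indexes, function(ix) {
    pep <- unique(ix@table$peptide)
    if (ilEquivalent) pep <- unique(chartr("I", "L", pep)) else pep
  })
  names(sets) <- sp
  n <- length(sp)
  counts <- matrix(0L, n, n, dimnames = list(sp, sp))
  for (i in seq_len(n)) {
    counts[i, i] <- length(sets[[i]])
    if (i < n) for (j in (i + 1L):n) {
      k <- length(intersect(sets[[i]], sets[[j]]))
      counts[i, j] <- counts[j, i] <- k
    }
  }
  totals <- stats::setNames(as.numeric(diag(counts)), sp)
  pct <- 100 * sweep(counts, 1L, pmax(totals, 1), "/")
  new("OverlapMatrix", counts = counts, totals = totals, percentages = pct)
}

#' Excise shared peptides from one protein sequence
#'
#' Digests the sequence with zero missed cleavages, deletes every
#' fragment whose string belongs to the shared set, and concatenates
#' the remaining fragments in order. Removal is coordinate-based over
#' digest fragments, never substring search: a shared string occurring
#' inside a longer, non-shared peptide is left untouched.
#'
#' @param sequence A single protein sequence.
#' @param shared A [SharedPeptideSet] (or plain character vector of
#'   peptides).
#' @param params [DigestParams]; the cleavage rule and minimum length
#'   define which fragments are candidates.
#' @return List with \code{sequence} (the trimmed string, possibly
#'   empty) and \code{spans} (data.frame \code{start}, \code{end},
#'   \code{peptide}: removed fragments, 0-based half-open coordinates
#'   on the input).
#' @examples
#' trimProtein("AAAAAAAKSSSSSSSKCCCCCCCK", c("SSSSSSSK"))
#' @export
trimProtein <- function(sequence, shared, params = DigestParams()) {
  il <- FALSE
  if (is(shared, "SharedPeptideSet")) {
    il <- isTRUE(shared@ilEquivalent)
    shared <- shared@peptides
  }
  frags <- cleave(sequence, DigestParams(params@rule, 0L, params@minLen))
  frags <- frags[nchar(frags$peptide) >= params@minLen, , drop = FALSE]
  key <- if (il) chartr("I", "L", frags$peptide) else frags$peptide
  hit <- key %in% shared
  spans <- frags[hit, c("start", "end", "peptide"), drop = FALSE]
  rownames(spans) <- NULL
  if (!nrow(spans))
    return(list(sequence = as.character(sequence), spans = spans))
  chars <- strsplit(as.character(sequence), "", fixed = TRUE)[[1L]]
  drop <- unlist(mapply(function(s, e) (s + 1L):e, spans$start, spans$end,
                        SIMPLIFY = FALSE))
  list(sequence = paste(chars[-drop], collapse = ""), spans = spans)
}

# contiguous runs of sorted integer positions -> 0-based half-open spans
.runsToSpans <- function(pos) {
  pos <- sort(pos)
  breaks <- which(diff(pos) > 1L)
  starts <- pos[c(1L, breaks + 1L)]
  ends <- pos[c(breaks, length(pos))]
  data.frame(start = starts - 1L, end = ends)
}

#' Trim a community of proteomes to species-disjoint peptide content
#'
#' Digests every proteome, finds peptides shared between two or more
#' species, and deletes them from all proteomes by excising the
#' corresponding digest fragments and concatenating the flanks. In
#' \code{single_pass} mode (the default) this is done once, followed by
#' a verification re-digest: deleting a fragment can occasionally
#' create a new shared peptide across the junction (e.g. under the
#' strict rule, a retained fragment ending in K followed by a retained
#' fragment starting with P no longer cleaves), and any such residual
#' sharing is reported rather than silently kept. \code{fixpoint} mode
#' repeats the digest/detect/trim cycle until a re-digest finds no
#' shared peptides, which is guaranteed to terminate because every
#' round strictly removes residues.
#'
#' With \code{missedCleavages > 0} the shared-peptide universe is
#' widened to missed-cleavage peptides; removal then excises all
#' residues covered by occurrences of shared peptides.
#'
#' @param proteomes List of two or more [Proteome] objects with
#'   distinct species labels.
#' @param params [DigestParams].
#' @param mode \code{"single_pass"} or \code{"fixpoint"}.
#' @param ilEquivalent Collapse I/L when matching peptides.
#' @return A [TrimResult].
#' @examples
#' a <- Proteome("A", c(p = "AAAAAAAKSSSSSSSKCCCCCCCK"))
#' b <- Proteome("B", c(q = "SSSSSSSKTTTTTTTK"))
#' tr <- trimProteomes(list(a, b))
#' proteinSequences(trimmedProteomes(tr)$A)
#' @export
trimProteomes <- function(proteomes, params = DigestParams(),
                          mode = c("single_pass", "fixpoint"),
                          ilEquivalent = FALSE) {
  mode <- match.arg(mode)
  if (length(proteomes) < 2L)
    stop("trimming needs proteomes from at least 2 species")
  if (!all(vapply(proteomes, is, TRUE, "Proteome")))
    stop("all inputs must be Proteome objects")
  sp <- vapply(proteomes, speciesName, "")
  if (anyDuplicated(sp)) stop("species labels must be distinct")
  names(proteomes) <- sp

  orig <- lapply(proteomes, proteinSequences)
  chars <- lapply(orig, function(s) lapply(s, function(x)
    strsplit(x, "", fixed = TRUE)[[1L]]))
  keep <- lapply(chars, function(cl) lapply(cl, function(v) rep(TRUE, length(v))))

  curSeqs <- function() lapply(sp, function(s) {
    out <- vapply(seq_along(chars[[s]]), function(j)
      paste(chars[[s]][[j]][keep[[s]][[j]]], collapse = ""), "")
    stats::setNames(out, names(chars[[s]]))
  })
  names(sp) <- sp

  sharedFirst <- NULL
  spanRows <- list()
  pepCount <- lapply(orig, function(s) stats::setNames(integer(length(s)), names(s)))
  round <- 0L
  repeat {
    round <- round + 1L
    seqs <- curSeqs()
    indexes <- lapply(sp, function(s) .digestSeqs(seqs[[s]], s, params))
    shared <- findShared(indexes, ilEquivalent = ilEquivalent)
    if (round == 1L) sharedFirst <- shared
    if (!length(shared@peptides)) break
    for (s in sp) {
      tab <- indexes[[s]]@table
      key <- if (ilEquivalent) chartr("I", "L", tab$peptide) else tab$peptide
      occ <- tab[key %in% shared@peptides, , drop = FALSE]
      if (!nrow(occ)) next
      occ <- occ[order(occ$protein_id, occ$start, occ$end), ]
      for (pid in unique(occ$protein_id)) {
        kv <- keep[[s]][[pid]]
        curToOrig <- which(kv)
        po <- occ[occ$protein_id == pid, , drop = FALSE]
        removedHere <- rep(FALSE, length(curToOrig))
        for (r in seq_len(nrow(po))) {
          pos <- (po$start[r] + 1L):po$end[r]   # 1-based current coords
          new <- pos[!removedHere[pos]]
          if (!length(new)) next
          removedHere[pos] <- TRUE
          origPos <- curToOrig[new]
          sp2 <- .runsToSpans(origPos)
          spanRows[[length(spanRows) + 1L]] <- data.frame(
            species = s, protein_id = pid,
            start = sp2$start, end = sp2$end,
            peptide = po$peptide[r], round = round)
          pepCount[[s]][pid] <- pepCount[[s]][pid] + 1L
        }
        kv[curToOrig[removedHere]] <- FALSE
        keep[[s]][[pid]] <- kv
      }
    }
    if (mode == "single_pass") break
    if (round > 1000L) stop("fixpoint trimming failed to converge")
  }

  finalSeqs <- curSeqs()
  verifyIdx <- lapply(sp, function(s) .digestSeqs(finalSeqs[[s]], s, params))
  residual <- findShared(verifyIdx, ilEquivalent = ilEquivalent)
  if (mode == "single_pass" && length(residual@peptides))
    warning(length(residual@peptides),
            " shared peptide(s) remain after single-pass trimming ",
            "(junction peptides); use mode = 'fixpoint' for a guarantee")

  spans <- if (length(spanRows)) do.call(rbind, spanRows) else
    data.frame(species = character(), protein_id = character(),
               start = integer(), end = integer(),
               peptide = character(), round = integer())
  spans <- spans[order(spans$species, spans$protein_id, spans$start), ]
  rownames(spans) <- NULL

  recs <- do.call(rbind, lapply(sp, function(s) {
    ids <- names(orig[[s]])
    ol <- nchar(orig[[s]])
    tl <- nchar(finalSeqs[[s]])
    data.frame(species = s, protein_id = ids,
               n_peptides_removed = as.integer(pepCount[[s]][ids]),
               n_residues_removed = as.integer(ol - tl),
               original_length = as.integer(ol),
               trimmed_length = as.integer(tl),
               became_empty = tl == 0L)
  }))
  rownames(recs) <- NULL

  trimmed <- lapply(sp, function(s) {
    seqs <- finalSeqs[[s]]
    ok <- nzchar(seqs)
    if (!all(ok))
      warning(sum(!ok), " protein(s) of species '", s,
              "' trimmed to zero length; dropped from the trimmed proteome")
    desc <- proteomes[[s]]@descriptions[ok]
    Proteome(s, seqs[ok], descriptions = desc)
  })

  new("TrimResult", trimmedProteomes = trimmed, records = recs,
      spans = spans, shared = sharedFirst, residualShared = residual,
      params = params, mode = mode, nRounds = round)
}

#' Per-protein trimming report
#'
#' @param result A [TrimResult].
#' @param all Include untouched proteins (default FALSE: rows with
#'   zero removals are suppressed).
#' @return data.frame with one row per (trimmed) protein: species,
#'   protein_id, n_peptides_removed, n_residues_removed,
#'   fraction_removed, became_empty. Per-species totals are attached
#'   as \code{attr(, "speciesTotals")}.
#' @export
trimSummary <- function(result, all = FALSE) {
  stopifnot(is(result, "TrimResult"))
  rec <- result@records
  out <- data.frame(species = rec$species, protein_id = rec$protein_id,
                    n_peptides_removed = rec$n_peptides_removed,
                    n_residues_removed = rec$n_residues_removed,
                    fraction_removed = ifelse(rec$original_length > 0,
                                              rec$n_residues_removed / rec$original_length, 0),
                    became_empty = rec$became_empty)
  if (!all) out <- out[out$n_peptides_removed > 0L, , drop = FALSE]
  out <- out[order(out$species, out$protein_id), ]
  rownames(out) <- NULL
  tot <- do.call(rbind, lapply(split(rec, rec$species), function(d)
    data.frame(species = d$species[1L],
               n_proteins_trimmed = sum(d$n_peptides_removed > 0L),
               n_peptides_removed = sum(d$n_peptides_removed),
               n_residues_removed = sum(d$n_residues_removed))))
  rownames(tot) <- NULL
  attr(out, "speciesTotals") <- tot
  out
}
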