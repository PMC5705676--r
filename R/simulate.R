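NONKR <- setdiff(AA_STANDARD20, c("K", "R"))

# One background tryptic fragment: geometric length (mean 1/cleavageFreq),
# internal residues non-K/R, terminal residue K or R, first residue never P
# so the fragment boundary cleaves under both tryptic rules.
.randomFragment <- function(cleavageFreq) {
  len <- 1L + stats::rgeom(1L, cleavageFreq)
  body <- if (len > 1L) sample(NONKR, len - 1L, replace = TRUE) else character()
  if (length(body) && body[1L] == "P")
    body[1L] <- sample(setdiff(NONKR, "P"), 1L)
  paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
}

.randomPlantedPeptide <- function(len) {
  stopifnot(len >= 7L)
  body <- sample(NONKR, len - 1L, replace = TRUE)
  if (body[1L] == "P") body[1L] <- sample(setdiff(NONKR, "P"), 1L)
  paste(c(body, sample(c("K", "R"), 1L)), collapse = "")
}

#' Simulate community proteomes with planted shared peptides
#'
#' Generates random proteomes for several species by concatenating
#' random tryptic fragments (geometric length distribution with mean
#' \code{1/cleavageFreq}, default mean 9 residues — realistic tryptic
#' fragment lengths), then inserts the requested shared peptides as
#' whole fragments at fragment boundaries, so every planted peptide is
#' an exact tryptic product under both cleavage rules. Accidental
#' background sharing is not prevented: after generation the proteomes
#' are re-digested and any collisions are detected and reported in the
#' ground truth, so tests can compare against the full truth.
#'
#' @param nSpecies Number of species (labelled "sp1", "sp2", ...).
#' @param nProteins Proteins per species (scalar or vector).
#' @param lengthRange Approximate min/max protein length in residues;
#'   fragments are appended until the target drawn from this range is
#'   reached.
#' @param cleavageFreq Per-residue probability of K/R (fragment-length
#'   parameter); default 1/9.
#' @param plantedShared List of planting instructions, each a list
#'   with \code{length} (peptide length, >= 7), \code{species}
#'   (indices or labels of the species that share it) and
#'   \code{nInsertions} (insertions per listed species, default 1).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return List with \code{proteomes} (named list of [Proteome]) and
#'   \code{groundTruth}: \code{planted} (data.frame peptide, species,
#'   protein_id, start, end — 0-based half-open), \code{plantedPeptides},
#'   \code{collisions} (accidentally shared background peptides) and
#'   \code{shared} (their union, what [findShared()] must report under
#'   default [DigestParams()]).
#' @examples
#' sim <- simulateProteomes(2, nProteins = 5,
#'   plantedShared = list(list(length = 10, species = c(1, 2))), seed = 1)
#' sim$groundTruth$plantedPeptides
#' @export
simulateProteomes <- function(nSpecies = 2L, nProteins = 20L,
                              lengthRange = c(100L, 400L),
                              cleavageFreq = 1 / 9,
                              plantedShared = list(),
                              seed = NULL) {
  stopifnot(nSpecies >= 1L, cleavageFreq > 0, cleavageFreq < 1)
  species <- paste0("sp", seq_len(nSpecies))
  nProteins <- rep_len(as.integer(nProteins), nSpecies)
  withSeed(seed, {
    # fragment lists per species/protein
    frags <- lapply(seq_len(nSpecies), function(s) {
      lapply(seq_len(nProteins[s]), function(j) {
        target <- sample(lengthRange[1L]:lengthRange[2L], 1L)
        out <- character()
        tot <- 0L
        while (tot < target) {
          f <- .randomFragment(cleavageFreq)
          out <- c(out, f)
          tot <- tot + nchar(f)
        }
        out
      })
    })
    # parallel marks distinguish planted fragments from background, so
    # coordinates stay correct when several insertions hit one protein
    marks <- lapply(frags, function(fl) lapply(fl, function(v)
      integer(length(v))))
    plantedPeps <- character()
    for (ins in plantedShared) {
      len <- as.integer(ins$length)
      who <- ins$species
      if (is.character(who)) who <- match(who, species)
      if (any(is.na(who)) || length(who) < 2L)
        stop("each planted peptide needs >= 2 valid species")
      nIns <- if (is.null(ins$nInsertions)) 1L else as.integer(ins$nInsertions)
      pep <- .randomPlantedPeptide(len)
      plantedPeps <- c(plantedPeps, pep)
      pid <- length(plantedPeps)
      for (s in who) for (r in seq_len(nIns)) {
        j <- sample.int(nProteins[s], 1L)
        pos <- sample.int(length(frags[[s]][[j]]) + 1L, 1L)  # boundary slot
        frags[[s]][[j]] <- append(frags[[s]][[j]], pep, after = pos - 1L)
        marks[[s]][[j]] <- append(marks[[s]][[j]], pid, after = pos - 1L)
      }
    }
    proteomes <- lapply(seq_len(nSpecies), function(s) {
      seqs <- vapply(frags[[s]], paste, "", collapse = "")
      names(seqs) <- sprintf("%s_p%03d", species[s], seq_along(seqs))
      Proteome(species[s], seqs)
    })
    names(proteomes) <- species

    # resolve planted coordinates from the final fragment lists
    rows <- list()
    for (s in seq_len(nSpecies)) for (j in seq_len(nProteins[s])) {
      mk <- marks[[s]][[j]]
      if (!any(mk > 0L)) next
      ends <- cumsum(nchar(frags[[s]][[j]]))
      starts <- c(0L, ends[-length(ends)])
      for (i in which(mk > 0L))
        rows[[length(rows) + 1L]] <- data.frame(
          peptide = plantedPeps[mk[i]], species = species[s],
          protein_id = sprintf("%s_p%03d", species[s], j),
          start = as.integer(starts[i]), end = as.integer(ends[i]))
    }
    plantedDf <- if (length(rows)) do.call(rbind, rows) else
      data.frame(peptide = character(), species = character(),
                 protein_id = character(), start = integer(),
                 end = integer())

    # self-consistency: each placement must read back from the sequence
    for (i in seq_len(nrow(plantedDf))) {
      seq <- proteinSequences(proteomes[[plantedDf$species[i]]])[[plantedDf$protein_id[i]]]
      got <- substring(seq, plantedDf$start[i] + 1L, plantedDf$end[i])
      if (got != plantedDf$peptide[i])
        stop("internal error: planted peptide does not read back")
    }

    shared <- if (nSpecies >= 2L) {
      idx <- lapply(proteomes, digestProteome, params = DigestParams())
      peptides(findShared(idx))
    } else character()
    collisions <- setdiff(shared, unique(plantedPeps))

    list(proteomes = proteomes,
         groundTruth = list(planted = plantedDf,
                            plantedPeptides = unique(plantedPeps),
                            collisions = collisions,
                            shared = shared))
  })
}

#' Simulate a label-free intensity matrix with planted group effects
#'
#' Protein log2 baselines are drawn from a normal distribution; an
#' effect of \code{effectSize} log2 units (random sign per protein) is
#' added to group 2 for a random affected subset; normal within-group
#' noise is added; missingness is applied last, either completely at
#' random or preferentially to low-intensity values (left-censoring,
#' as in real label-free data).
#'
#' @param nProteins Number of proteins; default 1000.
#' @param nPerGroup Replicates per group; default 5.
#' @param baselineMean,baselineSD Log2 baseline distribution
#'   (defaults 25 and 2, typical LFQ scale).
#' @param withinSD Within-group SD in log2 units; default 0.5.
#' @param effectSize Log2 difference planted on affected proteins;
#'   default 2 (four times the within-group SD).
#' @param affectedFraction Fraction of proteins carrying the effect;
#'   default 0.1.
#' @param missingRate Marginal missingness probability; default 0.
#' @param intensityDependentMissing Make missingness more likely for
#'   low intensities (default FALSE).
#' @param seed Integer seed.
#' @return List with \code{matrix} (proteins x samples, NA for
#'   missing), \code{groups} (named group label per sample) and
#'   \code{groundTruth} (\code{affected} ids and their effect
#'   \code{direction}, +1 meaning higher in group 2).
#' @export
simulateIntensities <- function(nProteins = 1000L, nPerGroup = 5L,
                                baselineMean = 25, baselineSD = 2,
                                withinSD = 0.5, effectSize = 2,
                                affectedFraction = 0.1,
                                missingRate = 0,
                                intensityDependentMissing = FALSE,
                                seed = NULL) {
  stopifnot(nProteins >= 1L, nPerGroup >= 2L, missingRate >= 0, missingRate < 1)
  withSeed(seed, {
    ids <- sprintf("prot_%04d", seq_len(nProteins))
    samples <- c(paste0("g1_", seq_len(nPerGroup)),
                 paste0("g2_", seq_len(nPerGroup)))
    groups <- stats::setNames(rep(c("group1", "group2"), each = nPerGroup),
                              samples)
    nAff <- round(affectedFraction * nProteins)
    affected <- sort(sample.int(nProteins, nAff))
    dir <- stats::setNames(sample(c(-1, 1), nAff, replace = TRUE), ids[affected])
    base <- stats::rnorm(nProteins, baselineMean, baselineSD)
    m <- matrix(base, nProteins, 2L * nPerGroup,
                dimnames = list(ids, samples))
    eff <- numeric(nProteins)
    eff[affected] <- dir * effectSize
    m[, groups == "group2"] <- m[, groups == "group2"] + eff
    m <- m + matrix(stats::rnorm(length(m), 0, withinSD), nrow(m))
    if (missingRate > 0) {
      p <- if (intensityDependentMissing) {
        # left-censoring: low intensities are more likely to be missing
        sdAll <- sqrt(baselineSD^2 + withinSD^2)
        pmin(1, 2 * missingRate *
               stats::pnorm(m, baselineMean, sdAll, lower.tail = FALSE))
      } else missingRate
      miss <- matrix(stats::runif(length(m)) < p, nrow(m))
      m[miss] <- NA_real_
    }
    list(matrix = m, groups = groups,
         groundTruth = list(affected = ids[affected], direction = dir))
  })
}

#' Simulate a pathway annotation with one planted enriched pathway
#'
#' Assigns random pathway memberships over a protein universe and, if
#' requested, plants one pathway whose membership is enriched for a
#' supplied set of changed proteins.
#'
#' @param universe Character vector of protein ids.
#' @param nPathways Number of pathways; default 20.
#' @param sizeRange Min/max pathway size; default c(10, 40).
#' @param sca Character vector of changed-protein ids (subset of the
#'   universe) used for planting.
#' @param plantedExcess Fraction of \code{sca} forced into the planted
#'   pathway (0 disables planting); default 0.
#' @param seed Integer seed.
#' @return List with \code{annotation} (data.frame protein_id,
#'   pathway_id, pathway_name) and \code{groundTruth}
#'   (\code{plantedPathway}, or NULL).
#' @export
simulateAnnotation <- function(universe, nPathways = 20L,
                               sizeRange = c(10L, 40L),
                               sca = character(), plantedExcess = 0,
                               seed = NULL) {
  stopifnot(length(universe) >= max(sizeRange), nPathways >= 1L)
  withSeed(seed, {
    ids <- sprintf("PW%02d", seq_len(nPathways))
    rows <- lapply(seq_len(nPathways), function(i) {
      size <- sample(sizeRange[1L]:sizeRange[2L], 1L)
      members <- sample(universe, size)
      data.frame(protein_id = members, pathway_id = ids[i],
                 pathway_name = paste("Pathway", i))
    })
    plantedPathway <- NULL
    if (plantedExcess > 0 && length(sca)) {
      plantedPathway <- ids[1L]
      forced <- sample(sca, max(1L, round(plantedExcess * length(sca))))
      size <- max(length(forced), sample(sizeRange[1L]:sizeRange[2L], 1L))
      filler <- sample(setdiff(universe, forced), size - length(forced))
      rows[[1L]] <- data.frame(protein_id = c(forced, filler),
                               pathway_id = ids[1L],
                               pathway_name = "Pathway 1")
    }
    ann <- do.call(rbind, rows)
    rownames(ann) <- NULL
    list(annotation = ann,
         groundTruth = list(plantedPathway = plantedPathway))
  })
}
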