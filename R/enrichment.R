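#' One-sided Fisher's exact test for over-representation
#'
#' Upper-tail probability of the 2x2 table
#' \tabular{lcc}{
#'            \tab in pathway \tab not in pathway \cr
#' changed    \tab a          \tab b              \cr
#' unchanged  \tab c          \tab g
#' }
#' i.e. \eqn{P[X \ge a]} for \eqn{X \sim}
#' Hypergeometric(\eqn{N = a+b+c+g}, \eqn{K = a+c}, \eqn{n = a+b}).
#'
#' @param a,b,c,g Non-negative integer cell counts.
#' @return The one-sided p-value.
#' @examples
#' fisherOneSided(2, 0, 0, 2)   # 1/6
#' @export
fisherOneSided <- function(a, b, c, g) {
  cells <- c(a, b, c, g)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("counts must be non-negative integers")
  if (sum(cells) == 0) stop("all-zero table")
  stats::phyper(a - 1, a + c, b + g, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment: sort ascending,
#' \eqn{p^{adj}_{(i)} = \min_{j \ge i} \min(1, (m/j)\,p_{(j)})},
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))   # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Direction-aware pathway over-representation analysis
#'
#' Tests every pathway for over-representation of significantly
#' changed (increased or decreased) proteins against the annotated
#' proteome, one one-sided Fisher's exact test per (pathway,
#' direction), with Benjamini-Hochberg correction applied across
#' pathways within each direction. The universe defaults to all
#' annotated proteins of the reference proteome; proteins in the
#' changed sets without any pathway annotation cannot be tested and
#' are counted separately (their number is reported on the result).
#' No significance filter is applied: the full table is returned
#' sorted by adjusted p.
#'
#' @param increased,decreased Character vectors of protein ids with
#'   significantly increased / decreased abundance (either may be
#'   empty).
#' @param annotation data.frame with columns \code{protein_id},
#'   \code{pathway_id}, optionally \code{pathway_name} (one row per
#'   membership; multi-pathway proteins are counted once per pathway).
#' @param universe \code{"annotated"} (default: every protein with at
#'   least one pathway) or \code{"detected"} (annotated proteins
#'   restricted to \code{detected}).
#' @param detected Character vector of detected protein ids, required
#'   for \code{universe = "detected"}.
#' @param combineDirections Also test the union of both sets as
#'   direction \code{"any"} (default FALSE).
#' @return An [EnrichmentResult].
#' @export
enrichPathways <- function(increased, decreased, annotation,
                           universe = c("annotated", "detected"),
                           detected = NULL, combineDirections = FALSE) {
  universe <- match.arg(universe)
  if (!all(c("protein_id", "pathway_id") %in% names(annotation)))
    stop("annotation needs columns protein_id, pathway_id")
  if (!"pathway_name" %in% names(annotation))
    annotation$pathway_name <- annotation$pathway_id
  uni <- unique(annotation$protein_id)
  if (universe == "detected") {
    if (is.null(detected)) stop("universe = 'detected' needs 'detected'")
    uni <- intersect(uni, detected)
    annotation <- annotation[annotation$protein_id %in% uni, , drop = FALSE]
  }
  if (!length(uni)) stop("empty annotation universe")

  sets <- list(increased = unique(as.character(increased)),
               decreased = unique(as.character(decreased)))
  if (combineDirections)
    sets$any <- unique(c(sets$increased, sets$decreased))

  members <- split(unique(annotation[c("protein_id", "pathway_id")])$protein_id,
                   unique(annotation[c("protein_id", "pathway_id")])$pathway_id)
  nameMap <- annotation$pathway_name[!duplicated(annotation$pathway_id)]
  names(nameMap) <- annotation$pathway_id[!duplicated(annotation$pathway_id)]

  nUnann <- integer(0)
  rows <- list()
  for (dir in names(sets)) {
    sca <- sets[[dir]]
    scaU <- intersect(sca, uni)
    nUnann[dir] <- length(sca) - length(scaU)
    nS <- length(scaU)
    pr <- vapply(names(members), function(pw) {
      a <- length(intersect(members[[pw]], scaU))
      cc <- length(members[[pw]]) - a
      b <- nS - a
      g <- length(uni) - a - b - cc
      fisherOneSided(a, b, cc, g)
    }, 0)
    df <- do.call(rbind, lapply(names(members), function(pw) {
      a <- length(intersect(members[[pw]], scaU))
      cc <- length(members[[pw]]) - a
      b <- nS - a
      g <- length(uni) - a - b - cc
      data.frame(pathway_id = pw,
                 pathway_name = unname(nameMap[pw]),
                 direction = dir, a = a, b = b, c = cc, g = g,
                 odds_ratio = (a * g) / (b * cc),
                 p_raw = unname(pr[pw]),
                 pathway_fraction_of_proteome = (a + cc) / length(uni),
                 sca_fraction_of_sca = if (nS > 0) a / nS else 0)
    }))
    df$p_adj <- bhAdjust(df$p_raw)
    rows[[dir]] <- df[order(df$p_adj, df$p_raw, df$pathway_id), ]
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[c("pathway_id", "pathway_name", "direction", "a", "b", "c", "g",
               "odds_ratio", "p_raw", "p_adj",
               "pathway_fraction_of_proteome", "sca_fraction_of_sca")]
  new("EnrichmentResult", table = tab,
      universeSize = length(uni), nUnannotated = nUnann)
}
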