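#' Log2-transform a raw intensity table
#'
#' Positive intensities become log2 values; zeros and missing entries
#' become \code{NA} — a zero label-free intensity is a non-detection,
#' not a measured abundance, and must never enter the statistics as 0.
#'
#' @param raw Numeric vector or matrix of non-negative raw intensities.
#' @return Same shape, log2-transformed with 0 mapped to \code{NA}.
#' @examples
#' logTransform(c(8, 0, 1, NA))   # 3, NA, 0, NA
#' @export
logTransform <- function(raw) {
  if (any(raw < 0, na.rm = TRUE)) stop("negative intensities are invalid")
  out <- raw
  out[!is.na(out) & out == 0] <- NA_real_
  out[!is.na(out)] <- log2(out[!is.na(out)])
  out
}

.checkDesign <- function(m, groups) {
  if (is.null(dim(m)) || is.null(rownames(m)))
    stop("intensity matrix must have protein ids as rownames")
  if (length(groups) != ncol(m))
    stop("design must assign every sample column exactly once")
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("exactly two groups are required")
  if (any(table(g) < 1L)) stop("both groups must be non-empty")
  g
}

#' Filter to quantifiable proteins
#'
#' Keeps proteins with valid (non-missing) values in at least
#' \code{minValidFrac} of the replicates of \emph{each} group —
#' \code{ceiling(minValidFrac * n_g)} per group, so with five
#' replicates per condition and the default 0.6 a protein needs at
#' least three valid values in both conditions.
#'
#' @param m Numeric matrix (proteins x samples, rownames = protein id)
#'   of log2 intensities with \code{NA} for non-detections.
#' @param groups Group label per column (two levels).
#' @param minValidFrac Required valid fraction per group, in (0, 1];
#'   default 0.6.
#' @return The row-subset matrix.
#' @export
filterQuantifiable <- function(m, groups, minValidFrac = 0.6) {
  g <- .checkDesign(m, groups)
  stopifnot(minValidFrac > 0, minValidFrac <= 1)
  lv <- levels(g)
  keep <- rep(TRUE, nrow(m))
  for (l in lv) {
    cols <- which(g == l)
    need <- ceiling(minValidFrac * length(cols))
    keep <- keep & rowSums(!is.na(m[, cols, drop = FALSE])) >= need
  }
  m[keep, , drop = FALSE]
}

#' S0-moderated Welch statistic
#'
#' The two-group statistic used for label-free differential abundance:
#' an unequal-variance (Welch) t-statistic whose standard-error
#' denominator is inflated by a constant fudge factor \code{s0},
#' \deqn{d = \frac{\bar x - \bar y}{s_0 + \sqrt{s_x^2/n_x + s_y^2/n_y}},}
#' with sample variances on \eqn{n-1} denominators. The fudge factor
#' de-emphasises proteins whose tiny variance would otherwise give a
#' huge t despite a negligible fold change; \code{s0 = 0} recovers the
#' classical Welch t. Missing values are dropped before computing
#' counts, means and variances.
#'
#' @param x,y Numeric vectors of log2 intensities for the two groups
#'   (at least two valid values each).
#' @param s0 Non-negative fudge factor; default 1.
#' @return The statistic (positive when \code{x} exceeds \code{y}).
#' @examples
#' samWelchD(c(1, 2, 3), c(4, 5, 6), s0 = 1)   # about -1.6515
#' @export
samWelchD <- function(x, y, s0 = 1) {
  stopifnot(s0 >= 0)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("at least 2 valid values per group are required")
  se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  (mean(x) - mean(y)) / (s0 + se)
}

# Vectorised per-row group stats with NA handling.
.rowStats <- function(m, cols) {
  x <- m[, cols, drop = FALSE]
  ok <- !is.na(x)
  n <- rowSums(ok)
  x0 <- x; x0[!ok] <- 0
  s1 <- rowSums(x0)
  s2 <- rowSums(x0 * x0)
  mu <- s1 / n
  v <- (s2 - n * mu * mu) / (n - 1)
  v[n < 2L] <- NA_real_
  mu[n < 1L] <- NA_real_
  list(n = n, mean = mu, var = pmax(v, 0))
}

.rowD <- function(m, cols1, cols2, s0) {
  a <- .rowStats(m, cols1)
  b <- .rowStats(m, cols2)
  d <- (a$mean - b$mean) / (s0 + sqrt(a$var / a$n + b$var / b$n))
  d[a$n < 2L | b$n < 2L] <- NA_real_
  list(d = d, stats = list(g1 = a, g2 = b))
}

#' Permutation-FDR differential abundance test
#'
#' Computes the S0-moderated Welch statistic per protein, then
#' estimates the false discovery rate of every candidate |d| cutoff by
#' re-computing the statistic under random relabelings of the samples
#' into two groups of the original sizes. When the number of distinct
#' relabelings is at most \code{nPermutations} they are enumerated
#' exhaustively (minus the identity labeling); otherwise
#' \code{nPermutations} random relabelings are drawn
#' seed-deterministically. For a cutoff \eqn{c},
#' \deqn{\widehat{FDR}(c) = \frac{\mathrm{mean}_\pi\,\#\{|d^*_\pi| \ge c\}}
#'   {\max(1, \#\{|d| \ge c\})},}
#' clipped to [0, 1] and made monotone non-increasing in \eqn{c}; the
#' chosen cutoff is the smallest \eqn{c} among the observed |d| values
#' with \eqn{\widehat{FDR}(c) \le \alpha}. Proteins with a permuted
#' group reduced below two valid values get an undefined permuted
#' statistic, which never counts as an exceedance.
#'
#' @param m Filtered log2-intensity matrix (see
#'   [filterQuantifiable()]); every protein needs at least two valid
#'   values per group.
#' @param groups Group label per column (two levels; the first level
#'   is "group 1" in the sign convention).
#' @param s0 Fudge factor; default 1.
#' @param alpha FDR threshold; default 0.05.
#' @param nPermutations Number of relabelings; default 250.
#' @param seed Integer seed for the random relabelings (ignored when
#'   enumeration is exhaustive); the caller's RNG state is restored.
#' @return A [DiffResult].
#' @export
permutationFDR <- function(m, groups, s0 = 1, alpha = 0.05,
                           nPermutations = 250L, seed = NULL) {
  g <- .checkDesign(m, groups)
  lv <- levels(g)
  cols1 <- which(g == lv[1L]); cols2 <- which(g == lv[2L])
  if (length(cols1) < 2L || length(cols2) < 2L)
    stop("each group needs at least 2 samples")
  n <- ncol(m); n1 <- length(cols1)

  obs <- .rowD(m, cols1, cols2, s0)
  d <- obs$d
  if (anyNA(d))
    stop("proteins with fewer than 2 valid values per group must be ",
         "filtered out before testing (see filterQuantifiable)")
  absd <- abs(d)

  nAll <- choose(n, n1)
  exhaustive <- nAll <= nPermutations + 1L
  perms <- if (exhaustive) {
    all <- utils::combn(n, n1, simplify = FALSE)
    all[!vapply(all, function(p) identical(sort(p), sort(cols1)), TRUE)]
  } else {
    withSeed(seed, {
      out <- vector("list", nPermutations)
      i <- 0L
      while (i < nPermutations) {
        p <- sort(sample.int(n, n1))
        if (identical(p, sort(cols1))) next
        i <- i + 1L
        out[[i]] <- p
      }
      out
    })
  }
  nPerm <- length(perms)

  permAbs <- unlist(lapply(perms, function(p) {
    dd <- .rowD(m, p, setdiff(seq_len(n), p), s0)$d
    abs(dd[!is.na(dd)])
  }))
  permSorted <- sort(permAbs)

  cand <- sort(unique(absd))
  # exceedance counts #{v >= c}: left-open findInterval counts #{v < c}
  nObsGE <- length(absd) - findInterval(cand, sort(absd), left.open = TRUE)
  nPermGE <- length(permSorted) - findInterval(cand, permSorted, left.open = TRUE)
  fdr <- (nPermGE / nPerm) / pmax(1, nObsGE)
  fdr <- pmin(pmax(fdr, 0), 1)
  fdr <- cummin(fdr)                      # monotone non-increasing in c

  ok <- which(fdr <= alpha)
  if (length(ok)) {
    cutoff <- cand[ok[1L]]
    fdrAt <- fdr[ok[1L]]
  } else {
    cutoff <- Inf
    fdrAt <- NA_real_
  }
  sig <- absd >= cutoff

  st <- obs$stats
  tab <- data.frame(protein_id = rownames(m),
                    n1 = st$g1$n, n2 = st$g2$n,
                    mean1 = st$g1$mean, mean2 = st$g2$mean,
                    log2_difference = st$g1$mean - st$g2$mean,
                    d = d, significant = sig)
  rownames(tab) <- NULL
  new("DiffResult", table = tab, cutoff = cutoff,
      fdrAtCutoff = fdrAt, nSignificant = as.integer(sum(sig)),
      fdrCurve = data.frame(cutoff = cand, fdr = fdr),
      s0 = s0, alpha = alpha, nPermutations = as.integer(nPerm),
      exhaustive = exhaustive)
}

#' Significantly changed protein sets by direction
#'
#' Convenience split of a [DiffResult] into the proteins with
#' significantly increased and decreased abundance in group 1 relative
#' to group 2, ready for [enrichPathways()].
#'
#' @param result A [DiffResult].
#' @return List with character vectors \code{increased} and
#'   \code{decreased}.
#' @export
significantSets <- function(result) {
  stopifnot(is(result, "DiffResult"))
  tb <- result@table
  list(increased = tb$protein_id[tb$significant & tb$log2_difference > 0],
       decreased = tb$protein_id[tb$significant & tb$log2_difference < 0])
}
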