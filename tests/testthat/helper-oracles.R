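# Independent oracles used throughout the suite. These deliberately
# share no code with the package: plain loops and first-principles
# formulas only.

# Random protein-like sequence; K, R and P are over-represented so that
# cleavage sites and the proline exception are exercised often.
randomSequence <- function(len) {
  aa <- c("A","C","D","E","F","G","H","I","L","M","N","Q","S","T","V","W","Y")
  probs <- c(rep(0.76 / length(aa), length(aa)), 0.08, 0.08, 0.08)
  paste(sample(c(aa, "K", "R", "P"), len, replace = TRUE, prob = probs),
        collapse = "")
}

# Brute-force digestion: mark cleavage sites by scanning the rule
# definition, then enumerate every run of <= k+1 consecutive fragments.
bruteCleave <- function(seq, rule, k) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  sites <- integer()
  if (n >= 2) for (i in 1:(n - 1)) {
    if (chars[i] == "K" || chars[i] == "R") {
      if (rule == "trypsin_p" || chars[i + 1] != "P")
        sites <- c(sites, i)
    }
  }
  b <- c(0L, sites, n)
  m <- length(b) - 1L
  rows <- list()
  for (i in 1:m) for (j in i:min(m, i + k)) {
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = substr(seq, b[i] + 1L, b[j + 1L]),
      start = b[i], end = b[j + 1L], n_missed = j - i)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$n_missed), ]
  rownames(out) <- NULL
  out
}

# Distinct >=7-residue tryptic peptides of a set of sequences, via the
# brute-force digester (used as an independent disjointness scanner).
bruteDistinctPeptides <- function(seqs, rule = "trypsin_strict",
                                  k = 0L, minLen = 7L) {
  peps <- character()
  for (s in seqs[nzchar(seqs)]) {
    d <- bruteCleave(s, rule, k)
    peps <- c(peps, d$peptide[nchar(d$peptide) >= minLen])
  }
  unique(peps[!grepl("[BXZUO]", peps)])
}

# Exhaustive enumeration of the one-sided Fisher tail from binomial
# coefficients (log space, so the tail is exact to ~1e-14 even for
# three-digit totals).
bruteFisherUpper <- function(a, b, c, g) {
  N <- a + b + c + g; K <- a + c; n <- a + b
  xs <- max(0, n - (N - K)):min(K, n)
  probs <- exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n))
  sum(probs[xs >= a])
}

# Hand-written Benjamini-Hochberg step-up.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in m:1)
    adj[i] <- min(1, ranked[i] * m / i, if (i < m) adj[i + 1] else 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Loop-based Welch d with fudge factor (no code shared with the package).
bruteD <- function(x, y, s0) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  vx <- sum((x - mx)^2) / (length(x) - 1)
  vy <- sum((y - my)^2) / (length(y) - 1)
  (mx - my) / (s0 + sqrt(vx / length(x) + vy / length(y)))
}

# Exhaustive permutation-FDR oracle for small designs: enumerate every
# relabeling of the columns into groups of the original sizes, drop
# the identity, and walk the cutoff candidates by hand.
brutePermutationCutoff <- function(m, groups, s0, alpha) {
  lv <- unique(groups)
  cols1 <- which(groups == lv[1])
  n <- ncol(m)
  d <- apply(m, 1, function(r) bruteD(r[cols1], r[-cols1], s0))
  combos <- combn(n, length(cols1), simplify = FALSE)
  combos <- Filter(function(p) !identical(sort(p), sort(cols1)), combos)
  permAbs <- lapply(combos, function(p)
    abs(apply(m, 1, function(r) bruteD(r[p], r[-p], s0))))
  cand <- sort(unique(abs(d)))
  fdr <- numeric(length(cand))
  for (i in seq_along(cand)) {
    c0 <- cand[i]
    exp0 <- mean(sapply(permAbs, function(v) sum(v >= c0)))
    fdr[i] <- min(1, max(0, exp0 / max(1, sum(abs(d) >= c0))))
  }
  fdr <- cummin(fdr)
  hit <- which(fdr <= alpha)
  list(d = d, cand = cand, fdr = fdr,
       cutoff = if (length(hit)) cand[hit[1]] else Inf,
       significant = if (length(hit)) abs(d) >= cand[hit[1]]
                     else rep(FALSE, nrow(m)))
}

# Two-species toy community used in several trim tests.
toyProteomes <- function() {
  list(Proteome("A", c(p = "AAAAAAAKSSSSSSSKCCCCCCCK")),
       Proteome("B", c(q = "SSSSSSSKTTTTTTTK")))
}
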