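# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Explicit generation-by-generation selfing of a biparental cross at two
# loci with meiotic recombination fraction r. Returns the line-level
# recombinant fraction among lines homozygous at both loci after
# `generations` rounds of selfing (F1 -> F_{generations+1}).
meiosis_ril_fraction <- function(r, n_lines, generations = 12) {
  # haplotypes coded as 2-vector of alleles (0 = parent A, 1 = parent B)
  gamete <- function(h1, h2) {
    # pick a starting haplotype, recombine with prob r
    first <- sample(c(TRUE, FALSE), 1)
    a <- if (first) h1 else h2
    b <- if (first) h2 else h1
    if (stats::runif(1) < r) c(a[1], b[2]) else a
  }
  rec <- 0L; hom <- 0L
  for (i in seq_len(n_lines)) {
    h1 <- c(0L, 0L); h2 <- c(1L, 1L)      # F1
    for (g in seq_len(generations)) {
      g1 <- gamete(h1, h2)
      g2 <- gamete(h1, h2)
      h1 <- g1; h2 <- g2
    }
    if (all(h1 == h2)) {
      hom <- hom + 1L
      if (h1[1] != h1[2]) rec <- rec + 1L
    }
  }
  rec / hom
}

# Dynamic-programming segmentation of one line's chromosome calls:
# minimize (#observed calls mismatching their segment genotype) +
# penalty * (#genotype switches). Independent oracle for the run-length
# cleaning heuristic. Returns the corrected call vector.
dp_segment <- function(calls, penalty = 2.5) {
  obs <- calls %in% c(0L, 2L)
  n <- length(calls)
  # states: 1 = genotype 0, 2 = genotype 2
  cost <- matrix(Inf, n, 2)
  back <- matrix(0L, n, 2)
  mis <- function(i, s) {
    if (!obs[i]) 0 else as.numeric(calls[i] != c(0L, 2L)[s])
  }
  cost[1, ] <- c(mis(1, 1), mis(1, 2))
  for (i in 2:n) {
    for (s in 1:2) {
      stay <- cost[i - 1, s]
      switch_ <- cost[i - 1, 3 - s] + penalty
      if (stay <= switch_) {
        cost[i, s] <- stay + mis(i, s); back[i, s] <- s
      } else {
        cost[i, s] <- switch_ + mis(i, s); back[i, s] <- 3 - s
      }
    }
  }
  path <- integer(n)
  path[n] <- which.min(cost[n, ])
  for (i in n:2) path[i - 1] <- back[i, path[i]]
  out <- calls
  out[obs] <- c(0L, 2L)[path[obs]]
  out
}

# single-marker regression LOD oracle (two-group least squares)
single_marker_lod <- function(y, score) {
  yc <- y - mean(y)
  sc <- score - mean(score)
  rss0 <- sum(yc^2)
  b <- sum(sc * yc) / sum(sc^2)
  rss1 <- sum((yc - b * sc)^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# small deterministic genotype fixture used by the linkage QC tests:
# 6 lines x 10 markers; line 2 has 40% missing, marker 4 has 20% missing
# among the remaining lines
qc_fixture <- function() {
  g <- matrix(0L, 6, 10,
              dimnames = list(sprintf("L%d", 1:6), sprintf("M%d", 1:10)))
  g[, 6:10] <- 2L
  g[2, 1:4] <- -1L                         # 40% missing line
  g[3, 4] <- -1L                           # marker 4: 1/5 missing after drop
  g
}
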