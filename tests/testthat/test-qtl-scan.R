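sim_chrom <- function(n_lines, n_markers = 21, length_cm = 100, seed = 1) {
  ms <- map_spec(data.frame(chrom = "1", length_cm = length_cm,
                            n_markers = n_markers))
  pop <- simulate_ril_population(ms, n_lines, het_rate = 0, seed = seed)
  pop$geno <- set_het_missing(pop$geno)
  pop
}

test_that("genotype probabilities honor observed calls and the prior", {
  pop <- sim_chrom(30, seed = 2)
  gp <- genotype_probabilities(pop$geno, pop$map)
  # at marker positions, probability 1 on the observed class
  for (j in c(1, 11, 21)) {
    pcol <- which(gp$positions$cm == pop$map$cm[j])
    pB <- unname(gp$pB[, pcol])
    expect_equal(pB, as.numeric(pop$geno[, j] == 2L))
  }
  expect_true(all(gp$pB >= 0 & gp$pB <= 1))
  # a line missing every call sits at the 0.5 prior
  g2 <- pop$geno
  g2[1, ] <- -1L
  gp2 <- genotype_probabilities(g2, pop$map)
  expect_true(all(gp2$pB[1, ] == 0.5))
})

test_that("between-marker probabilities match brute-force simulation", {
  # 100,000 RILs over three equidistant markers; the empirical frequency
  # of the middle genotype given both flanks is the oracle for the
  # conditional probability at the midpoint
  d <- 10                                   # cM per half-interval
  ms <- map_spec(data.frame(chrom = "1", length_cm = 2 * d, n_markers = 3))
  pop <- simulate_ril_population(ms, 1e5, het_rate = 0, seed = 3)
  g <- pop$geno
  both0 <- g[, 1] == 0L & g[, 3] == 0L
  emp <- mean(g[both0, 2] == 0L)
  masked <- g[, c(1, 3)]
  map2 <- pop$map[c(1, 3), ]
  gp <- genotype_probabilities(masked, map2, step_cm = d)
  mid <- which(gp$positions$cm == d)
  line0 <- which(both0)[1]
  pA_mid <- 1 - gp$pB[line0, mid]
  expect_lt(abs(pA_mid - emp), 0.01)
})

test_that("interval-mapping LOD equals single-marker regression at markers", {
  set.seed(4)
  for (i in 1:10) {
    pop <- sim_chrom(60 + 10 * i, seed = 100 + i)
    gp <- genotype_probabilities(pop$geno, pop$map)
    y <- rnorm(nrow(pop$geno)) +
      0.5 * ifelse(pop$geno[, 8] == 2L, 1, -1)
    names(y) <- rownames(pop$geno)
    pr <- interval_mapping_scan(y, gp)
    for (j in c(3, 8, 15)) {
      score <- ifelse(pop$geno[, j] == 2L, 1, -1)
      oracle <- single_marker_lod(y, score)
      at <- which(pr$cm == pop$map$cm[j])
      expect_equal(pr$lod[at], oracle, tolerance = 1e-8)
    }
  }
})

test_that("LOD is invariant to affine phenotype transformation", {
  pop <- sim_chrom(80, seed = 5)
  gp <- genotype_probabilities(pop$geno, pop$map)
  set.seed(6)
  y <- setNames(rnorm(80), rownames(pop$geno))
  p1 <- interval_mapping_scan(y, gp)
  p2 <- interval_mapping_scan(3.2 * y - 1.7, gp)
  expect_equal(p1$lod, p2$lod, tolerance = 1e-9)
  expect_equal(p2$additive, 3.2 * p1$additive, tolerance = 1e-9)
})

test_that("constant phenotypes yield a flagged all-zero profile", {
  pop <- sim_chrom(40, seed = 7)
  gp <- genotype_probabilities(pop$geno, pop$map)
  y <- setNames(rep(1, 40), rownames(pop$geno))
  pr <- interval_mapping_scan(y, gp)
  expect_true(attr(pr, "flat"))
  expect_true(all(pr$lod == 0))
})

test_that("the additive-effect sign tracks the parent-B allele", {
  pop <- sim_chrom(100, seed = 8)
  gp <- genotype_probabilities(pop$geno, pop$map)
  score <- ifelse(pop$geno[, 11] == 2L, 1, -1)
  set.seed(9)
  y_up <- setNames(0.5 * score + rnorm(100, 0, 0.3), rownames(pop$geno))
  y_dn <- setNames(-0.5 * score + rnorm(100, 0, 0.3), rownames(pop$geno))
  at <- which(gp$positions$cm == pop$map$cm[11])
  expect_gt(interval_mapping_scan(y_up, gp)$additive[at], 0)
  expect_lt(interval_mapping_scan(y_dn, gp)$additive[at], 0)
})

test_that("ICIM reduces to plain interval mapping when nothing enters", {
  pop <- sim_chrom(60, seed = 10)
  gp <- genotype_probabilities(pop$geno, pop$map)
  set.seed(11)
  y <- setNames(rnorm(60), rownames(pop$geno))   # pure noise
  im <- interval_mapping_scan(y, gp)
  ic <- icim_scan(y, pop$geno, gp, pin = 1e-6)
  expect_length(attr(ic, "selected"), 0)
  expect_equal(ic$lod, im$lod, tolerance = 1e-12)
})

test_that("ICIM re-detects a QTL in its own interval at full strength", {
  pop <- sim_chrom(237, seed = 12)
  gp <- genotype_probabilities(pop$geno, pop$map)
  set.seed(13)
  score <- ifelse(pop$geno[, 11] == 2L, 1, -1)
  y <- setNames(score + rnorm(237, 0, 2), rownames(pop$geno))
  im <- interval_mapping_scan(y, gp)
  ic <- icim_scan(y, pop$geno, gp)
  peak_im <- max(im$lod)
  peak_ic <- max(ic$lod[abs(ic$cm - 50) <= 10])
  expect_gt(peak_ic, 0.9 * peak_im)
})

test_that("background adjustment raises power with a second unlinked QTL", {
  ms <- map_spec(data.frame(chrom = c("1", "2"), length_cm = 100,
                            n_markers = 21))
  wins <- 0; n_runs <- 60
  for (i in seq_len(n_runs)) {
    pop <- simulate_ril_population(ms, 150, het_rate = 0, seed = 500 + i)
    g <- set_het_missing(pop$geno)
    gp <- genotype_probabilities(g, pop$map)
    set.seed(600 + i)
    s1 <- ifelse(g[, 11] == 2L, 1, -1)      # chr1, 50 cM
    s2 <- ifelse(g[, 32] == 2L, 1, -1)      # chr2, 50 cM
    y <- setNames(0.6 * s1 + 0.9 * s2 + rnorm(150), rownames(g))
    on1 <- gp$positions$chrom == "1" & abs(gp$positions$cm - 50) <= 5
    lod_im <- max(interval_mapping_scan(y, gp)$lod[on1])
    lod_ic <- max(icim_scan(y, g, gp)$lod[on1])
    if (lod_ic >= lod_im) wins <- wins + 1
  }
  expect_gte(wins / n_runs, 0.9)
})

test_that("QTL calling applies thresholds, separation and naming rules", {
  flat <- data.frame(chrom = "1", cm = 0:100, lod = 1.5, additive = 0.1,
                     pve = 0.05, n = 100)
  expect_equal(nrow(call_qtl(flat)), 0)
  # single peak at chr5, 119 cM
  cm <- 0:150
  prof <- data.frame(chrom = "5", cm = cm,
                     lod = 4 * exp(-(cm - 119)^2 / 50),
                     additive = 0.03, pve = 0.08, n = 100)
  calls <- call_qtl(prof)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$name, "q5_119")
  expect_true(calls$ci_lo_cm <= 119 & calls$ci_hi_cm >= 119)
  # two peaks 60 cM apart with a deep valley are separate calls
  prof2 <- data.frame(chrom = "1", cm = cm,
                      lod = 3 * exp(-(cm - 40)^2 / 30) +
                        3.5 * exp(-(cm - 100)^2 / 30),
                      additive = 0.03, pve = 0.08, n = 100)
  calls2 <- call_qtl(prof2)
  expect_equal(nrow(calls2), 2)
  expect_equal(sort(calls2$peak_cm), c(40, 100))
  # a peak passing LOD but failing PVE is not called
  prof3 <- prof; prof3$pve <- 0.01
  expect_equal(nrow(call_qtl(prof3)), 0)
})

test_that("injected QTL peaks localize near the simulated position", {
  hits <- 0; n_runs <- 40
  for (i in seq_len(n_runs)) {
    pop <- sim_chrom(237, seed = 700 + i)
    gp <- genotype_probabilities(pop$geno, pop$map)
    set.seed(800 + i)
    score <- ifelse(pop$geno[, 11] == 2L, 1, -1)   # QTL at 50 cM
    y <- setNames(score + rnorm(237, 0, 2), rownames(pop$geno))  # PVE 20%
    pr <- interval_mapping_scan(y, gp)
    if (abs(pr$cm[which.max(pr$lod)] - 50) <= 10) hits <- hits + 1
  }
  expect_gte(hits / n_runs, 0.95)
})
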