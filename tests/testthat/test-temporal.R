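sim_daily_setup <- function(n_lines = 237, seed = 1) {
  ms <- map_spec(data.frame(chrom = "1", length_cm = 100, n_markers = 21))
  pop <- simulate_ril_population(ms, n_lines, het_rate = 0, seed = seed)
  pop$geno <- set_het_missing(pop$geno)
  pop$gp <- genotype_probabilities(pop$geno, pop$map)
  pop
}

daily_matrix <- function(pop, effect, window, noise_sd, seed,
                         marker = 11) {
  set.seed(seed)
  days <- 1:85
  base <- weibull_height(days, 1.1, 58, 7)
  score <- ifelse(pop$geno[, marker] == 2L, 1, -1)
  n <- nrow(pop$geno)
  m <- t(vapply(seq_len(n), function(i) {
    base + (days >= window[1] & days <= window[2]) * effect * score[i] +
      rnorm(85, 0, noise_sd)
  }, numeric(85)))
  dimnames(m) <- list(rownames(pop$geno), paste0("d", days))
  m
}

test_that("daily scans emit one complete profile per day", {
  pop <- sim_daily_setup(60, seed = 2)
  daily <- daily_matrix(pop, effect = 0, window = c(0, 0),
                        noise_sd = 0.02, seed = 3)
  scans <- scan_all_days(daily, pop$geno, pop$gp, method = "im")
  expect_length(scans$profiles, 85)
  expect_equal(scans$days, 1:85)
  expect_true(all(vapply(scans$profiles, nrow, numeric(1)) ==
                    nrow(pop$gp$positions)))
})

test_that("zero genetic variance gives all-zero daily LOD", {
  pop <- sim_daily_setup(40, seed = 4)
  days <- 1:85
  base <- weibull_height(days, 1.1, 58, 7)
  daily <- matrix(rep(base, each = 40), 40,
                  dimnames = list(rownames(pop$geno), paste0("d", days)))
  scans <- scan_all_days(daily, pop$geno, pop$gp, method = "im")
  expect_true(all(vapply(scans$profiles, function(p) all(p$lod == 0),
                         logical(1))))
  tq <- cluster_temporal(scans)
  expect_equal(nrow(tq$qtl), 0)
})

test_that("an asymptote QTL grows in signal through the season", {
  pop <- sim_daily_setup(150, seed = 5)
  set.seed(6)
  days <- 1:85
  score <- ifelse(pop$geno[, 11] == 2L, 1, -1)
  # effect proportional to the growth curve: an asymptote (L) locus
  base <- weibull_height(days, 1.1, 58, 7)
  m <- t(vapply(seq_len(150), function(i) {
    base * (1 + 0.04 * score[i]) + rnorm(85, 0, 0.02)
  }, numeric(85)))
  dimnames(m) <- list(rownames(pop$geno), paste0("d", days))
  scans <- scan_all_days(m, pop$geno, pop$gp, method = "im")
  at <- which(pop$gp$positions$cm == 50)
  lod_early <- mean(vapply(scans$profiles[10:20],
                           function(p) p$lod[at], numeric(1)))
  lod_late <- mean(vapply(scans$profiles[70:80],
                          function(p) p$lod[at], numeric(1)))
  expect_gt(lod_late, lod_early)
})

test_that("a noise-free windowed QTL clusters to exactly its active span", {
  pop <- sim_daily_setup(237, seed = 7)
  daily <- daily_matrix(pop, effect = 0.03, window = c(22, 62),
                        noise_sd = 0, seed = 8)
  scans <- scan_all_days(daily, pop$geno, pop$gp, method = "im")
  tq <- cluster_temporal(scans)
  expect_equal(nrow(tq$qtl), 1)
  expect_equal(tq$qtl$onset, 22)
  expect_equal(tq$qtl$offset, 62)
  expect_lt(abs(tq$qtl$peak_cm - 50), 5)
  # trajectories cover all 85 days
  expect_equal(nrow(tq$trajectories), 85)
})

test_that("a noisy windowed QTL is recovered by its dominant cluster", {
  pop <- sim_daily_setup(237, seed = 7)
  daily <- daily_matrix(pop, effect = 0.03, window = c(22, 62),
                        noise_sd = 0.05, seed = 8)
  scans <- scan_all_days(daily, pop$geno, pop$gp, method = "im")
  tq <- cluster_temporal(scans)
  expect_gte(nrow(tq$qtl), 1)
  main <- tq$qtl[which.max(tq$qtl$max_lod), ]
  expect_lte(abs(main$onset - 22), 3)
  expect_lte(abs(main$offset - 62), 3)
  expect_lt(abs(main$peak_cm - 50), 10)
})

test_that("two distant QTL resolve into two season-long ICIM clusters", {
  # with two strong loci 50 cM apart, plain interval mapping leaves a
  # ghost ridge between them; the ICIM background adjustment collapses
  # the profile to the two real peaks
  pop <- sim_daily_setup(237, seed = 9)
  set.seed(10)
  days <- 1:85
  base <- weibull_height(days, 1.1, 58, 7)
  s1 <- ifelse(pop$geno[, 6] == 2L, 1, -1)    # 25 cM
  s2 <- ifelse(pop$geno[, 16] == 2L, 1, -1)   # 75 cM
  m <- t(vapply(seq_len(237), function(i) {
    base + 0.03 * s1[i] + 0.03 * s2[i] + rnorm(85, 0, 0.05)
  }, numeric(85)))
  dimnames(m) <- list(rownames(pop$geno), paste0("d", days))
  scans <- scan_all_days(m, pop$geno, pop$gp, method = "icim")
  tq <- cluster_temporal(scans)
  season_long <- tq$qtl[tq$qtl$n_days >= 50, ]
  expect_equal(nrow(season_long), 2)
  expect_equal(sort(round(season_long$peak_cm / 25) * 25), c(25, 75))
})

test_that("cluster count is monotone non-increasing in the window", {
  pop <- sim_daily_setup(150, seed = 11)
  daily <- daily_matrix(pop, effect = 0.03, window = c(20, 70),
                        noise_sd = 0.06, seed = 12)
  scans <- scan_all_days(daily, pop$geno, pop$gp, method = "im")
  counts <- vapply(c(2, 5, 10, 20, 40), function(w) {
    nrow(cluster_temporal(scans, window_cm = w)$qtl)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # determinism
  a <- cluster_temporal(scans)
  b <- cluster_temporal(scans)
  expect_identical(a$qtl, b$qtl)
})

test_that("sign switches require significance on both sides", {
  traj <- data.frame(das = 1:85, lod = 5,
                     additive = c(rep(0.05, 50), rep(-0.05, 35)))
  out <- detect_sign_switch(traj)
  expect_true(out$switched)
  expect_equal(out$switch_das[1], 51)
  # constant sign: no switch
  traj2 <- traj; traj2$additive <- 0.05
  expect_false(detect_sign_switch(traj2)$switched)
  # crossing happens only while below threshold: no switch
  traj3 <- traj
  traj3$lod <- c(rep(5, 40), rep(0.5, 45))
  expect_false(detect_sign_switch(traj3)$switched)
})

test_that("co-localization pairs QTL within the window only", {
  qa <- data.frame(name = c("q1_40", "q2_10"), chrom = c("1", "2"),
                   peak_cm = c(40, 10))
  qb <- data.frame(name = c("q1_44", "q1_55", "q3_10"),
                   chrom = c("1", "1", "3"), peak_cm = c(44, 55, 10))
  out <- colocalize(list(asymptote = qa, terminal = qb), window_cm = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$qtl1, "q1_40")
  expect_equal(out$qtl2, "q1_44")
  expect_equal(out$distance_cm, 4)
  # identical peaks pair at distance zero
  out2 <- colocalize(list(a = qa, b = qa), window_cm = 10)
  expect_true(any(out2$distance_cm == 0))
  # 15 cM apart with window 10 never pairs
  qc <- data.frame(name = "q1_55", chrom = "1", peak_cm = 55)
  expect_equal(nrow(colocalize(list(a = qa, b = qc), window_cm = 10)), 0)
})

test_that("candidate-gene distances and bins match brute force", {
  genes <- data.frame(name = sprintf("g%d", 1:5),
                      chrom = c("1", "1", "2", "2", "3"),
                      start = c(100.4e6, 200e6, 50e6, 80e6, 10e6),
                      end = c(100.6e6, 201e6, 51e6, 81e6, 11e6))
  qtl <- data.frame(name = c("qA", "qB", "qC"),
                    chrom = c("1", "2", "4"),
                    bp_lo = c(99e6, 50.2e6, 5e6),
                    bp_hi = c(101e6, 51.0e6, 6e6))
  out <- candidate_gene_distance(qtl, genes)
  # center 100.0 Mb, gene at 100.4-100.6 -> 0.4 Mb
  expect_equal(out$distances$distance_bp[1], 0.4e6)
  # center inside the gene span -> 0
  expect_equal(out$distances$distance_bp[2], 0)
  # chromosome without genes -> NA
  expect_true(is.na(out$distances$distance_bp[3]))
  # bin counts against brute force over all genes
  brute <- vapply(seq_len(nrow(qtl)), function(i) {
    g <- genes[genes$chrom == qtl$chrom[i], ]
    if (nrow(g) == 0) return(NA_real_)
    center <- (qtl$bp_lo[i] + qtl$bp_hi[i]) / 2
    min(ifelse(center >= g$start & center <= g$end, 0,
               pmin(abs(center - g$start), abs(center - g$end))))
  }, numeric(1))
  expect_equal(out$n_within_1mb, sum(brute < 1e6, na.rm = TRUE))
  expect_equal(out$n_within_5mb, sum(brute < 5e6, na.rm = TRUE))
})
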