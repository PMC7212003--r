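test_that("Kosambi function matches closed forms and round-trips", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  expect_equal(round(kosambi_cm(0.25), 3), 27.465)
  expect_error(kosambi_cm(0.5))
  for (r in c(0.01, 0.1, 0.25, 0.4, 0.49)) {
    expect_equal(kosambi_r(kosambi_cm(r)), r, tolerance = 1e-12)
  }
  # strictly increasing and convex
  r <- seq(0, 0.49, by = 0.01)
  d <- kosambi_cm(r)
  expect_true(all(diff(d) > 0))
  expect_true(all(diff(diff(d)) > 0))
})

test_that("selfed-RIL recombination algebra inverts exactly", {
  expect_equal(ril_r(0), 0)
  expect_equal(ril_r(1 / 3), 0.25)
  for (r in c(0.05, 0.1, 0.3)) expect_equal(ril_r(ril_R(r)), r)
})

test_that("missing-data filters use strict thresholds", {
  g <- qc_fixture()
  out <- filter_missing(g)
  expect_equal(dim(out$geno), c(5, 9))
  expect_equal(out$report$lines_dropped, "L2")
  expect_equal(out$report$markers_dropped, "M4")
  # complete matrix passes unchanged
  g2 <- matrix(0L, 4, 4, dimnames = list(letters[1:4], LETTERS[1:4]))
  expect_identical(filter_missing(g2)$geno, g2)
  # exactly 10% missing is retained
  g3 <- matrix(0L, 3, 10, dimnames = list(letters[1:3], sprintf("M%d", 1:10)))
  g3[1, 1] <- -1L
  expect_equal(nrow(filter_missing(g3)$geno), 3)
  g4 <- g3; g4[, 1:2] <- -1L               # every line 20% missing
  expect_error(filter_missing(g4))
})

test_that("het calls become missing, nothing else changes", {
  v <- matrix(c(0L, 1L, 2L, -1L), 1)
  expect_equal(as.integer(set_het_missing(v)), c(0L, -1L, 2L, -1L))
  g <- matrix(c(0L, 2L, 2L, 0L), 2)
  expect_identical(set_het_missing(g), g)
  set.seed(3)
  g2 <- matrix(sample(c(0L, 1L, 2L), 400, replace = TRUE,
                      prob = c(0.45, 0.1, 0.45)), 20)
  h <- mean(g2 == 1)
  expect_equal(mean(set_het_missing(g2) == -1), h)
})

sim_dense <- function(n_lines, n_markers = 201, length_cm = 100, seed = 1) {
  ms <- map_spec(data.frame(chrom = "1", length_cm = length_cm,
                            n_markers = n_markers))
  simulate_ril_population(ms, n_lines, het_rate = 0, seed = seed)
}

test_that("single-call islands are flipped without adding breakpoints", {
  map <- data.frame(marker = sprintf("M%d", 1:9), chrom = "1",
                    bp = (1:9) * 1e6, cm = 0:8)
  g <- matrix(rep(c(rep(0L, 4), rep(2L, 5)), 2), 2, byrow = TRUE,
              dimnames = list(c("a", "b"), map$marker))
  g[1, 2] <- 2L                            # island of 2 inside the 0-run
  out <- clean_double_recombinants(g, map)
  expect_equal(unname(out$geno[1, 2]), 0L)
  expect_equal(out$n_corrected, 1L)
  # both lines keep exactly the one true breakpoint between M4 and M5
  expect_equal(nrow(out$breakpoints), 2)
  expect_equal(out$breakpoints$pos_cm, c(3.5, 3.5))
})

test_that("true crossovers on clean data survive cleaning untouched", {
  # fixture seed chosen so the simulated lines carry no sub-minimum true
  # runs; cleaning must then be the identity
  pop <- sim_dense(50, n_markers = 21, length_cm = 20, seed = 6)
  out <- clean_double_recombinants(pop$geno, pop$map)
  expect_identical(out$geno, pop$geno)
  expect_equal(out$n_corrected, 0L)
  # each reported breakpoint sits within one marker interval of a true one
  for (i in seq_len(nrow(out$breakpoints))) {
    tl <- pop$breakpoints[pop$breakpoints$line == out$breakpoints$line[i], ]
    expect_lt(min(abs(tl$pos_cm - out$breakpoints$pos_cm[i])), 1 + 1e-9)
  }
})

test_that("cleaning corrects injected errors as well as the DP oracle", {
  pop <- sim_dense(100, seed = 8)
  g <- pop$geno
  set.seed(9)
  err <- which(runif(length(g)) < 0.01)
  g2 <- g; g2[err] <- 2L - g[err]
  out <- clean_double_recombinants(g2, pop$map, min_run_markers = 3)
  rate <- mean(out$geno[err] == g[err])
  # DP segmentation oracle on the same corrupted data
  dp <- g2
  for (li in seq_len(nrow(g2))) dp[li, ] <- dp_segment(g2[li, ])
  rate_dp <- mean(dp[err] == g[err])
  expect_gte(rate, 0.9)
  expect_gte(rate, rate_dp - 0.05)
  # idempotence: second pass is a no-op
  out2 <- clean_double_recombinants(out$geno, pop$map, min_run_markers = 3)
  expect_identical(out2$geno, out$geno)
})

test_that("redundant markers bin to the least-missing representative", {
  map <- data.frame(marker = c("A", "B", "C", "D"), chrom = "1",
                    bp = 1:4 * 1e6, cm = c(0, 0, 5, 10))
  g <- cbind(A = c(0L, 0L, 2L, 2L, 0L),
             B = c(0L, -1L, 2L, 2L, 0L),   # same pattern, more missing
             C = c(0L, 0L, 2L, 2L, 0L),    # identical to A as well
             D = c(2L, 0L, 2L, 2L, 0L))
  rownames(g) <- letters[1:5]
  out <- bin_redundant_markers(g, map)
  expect_equal(out$keep, c("A", "D"))
  expect_equal(out$bins$representative, c("A", "A", "A", "D"))
  # all-distinct matrix stays whole
  g2 <- cbind(A = c(0L, 0L, 2L), B = c(2L, 0L, 0L))
  rownames(g2) <- letters[1:3]
  out2 <- bin_redundant_markers(g2, map[1:2, ])
  expect_equal(out2$keep, c("A", "B"))
  # brute-force O(m^2) duplicate count agrees
  pop <- sim_dense(30, n_markers = 51, length_cm = 25, seed = 10)
  out3 <- bin_redundant_markers(pop$geno, pop$map)
  dup_pairs <- outer(seq_len(51), seq_len(51), Vectorize(function(i, j) {
    i < j && all(pop$geno[, i] == pop$geno[, j])
  }))
  n_groups <- 51 - sum(apply(dup_pairs, 2, any))
  expect_equal(length(out3$keep), n_groups)
})

test_that("recombination estimates invert the RIL expectation", {
  g <- cbind(m1 = rep(c(0L, 2L), each = 15),
             m2 = rep(c(0L, 2L), each = 15))
  g[1:10, 2] <- 2L - g[1:10, 2]            # 10/30 recombinant
  rownames(g) <- sprintf("l%d", 1:30)
  est <- estimate_recombination(g, "m1", "m2")
  expect_equal(est$R, 1 / 3)
  expect_equal(est$r, 0.25)
  expect_error(estimate_recombination(g[1:10, ], "m1", "m2"))
  # simulation: 10,000 RILs at r = 0.10
  ms <- map_spec(data.frame(chrom = "1", length_cm = kosambi_cm(0.10),
                            n_markers = 2))
  pop <- simulate_ril_population(ms, 10000, het_rate = 0, seed = 11)
  est2 <- estimate_recombination(pop$geno, colnames(pop$geno)[1],
                                 colnames(pop$geno)[2])
  expect_lt(abs(est2$r - 0.10), 0.008)
})

test_that("map construction recovers simulated chromosome length", {
  pop <- sim_dense(200, n_markers = 101, length_cm = 100, seed = 12)
  bm <- build_map(set_het_missing(pop$geno), pop$map)
  expect_lt(abs(bm$lengths[["1"]] - 100), 10)
  expect_true(all(diff(bm$map$cm) >= 0))
  expect_equal(sum(diff(bm$map$cm)), bm$total_length_cm, tolerance = 1e-9)
  # two perfectly linked markers map 0 cM apart
  g <- cbind(a = rep(c(0L, 2L), 15), b = rep(c(0L, 2L), 15))
  rownames(g) <- sprintf("l%d", 1:30)
  pm <- data.frame(marker = c("a", "b"), chrom = "1", bp = c(1, 2) * 1e6)
  bm2 <- build_map(g, pm)
  expect_equal(bm2$total_length_cm, 0)
  # unlinked markers hit the cap and are flagged
  set.seed(13)
  g3 <- cbind(a = sample(c(0L, 2L), 200, TRUE),
              b = sample(c(0L, 2L), 200, TRUE))
  rownames(g3) <- sprintf("l%d", 1:200)
  bm3 <- build_map(g3, pm)
  expect_true(any(bm3$map$capped))
})
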