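#' Trait architecture for simulated growth curves
#'
#' Defines how genotype maps to the three Weibull growth parameters: a QTL
#' table of additive effects plus independent polygenic deviations per
#' parameter. QTL act on `L` (asymptote, m), `x0` (inflection-point
#' parameter, DAS) or `b` (shape); a QTL with `param = "height"` acts
#' directly on observed height within an activity window of DAS
#' (an "opportunistic" locus responding to a transient stimulus rather
#' than shifting the whole curve).
#'
#' @param qtl data.frame with columns `chrom`, `pos_cm`, `param`
#'   (one of `"L"`, `"x0"`, `"b"`, `"height"`), `effect` (additive effect in
#'   parameter units; the parent-B allele adds `+effect`), and optionally
#'   `window_start`, `window_end` (DAS; only for `param = "height"`).
#'   May be empty (no major loci).
#' @param means named numeric: population means `L` (m), `x0` (DAS), `b`.
#'   Defaults L = 1.10 m, x0 = 58 DAS, b = 7, matching inbred maize.
#' @param polygenic_sd named numeric: sd of polygenic deviations per
#'   parameter (same units).
#' @return `trait_architecture` object (a validated list).
#' @export
trait_architecture <- function(qtl = NULL,
                               means = c(L = 1.10, x0 = 58, b = 7),
                               polygenic_sd = c(L = 0.05, x0 = 2, b = 0.5)) {
  if (is.null(qtl) || nrow(qtl) == 0) {
    qtl <- data.frame(chrom = character(), pos_cm = numeric(),
                      param = character(), effect = numeric(),
                      window_start = numeric(), window_end = numeric())
  }
  if (!all(qtl$param %in% c("L", "x0", "b", "height"))) {
    stop("qtl$param must be one of L, x0, b, height")
  }
  if (!all(is.finite(qtl$effect))) stop("QTL effects must be finite")
  if (is.null(qtl$window_start)) qtl$window_start <- NA_real_
  if (is.null(qtl$window_end)) qtl$window_end <- NA_real_
  stopifnot(all(means[c("L", "x0", "b")] > 0),
            all(polygenic_sd >= 0))
  structure(list(qtl = qtl, means = means, polygenic_sd = polygenic_sd),
            class = "trait_architecture")
}

#' Field trial design for the simulator
#'
#' Randomized complete block design: each entry appears once per replicate
#' block within each environment, plots indexed by range (along the
#' irrigation run) and row. Defaults mirror a two-environment
#' (irrigated / non-irrigated), two-replicate maize trial flown on eight
#' usable dates (35, 43, 57, 62, 65, 69, 100, 117 DAS).
#'
#' @param environments environment labels.
#' @param n_reps replicates (blocks) per environment.
#' @param n_rows rows per range in the field grid (plots fill ranges
#'   sequentially, `n_rows` plots per range).
#' @param flights flight schedule, DAS (> 0).
#' @param sd_flight residual measurement sd per plot x flight, m.
#' @param sd_rep,sd_range,sd_row sd of replicate / range / row random
#'   effects, m.
#' @param env_param_shift named list: per-environment additive shift of the
#'   parameter means `c(L=, x0=, b=)`. The default delays the inflection
#'   point by 2 DAS and lowers asymptote and shape under the non-irrigated
#'   regime, the direction of the study's water-stress response.
#' @return `trial_design` object.
#' @export
trial_design <- function(environments = c("irrigated", "non_irrigated"),
                         n_reps = 2,
                         n_rows = 8,
                         flights = c(35, 43, 57, 62, 65, 69, 100, 117),
                         sd_flight = 0.03,
                         sd_rep = 0.01, sd_range = 0.015, sd_row = 0.01,
                         env_param_shift = NULL) {
  stopifnot(all(flights > 0), n_reps >= 1, n_rows >= 1,
            sd_flight >= 0, sd_rep >= 0, sd_range >= 0, sd_row >= 0)
  if (is.null(env_param_shift)) {
    env_param_shift <- lapply(environments, function(e) {
      if (grepl("non", e)) c(L = -0.05, x0 = 2, b = -0.8)
      else c(L = 0, x0 = 0, b = 0)
    })
    names(env_param_shift) <- environments
  }
  structure(list(environments = environments, n_reps = n_reps,
                 n_rows = n_rows, flights = flights,
                 sd_flight = sd_flight, sd_rep = sd_rep,
                 sd_range = sd_range, sd_row = sd_row,
                 env_param_shift = env_param_shift),
            class = "trial_design")
}

# additive genotype score (-1, 0, +1) at the marker nearest a QTL position
.qtl_score <- function(geno, map, chrom, pos_cm) {
  idx <- which(map$chrom == as.character(chrom))
  if (length(idx) == 0) stop("QTL chromosome not in map: ", chrom)
  m <- idx[which.min(abs(map$cm[idx] - pos_cm))]
  g <- geno[, m]
  s <- numeric(length(g))
  s[g == 0] <- -1
  s[g == 2] <- 1
  s  # het (1) and missing (-1) contribute 0
}

#' Simulate a multi-flight height trial over a RIL population
#'
#' Draws per-entry growth parameters (population mean + environment shift +
#' QTL additive effects + polygenic deviation), lays entries out in an RCBD
#' within each environment, and emits one height observation per plot and
#' flight:
#' `height = f(DAS; L_i, x0_i, b_i) + windowed QTL effects + rep + range +
#' row + noise`, where `f` is the Weibull sigmoid. All draws are recorded
#' in a ground-truth object for recovery tests.
#'
#' @param pop a population as returned by [simulate_ril_population()]
#'   (list with `geno` and `map`).
#' @param architecture a [trait_architecture()].
#' @param design a [trial_design()].
#' @param seed optional integer seed.
#' @return List with `obs` (data.frame: `entry`, `env`, `rep`, `range`,
#'   `row`, `das`, `height_m`) and `truth` (per-entry true parameters by
#'   environment, the QTL table, true variance components, and the random
#'   effect draws).
#' @export
simulate_trial <- function(pop, architecture, design, seed = NULL) {
  stopifnot(inherits(architecture, "trait_architecture"),
            inherits(design, "trial_design"))
  if (!is.null(seed)) set.seed(seed)
  geno <- pop$geno; map <- pop$map
  entries <- rownames(geno)
  n <- length(entries)
  if (is.null(entries)) stop("genotype matrix must have line ids as rownames")

  qtl <- architecture$qtl
  means <- architecture$means
  psd <- architecture$polygenic_sd

  # genotype scores per QTL (shared across environments)
  scores <- if (nrow(qtl) > 0) {
    vapply(seq_len(nrow(qtl)),
           function(k) .qtl_score(geno, map, qtl$chrom[k], qtl$pos_cm[k]),
           numeric(n))
  } else matrix(0, n, 0)

  # polygenic deviations: one draw per entry per parameter, shared across envs
  poly <- cbind(L = stats::rnorm(n, 0, psd[["L"]]),
                x0 = stats::rnorm(n, 0, psd[["x0"]]),
                b = stats::rnorm(n, 0, psd[["b"]]))

  qtl_on <- function(param) {
    k <- which(qtl$param == param)
    if (length(k) == 0) rep(0, n)
    else as.numeric(scores[, k, drop = FALSE] %*% qtl$effect[k])
  }
  gL <- qtl_on("L"); gx0 <- qtl_on("x0"); gb <- qtl_on("b")
  hk <- which(qtl$param == "height")

  obs_list <- list(); truth_pars <- list(); effects_log <- list()
  for (env in design$environments) {
    sh <- design$env_param_shift[[env]]
    L  <- pmax(means[["L"]] + sh[["L"]] + gL + poly[, "L"], 0.05)
    x0 <- pmax(means[["x0"]] + sh[["x0"]] + gx0 + poly[, "x0"], 5)
    b  <- pmax(means[["b"]] + sh[["b"]] + gb + poly[, "b"], 0.5)
    truth_pars[[env]] <- data.frame(entry = entries, env = env,
                                    L = L, x0 = x0, b = b)

    rep_eff <- stats::rnorm(design$n_reps, 0, design$sd_rep)
    n_ranges <- ceiling(n * design$n_reps / design$n_rows)
    range_eff <- stats::rnorm(n_ranges, 0, design$sd_range)
    row_eff <- stats::rnorm(design$n_rows, 0, design$sd_row)
    effects_log[[env]] <- list(rep = rep_eff, range = range_eff,
                               row = row_eff)

    plot_k <- 0
    for (r in seq_len(design$n_reps)) {
      ord <- sample.int(n)                  # RCBD randomization within block
      for (i in ord) {
        plot_k <- plot_k + 1
        rng <- (plot_k - 1) %/% design$n_rows + 1
        row <- (plot_k - 1) %% design$n_rows + 1
        das <- design$flights
        h <- weibull_height(das, L[i], x0[i], b[i])
        if (length(hk) > 0) {
          for (k in hk) {
            inwin <- das >= qtl$window_start[k] & das <= qtl$window_end[k]
            h <- h + inwin * qtl$effect[k] * scores[i, k]
          }
        }
        h <- h + rep_eff[r] + range_eff[rng] + row_eff[row] +
          stats::rnorm(length(das), 0, design$sd_flight)
        obs_list[[length(obs_list) + 1]] <- data.frame(
          entry = entries[i], env = env, rep = r, range = rng, row = row,
          das = das, height_m = h, stringsAsFactors = FALSE)
      }
    }
  }
  obs <- do.call(rbind, obs_list)
  rownames(obs) <- NULL
  truth <- list(
    entry_params = do.call(rbind, truth_pars),
    qtl = qtl,
    variance_components = data.frame(
      component = c("rep", "range", "row", "residual"),
      sd = c(design$sd_rep, design$sd_range, design$sd_row,
             design$sd_flight)),
    effects = effects_log,
    breakpoints = pop$breakpoints
  )
  list(obs = obs, truth = truth)
}
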