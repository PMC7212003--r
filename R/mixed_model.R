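#' Fit the per-flight random-effects model by REML
#'
#' Fits `height = mu + G + Rep + Range + Row + error` with all design terms
#' random, as appropriate for an RCBD with spatial (range/row) structure,
#' to one flight date x environment x population slice. Estimation is
#' REML via lme4; variance components at the zero boundary are reported as
#' zero with a boundary flag. Terms absent from `random_terms` (or with a
#' single observed level) are dropped from the model and reported as zero.
#'
#' @param obs data.frame with the response column and the design columns
#'   (`entry`, `rep`, `range`, `row` by default).
#' @param response response column name (default `"height_m"`).
#' @param random_terms design columns fit as random intercepts. `"entry"`
#'   (genotype) must be present.
#' @return Object of class `reml_fit`: `varcomp` (named vector `G`, `Rep`,
#'   `Range`, `Row`, `residual`, in squared response units), `blup`
#'   (data.frame `entry`, `blup` deviation, `predicted = mu + blup`),
#'   `mu`, `logLik` (restricted), `converged`, `boundary` (names of
#'   components pinned at zero), `n_obs`.
#' @export
fit_reml <- function(obs, response = "height_m",
                     random_terms = c("entry", "rep", "range", "row")) {
  stopifnot(is.data.frame(obs), response %in% names(obs),
            "entry" %in% random_terms,
            all(random_terms %in% names(obs)))
  y <- obs[[response]]
  if (length(y) <= length(random_terms)) stop("too few observations")

  # keep only terms with >= 2 observed levels
  usable <- random_terms[vapply(random_terms,
                                function(tm) length(unique(obs[[tm]])) >= 2,
                                logical(1))]
  if (!"entry" %in% usable) stop("genotype term needs >= 2 levels")
  for (tm in usable) obs[[tm]] <- factor(obs[[tm]])

  form <- stats::as.formula(paste(
    response, "~ 1 +",
    paste(sprintf("(1 | %s)", usable), collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(form, data = obs, REML = TRUE,
               control = lme4::lmerControl(check.nlev.gtr.1 = "ignore",
                                           calc.derivs = FALSE))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp_of <- c(entry = "G", rep = "Rep", range = "Range", row = "Row")
  varcomp <- c(G = 0, Rep = 0, Range = 0, Row = 0, residual = 0)
  for (i in seq_len(nrow(vc))) {
    grp <- vc$grp[i]
    nm <- if (grp == "Residual") "residual" else comp_of[[grp]]
    varcomp[nm] <- vc$vcov[i]
  }
  boundary <- names(varcomp)[varcomp < 1e-10 &
                               names(varcomp) %in% c(comp_of[usable])]
  varcomp[varcomp < 0] <- 0

  re <- lme4::ranef(fit)$entry
  mu <- unname(lme4::fixef(fit)[1])
  blup <- data.frame(entry = rownames(re), blup = re[, 1],
                     predicted = mu + re[, 1], stringsAsFactors = FALSE)

  # degenerate noise-free data: the profiled REML criterion is flat as the
  # residual variance vanishes, so take the method-of-moments limit
  # (entry-term-only models): sigma2_G = variance of entry means,
  # unshrunk BLUPs
  if (identical(usable, "entry") &&
      varcomp[["residual"]] < 1e-8 * stats::var(y)) {
    em <- tapply(y, obs$entry, mean)
    within_var <- mean(tapply(y, obs$entry, function(v) {
      if (length(v) < 2) 0 else stats::var(v)
    }))
    varcomp["G"] <- stats::var(as.numeric(em))
    varcomp["residual"] <- within_var
    mu <- mean(y)
    blup <- data.frame(entry = names(em),
                       blup = as.numeric(em) - mu,
                       predicted = as.numeric(em),
                       stringsAsFactors = FALSE)
  }
  conv <- is.null(fit@optinfo$conv$lme4$messages) ||
    !any(grepl("failed to converge", fit@optinfo$conv$lme4$messages))
  structure(list(varcomp = varcomp, blup = blup, mu = mu,
                 logLik = as.numeric(stats::logLik(fit)),
                 converged = conv, boundary = boundary,
                 n_obs = nrow(obs)),
            class = "reml_fit")
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = sigma2_G / (sigma2_G + sigma2_e / n_reps)`.
#'
#' @param varcomp named vector with `G` and `residual` components (m^2), or
#'   a `reml_fit`.
#' @param n_reps number of replicates (>= 1).
#' @return H2 in `[0, 1]`; `NA` when both components are zero.
#' @export
heritability <- function(varcomp, n_reps) {
  if (inherits(varcomp, "reml_fit")) varcomp <- varcomp$varcomp
  stopifnot(n_reps >= 1, varcomp[["G"]] >= 0, varcomp[["residual"]] >= 0)
  den <- varcomp[["G"]] + varcomp[["residual"]] / n_reps
  if (den == 0) return(NA_real_)
  unname(varcomp[["G"]] / den)
}

#' Percent-of-variance decomposition
#'
#' Each variance component as a percentage of the total (the Figure-style
#' stacked decomposition reported per flight date).
#'
#' @param varcomp named non-negative vector of variance components, or a
#'   `reml_fit`.
#' @return Named vector of shares in percent, summing to 100.
#' @export
percent_variance_table <- function(varcomp) {
  if (inherits(varcomp, "reml_fit")) varcomp <- varcomp$varcomp
  total <- sum(varcomp)
  if (total <= 0) stop("total variance must be > 0")
  100 * varcomp / total
}

#' Fisher's least significant difference (LSD) letter groups
#'
#' Pairs of means further apart than
#' `t(1 - alpha/2, df) * sqrt(2 * mse / n)` are declared different.
#' Letters are assigned deterministically: means sorted descending, then
#' greedy grouping — each mean gets the letters of all maximal runs of
#' mutually non-different means it belongs to.
#'
#' @param means named numeric vector of group means.
#' @param mse error mean square.
#' @param df error degrees of freedom (>= 1).
#' @param n_per_group replications per group mean (>= 1).
#' @param alpha significance level.
#' @return data.frame `group`, `mean`, `letters`, sorted by descending
#'   mean; attribute `"lsd"` holds the threshold.
#' @export
lsd_test <- function(means, mse, df, n_per_group, alpha = 0.05) {
  stopifnot(df >= 1, n_per_group >= 1, alpha > 0, alpha < 1, mse >= 0)
  lsd <- stats::qt(1 - alpha / 2, df) * sqrt(2 * mse / n_per_group)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  k <- length(m)
  # maximal runs [i..j] of means that all agree within the LSD
  runs <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && (m[i] - m[j + 1]) <= lsd) j <- j + 1
    covered <- length(runs) > 0 &&
      runs[[length(runs)]][1] <= i && runs[[length(runs)]][2] >= j
    if (!covered) runs[[length(runs) + 1]] <- c(i, j)
    i <- i + 1
  }
  letters_of <- character(k)
  for (ri in seq_along(runs)) {
    span <- runs[[ri]]
    lab <- letters[(ri - 1) %% 26 + 1]
    idx <- span[1]:span[2]
    letters_of[idx] <- paste0(letters_of[idx], lab)
  }
  out <- data.frame(group = names(m), mean = unname(m),
                    letters = letters_of, stringsAsFactors = FALSE)
  attr(out, "lsd") <- lsd
  out
}

#' Per-flight REML fits over a phenotype table
#'
#' Splits long-format observations by flight date (and any further grouping
#' columns, e.g. environment and population) and fits [fit_reml()] to each
#' slice; the standard per-flight BLUP extraction step.
#'
#' @param obs long data.frame with `das` plus the [fit_reml()] columns.
#' @param by grouping columns (default `c("das", "env")`).
#' @param ... passed to [fit_reml()].
#' @return List with `varcomp` (long data.frame: group columns, component,
#'   estimate, share_pct, H2, n_obs, converged) and `blup` (group columns +
#'   entry, blup, predicted).
#' @export
blup_by <- function(obs, by = c("das", "env"), ...) {
  stopifnot(all(by %in% names(obs)))
  key <- interaction(obs[by], drop = TRUE, sep = "\r")
  vc_rows <- list(); blup_rows <- list()
  for (lev in levels(key)) {
    slice <- obs[key == lev, , drop = FALSE]
    fit <- fit_reml(slice, ...)
    n_reps <- length(unique(slice$rep))
    keyvals <- slice[1, by, drop = FALSE]
    share <- percent_variance_table(fit$varcomp)
    vc_rows[[lev]] <- cbind(
      keyvals,
      data.frame(component = names(fit$varcomp),
                 estimate = unname(fit$varcomp),
                 share_pct = unname(share),
                 H2 = heritability(fit, n_reps),
                 n_obs = fit$n_obs, converged = fit$converged),
      row.names = NULL)
    blup_rows[[lev]] <- cbind(keyvals, fit$blup, row.names = NULL)
  }
  list(varcomp = do.call(rbind, c(vc_rows, make.row.names = FALSE)),
       blup = do.call(rbind, c(blup_rows, make.row.names = FALSE)))
}
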