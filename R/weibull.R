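#' Three-parameter Weibull sigmoid growth curve
#'
#' `f(x) = L * (1 - exp(-(x/x0)^b))`: height (m) as a function of days after
#' sowing `x`, with asymptote `L` (terminal height, m), inflection-point
#' parameter `x0` (DAS) and unitless shape `b`. Unlike the logistic, the
#' inflection is not pinned to half the asymptote, which suits the
#' asymmetric growth of maize. At `x = x0` the curve passes through
#' `L * (1 - 1/e) ~= 0.632 L`.
#'
#' @param x days after sowing (>= 0), vectorized.
#' @param L,x0,b curve parameters, all > 0.
#' @return Height in m, in `[0, L)`.
#' @export
weibull_height <- function(x, L, x0, b) {
  if (any(x < 0)) stop("x must be non-negative")
  stopifnot(L > 0, x0 > 0, b > 0)
  L * (1 - exp(-(x / x0)^b))
}

#' Absolute growth rate (AGR) of a fitted Weibull curve
#'
#' The analytic derivative of the growth curve,
#' `f'(x) = L * (b/x0) * (x/x0)^(b-1) * exp(-(x/x0)^b)`, reported in
#' mm/day.
#'
#' @param fit a `weibull_fit` (from [fit_weibull()]) or a list/vector with
#'   `L`, `x0`, `b`.
#' @param x days after sowing (>= 0), vectorized.
#' @return AGR in mm/day (>= 0).
#' @export
absolute_growth_rate <- function(fit, x) {
  if (any(x < 0)) stop("x must be non-negative")
  p <- as.list(fit)[c("L", "x0", "b")]
  L <- p$L; x0 <- p$x0; b <- p$b
  stopifnot(L > 0, x0 > 0, b > 0)
  u <- x / x0
  1000 * L * (b / x0) * u^(b - 1) * exp(-u^b)
}

#' Maximum absolute growth rate and its timing
#'
#' The calculus argmax of the Weibull AGR is `x0 * ((b-1)/b)^(1/b)` (for
#' `b > 1`), slightly earlier than `x0`. Field studies conventionally
#' report the maximum AGR at the inflection-point parameter `x = x0`
#' itself; both are returned, with the convention value (`das = x0`) as
#' the headline `agr_max`.
#'
#' @param fit a `weibull_fit` or list with `L`, `x0`, `b`.
#' @return List: `agr_max` (mm/day, AGR at `x0`), `das` (= x0),
#'   `agr_max_exact` (mm/day at the calculus argmax), `das_exact`.
#' @export
agr_max <- function(fit) {
  p <- as.list(fit)[c("L", "x0", "b")]
  das_exact <- if (p$b > 1) p$x0 * ((p$b - 1) / p$b)^(1 / p$b) else 0
  list(agr_max = absolute_growth_rate(p, p$x0),
       das = p$x0,
       agr_max_exact = if (das_exact > 0) absolute_growth_rate(p, das_exact)
                       else NA_real_,
       das_exact = das_exact)
}

#' Fit the Weibull growth curve to one entry's height trajectory
#'
#' Bounded Levenberg-Marquardt least squares. Starting values: `L` at the
#' maximum observed height, `x0` at the first time the trajectory exceeds
#' half of that maximum, `b = 5`; bounds `L in (0, 3*max]`, `x0 in (0,
#' 200]`, `b in (0.5, 30]`.
#'
#' @param times observation times, DAS.
#' @param heights observed heights, m (same length, >= 4 pairs over >= 3
#'   distinct times).
#' @param b_init starting shape value.
#' @return Object of class `weibull_fit`: `L`, `x0`, `b`, `r2`, `rmse` (m),
#'   `df` (residual degrees of freedom), `n`, `converged`, plus the data.
#'   Degenerate inputs (constant heights) return `converged = FALSE`.
#' @export
fit_weibull <- function(times, heights, b_init = 5) {
  ok <- is.finite(times) & is.finite(heights)
  times <- times[ok]; heights <- heights[ok]
  if (length(times) < 4 || length(unique(times)) < 3) {
    stop("need >= 4 observations over >= 3 distinct times")
  }
  out <- list(L = NA_real_, x0 = NA_real_, b = NA_real_,
              r2 = NA_real_, rmse = NA_real_,
              df = length(times) - 3L, n = length(times),
              converged = FALSE, times = times, heights = heights)
  class(out) <- "weibull_fit"
  hmax <- max(heights)
  if (stats::sd(heights) < 1e-12 || hmax <= 0) return(out)

  ord <- order(times)
  x0_start <- times[ord][which(heights[ord] >= hmax / 2)[1]]
  if (is.na(x0_start) || x0_start <= 0) x0_start <- stats::median(times)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      heights ~ L * (1 - exp(-(times / x0)^b)),
      start = list(L = hmax, x0 = x0_start, b = b_init),
      lower = c(L = 1e-6, x0 = 1e-6, b = 0.5),
      upper = c(L = 3 * hmax, x0 = 200, b = 30),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  res <- stats::resid(fit)
  tss <- sum((heights - mean(heights))^2)
  out$L <- unname(cf["L"]); out$x0 <- unname(cf["x0"]); out$b <- unname(cf["b"])
  out$rmse <- sqrt(mean(res^2))
  out$r2 <- 1 - sum(res^2) / tss
  out$converged <- TRUE
  out
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Weibull fit: L = %.3f m, x0 = %.1f DAS, b = %.2f (R2 = %.4f, RMSE = %.1f cm, n = %d)\n",
      x$L, x$x0, x$b, x$r2, 100 * x$rmse, x$n))
  } else {
    cat("Weibull fit: not converged (degenerate or failed fit)\n")
  }
  invisible(x)
}

# the four candidate sigmoid families, parameterized with an asymptote L
.sigmoid_families <- function() {
  list(
    Weibull = list(
      formula = y ~ L * (1 - exp(-(x / x0)^b)),
      start = function(x, y) list(L = max(y), x0 = stats::median(x), b = 5),
      lower = c(L = 1e-6, x0 = 1e-6, b = 0.5),
      upper = function(y) c(L = 3 * max(y), x0 = 200, b = 30)),
    Logistic = list(
      formula = y ~ L / (1 + exp(-k * (x - x0))),
      start = function(x, y) list(L = max(y), x0 = stats::median(x), k = 0.1),
      lower = c(L = 1e-6, x0 = 1e-6, k = 1e-4),
      upper = function(y) c(L = 3 * max(y), x0 = 200, k = 5)),
    Gompertz = list(
      formula = y ~ L * exp(-exp(-k * (x - x0))),
      start = function(x, y) list(L = max(y), x0 = stats::median(x), k = 0.1),
      lower = c(L = 1e-6, x0 = 1e-6, k = 1e-4),
      upper = function(y) c(L = 3 * max(y), x0 = 200, k = 5)),
    Probit = list(
      formula = y ~ L * pnorm(k * (x - x0)),
      start = function(x, y) list(L = max(y), x0 = stats::median(x), k = 0.1),
      lower = c(L = 1e-6, x0 = 1e-6, k = 1e-4),
      upper = function(y) c(L = 3 * max(y), x0 = 200, k = 5))
  )
}

#' Compare sigmoid growth families on one trajectory
#'
#' Fits Weibull, Logistic, Gompertz and Probit-type sigmoids by bounded
#' least squares and ranks them by small-sample-corrected AIC (AICc,
#' Gaussian likelihood). Exact criterion ties are broken by the fixed
#' family order above and flagged.
#'
#' @param times,heights the trajectory (as in [fit_weibull()]).
#' @return List: `best` (family name), `table` (family, k, rss, aicc,
#'   converged), `tie` (logical).
#' @export
select_growth_model <- function(times, heights) {
  fams <- .sigmoid_families()
  n <- length(times)
  rows <- lapply(names(fams), function(fn) {
    f <- fams[[fn]]
    fit <- tryCatch(
      minpack.lm::nlsLM(f$formula, data = list(x = times, y = heights),
                        start = f$start(times, heights),
                        lower = f$lower, upper = f$upper(heights),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(data.frame(family = fn, k = NA, rss = NA, aicc = Inf,
                        converged = FALSE))
    }
    rss <- sum(stats::resid(fit)^2)
    k <- length(stats::coef(fit)) + 1          # + residual variance
    aicc <- n * log(max(rss, 1e-300) / n) + 2 * k +
      if (n - k - 1 > 0) 2 * k * (k + 1) / (n - k - 1) else Inf
    data.frame(family = fn, k = k, rss = rss, aicc = aicc, converged = TRUE)
  })
  tab <- do.call(rbind, rows)
  if (all(!tab$converged)) stop("no candidate growth model converged")
  best_i <- which(tab$aicc == min(tab$aicc))   # first index wins on ties
  list(best = tab$family[best_i[1]], table = tab,
       tie = length(best_i) > 1)
}

#' Chi-square goodness-of-fit filter for growth-curve fits
#'
#' Flags entries whose curve misfits their observations. Under an adequate
#' model with Gaussian noise of variance `sigma^2`, `RSS/sigma^2` has mean
#' `n - p`; the standardized excess `z = (RSS/sigma^2 - (n-p)) /
#' sqrt(2(n-p))` is squared and referred to a chi-square with 1 df at
#' `alpha`. Only excess misfit counts (one-sided): fits better than
#' expected are always kept, as is a statistic exactly at the critical
#' value.
#'
#' @param fit a converged `weibull_fit`.
#' @param sigma noise sd of the heights (m), e.g. the REML residual sd of
#'   the BLUP stage or a pooled estimate across entries.
#' @param alpha significance level (default 0.05).
#' @return `TRUE` to keep the fit, `FALSE` to drop it.
#' @export
goodness_of_fit_filter <- function(fit, sigma, alpha = 0.05) {
  if (!isTRUE(fit$converged)) return(FALSE)
  if (fit$df < 1) stop("residual df < 1")
  stopifnot(sigma > 0, alpha > 0, alpha < 1)
  rss <- fit$rmse^2 * fit$n
  excess <- rss / sigma^2 - fit$df
  if (excess <= 0) return(TRUE)
  stat <- (excess / sqrt(2 * fit$df))^2
  stat <= stats::qchisq(1 - alpha, df = 1)     # keep at the boundary
}

#' Impute daily heights from a fitted growth curve
#'
#' Evaluates the fitted Weibull curve on integer days (default 1-85 DAS),
#' the daily grid used for day-by-day QTL scans.
#'
#' @param fit a converged `weibull_fit`.
#' @param day_range integer range `c(first, last)` of DAS.
#' @return Named numeric vector, one height (m) per day.
#' @export
impute_daily_heights <- function(fit, day_range = c(1, 85)) {
  if (!isTRUE(fit$converged)) stop("cannot impute from a non-converged fit")
  days <- seq(day_range[1], day_range[2])
  stats::setNames(weibull_height(days, fit$L, fit$x0, fit$b),
                  paste0("d", days))
}
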