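#' Simulate a selfed recombinant inbred line (RIL) population
#'
#' Generates line genotypes along each chromosome as a two-state Markov
#' chain over markers. Between adjacent markers the line-level transition
#' probability is the Haldane-Waterman selfed-RIL expectation
#' `R = 2r/(1+2r)`, with the meiotic fraction `r` recovered from the cM
#' spacing by inverting the Kosambi function — so the simulated
#' recombination structure matches the map function used for map
#' construction downstream. Residual heterozygosity (incomplete fixation at
#' F6+) is injected by flipping calls to het (1) at rate `het_rate`.
#'
#' Calls are coded 0 (parent-A homozygote), 2 (parent-B homozygote),
#' 1 (heterozygote), -1 (missing; injected at `missing_rate`).
#'
#' @param map marker map data.frame (`marker`, `chrom`, `bp`, `cm`) or a
#'   [map_spec()] (laid out via [marker_map()]).
#' @param n_lines number of RILs to simulate (>= 1).
#' @param het_rate residual heterozygosity rate in `[0, 0.5)` (default 0.03,
#'   about `(1/2)^5` for an F6 line).
#' @param missing_rate fraction of calls set missing (default 0).
#' @param seed optional integer seed for reproducibility.
#' @return List with `geno` (integer matrix, lines x markers, dimnames set),
#'   `map` (the marker map), and `breakpoints`: a data.frame of true
#'   crossover midpoints (`line`, `chrom`, `left_marker`, `right_marker`,
#'   `pos_cm`) recorded before het/missing injection.
#' @export
simulate_ril_population <- function(map, n_lines, het_rate = 0.03,
                                    missing_rate = 0, seed = NULL) {
  if (inherits(map, "map_spec")) map <- marker_map(map)
  stopifnot(n_lines >= 1, het_rate >= 0, het_rate < 0.5,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  chroms <- unique(map$chrom)
  line_ids <- sprintf("L%03d", seq_len(n_lines))

  geno <- matrix(NA_integer_, n_lines, nrow(map),
                 dimnames = list(line_ids, map$marker))
  bp_list <- vector("list", length(chroms))

  for (ci in seq_along(chroms)) {
    idx <- which(map$chrom == chroms[ci])
    cm <- map$cm[idx]
    if (length(idx) < 2) stop("need >= 2 markers per chromosome")
    if (is.unsorted(cm, strictly = FALSE)) stop("map cM must be non-decreasing")
    d <- diff(cm)
    R <- ril_R(kosambi_r(d))                 # per-interval transition prob
    g <- matrix(0L, n_lines, length(idx))
    g[, 1] <- sample(c(0L, 2L), n_lines, replace = TRUE)
    for (j in seq_along(R)) {
      flip <- stats::runif(n_lines) < R[j]
      g[, j + 1] <- ifelse(flip, 2L - g[, j], g[, j])
    }
    # record true crossovers at interval midpoints
    sw <- which(g[, -1, drop = FALSE] != g[, -ncol(g), drop = FALSE],
                arr.ind = TRUE)
    if (nrow(sw) > 0) {
      bp_list[[ci]] <- data.frame(
        line = line_ids[sw[, 1]],
        chrom = chroms[ci],
        left_marker = map$marker[idx[sw[, 2]]],
        right_marker = map$marker[idx[sw[, 2] + 1]],
        pos_cm = (cm[sw[, 2]] + cm[sw[, 2] + 1]) / 2,
        stringsAsFactors = FALSE
      )
    }
    geno[, idx] <- g
  }

  n_calls <- length(geno)
  if (het_rate > 0) {
    het <- which(stats::runif(n_calls) < het_rate)
    geno[het] <- 1L
  }
  if (missing_rate > 0) {
    mis <- which(stats::runif(n_calls) < missing_rate)
    geno[mis] <- -1L
  }
  breakpoints <- if (all(vapply(bp_list, is.null, logical(1)))) {
    data.frame(line = character(), chrom = character(),
               left_marker = character(), right_marker = character(),
               pos_cm = numeric())
  } else do.call(rbind, bp_list)
  rownames(breakpoints) <- NULL
  list(geno = geno, map = map, breakpoints = breakpoints)
}
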