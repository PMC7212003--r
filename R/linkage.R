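#' Filter lines and markers by missing-data rate
#'
#' Drops lines and then markers whose missing fraction strictly exceeds the
#' threshold (a line at exactly the threshold is retained). Marker rates
#' are computed after the line filter.
#'
#' @param geno integer matrix, lines x markers, calls in
#'   `{-1 missing, 0, 1, 2}`.
#' @param max_line_missing,max_marker_missing thresholds in `[0, 1]`
#'   (default 0.10 each).
#' @return List: `geno` (filtered, original order preserved), `report`
#'   (lines/markers dropped with their ids).
#' @export
filter_missing <- function(geno, max_line_missing = 0.10,
                           max_marker_missing = 0.10) {
  stopifnot(is.matrix(geno),
            max_line_missing >= 0, max_line_missing <= 1,
            max_marker_missing >= 0, max_marker_missing <= 1)
  line_miss <- rowMeans(geno == -1)
  keep_l <- line_miss <= max_line_missing
  g <- geno[keep_l, , drop = FALSE]
  if (nrow(g) == 0) stop("all lines filtered by missing-data rate")
  mark_miss <- colMeans(g == -1)
  keep_m <- mark_miss <= max_marker_missing
  g <- g[, keep_m, drop = FALSE]
  if (ncol(g) == 0) stop("all markers filtered by missing-data rate")
  list(geno = g,
       report = list(
         lines_dropped = rownames(geno)[!keep_l],
         markers_dropped = colnames(geno)[!keep_m],
         n_lines_dropped = sum(!keep_l),
         n_markers_dropped = sum(!keep_m)))
}

#' Set heterozygous calls to missing
#'
#' RIL populations phenotyped at F6 or later carry little true
#' heterozygosity; het calls (1) are set missing (-1) and the analysis
#' proceeds on the two homozygous classes only.
#'
#' @param geno call matrix.
#' @return Matrix with every 1 replaced by -1.
#' @export
set_het_missing <- function(geno) {
  geno[geno == 1] <- -1L
  geno
}

# run-length encode the non-missing homozygous calls of one line/chromosome
.geno_runs <- function(calls) {
  obs <- which(calls %in% c(0L, 2L))
  if (length(obs) == 0) return(NULL)
  r <- rle(calls[obs])
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(value = r$values,
             start = obs[starts], end = obs[ends],  # marker indices
             n = r$lengths)
}

#' Clean double recombinants by run-length absorption
#'
#' Along each chromosome of each line, homozygous genotype runs shorter
#' than a minimum region (in cM, as a fraction of chromosome length, or in
#' marker count) are absorbed into the flanking runs: the short run's
#' calls are flipped to the neighboring genotype, removing spurious
#' double-crossover islands that are far more likely genotyping errors
#' than real. Absorption prefers the longer flanking run (left on ties)
#' and iterates until all runs meet the minimum. Breakpoints between the
#' surviving runs are reported at the cM midpoint of the bounding marker
#' interval.
#'
#' @param geno call matrix (het already set missing; calls in
#'   `{-1, 0, 2}`).
#' @param map marker map (`marker`, `chrom`, `bp`, `cm`) covering every
#'   column of `geno`, in map order.
#' @param min_region_frac minimum run length as a fraction of chromosome
#'   cM length, in `(0, 0.1)` (default 0.001, i.e. 0.1% of the
#'   chromosome).
#' @param min_run_markers minimum run length in markers (default 2: a
#'   single-marker island is always absorbed).
#' @return List: `geno` (corrected calls), `breakpoints` (data.frame
#'   `line`, `chrom`, `left_marker`, `right_marker`, `pos_cm`), `n_corrected`
#'   (calls changed).
#' @export
clean_double_recombinants <- function(geno, map, min_region_frac = 0.001,
                                      min_run_markers = 2) {
  stopifnot(min_region_frac > 0, min_region_frac < 0.1)
  if (!all(colnames(geno) %in% map$marker)) stop("unmapped markers in matrix")
  map <- map[match(colnames(geno), map$marker), ]
  out <- geno
  n_corrected <- 0L
  bp_rows <- list()
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    cm <- map$cm[idx]
    min_cm <- min_region_frac * (max(cm) - min(cm))
    for (li in seq_len(nrow(geno))) {
      calls <- out[li, idx]
      runs <- .geno_runs(calls)
      if (is.null(runs) || nrow(runs) == 1) next
      repeat {
        if (nrow(runs) == 1) break
        span <- cm[runs$end] - cm[runs$start]
        short <- which(runs$n < min_run_markers | span < min_cm)
        if (length(short) == 0) break
        # absorb true islands (equal-valued neighbors) before edge runs:
        # flipping an island is unambiguous, an edge run is not
        isl <- short[short > 1 & short < nrow(runs)]
        isl <- isl[runs$value[isl - 1] == runs$value[isl + 1]]
        cand <- if (length(isl) > 0) isl else short
        k <- cand[which.min(runs$n[cand])]
        # absorb run k into the longer neighbor (left on ties)
        left_n <- if (k > 1) runs$n[k - 1] else -1L
        right_n <- if (k < nrow(runs)) runs$n[k + 1] else -1L
        into <- if (left_n >= right_n) k - 1L else k + 1L
        flip_idx <- runs$start[k]:runs$end[k]
        obs_flip <- flip_idx[calls[flip_idx] %in% c(0L, 2L)]
        calls[obs_flip] <- runs$value[into]
        n_corrected <- n_corrected + length(obs_flip)
        runs <- .geno_runs(calls)
      }
      out[li, idx] <- calls
      if (nrow(runs) > 1) {
        for (b in seq_len(nrow(runs) - 1)) {
          bp_rows[[length(bp_rows) + 1]] <- data.frame(
            line = rownames(geno)[li], chrom = chrom,
            left_marker = map$marker[idx[runs$end[b]]],
            right_marker = map$marker[idx[runs$start[b + 1]]],
            pos_cm = (cm[runs$end[b]] + cm[runs$start[b + 1]]) / 2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  breakpoints <- if (length(bp_rows) == 0) {
    data.frame(line = character(), chrom = character(),
               left_marker = character(), right_marker = character(),
               pos_cm = numeric())
  } else do.call(rbind, bp_rows)
  rownames(breakpoints) <- NULL
  list(geno = out, breakpoints = breakpoints, n_corrected = n_corrected)
}

#' Bin markers with redundant segregation patterns
#'
#' Markers whose non-missing calls agree on every shared line (zero
#' mismatches, pairwise-complete comparison) within a chromosome are
#' grouped into a bin; the representative is the member with the fewest
#' missing calls, ties broken by smallest physical position.
#'
#' @param geno cleaned call matrix.
#' @param map marker map covering the columns.
#' @return List: `keep` (representative marker ids, in map order), `bins`
#'   (data.frame `marker`, `bin`, `representative`), `geno` (matrix reduced
#'   to representatives).
#' @export
bin_redundant_markers <- function(geno, map) {
  map <- map[match(colnames(geno), map$marker), ]
  bin_id <- integer(ncol(geno))
  rep_of <- character(0)
  next_bin <- 0L
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    reps <- integer(0)                       # column indices of current reps
    for (j in idx) {
      placed <- FALSE
      for (r in reps) {
        shared <- geno[, j] != -1L & geno[, r] != -1L
        if (any(shared) && all(geno[shared, j] == geno[shared, r])) {
          bin_id[j] <- bin_id[r]
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        next_bin <- next_bin + 1L
        bin_id[j] <- next_bin
        reps <- c(reps, j)
      }
    }
  }
  miss <- colSums(geno == -1L)
  keep <- vapply(seq_len(next_bin), function(b) {
    members <- which(bin_id == b)
    members <- members[order(miss[members], map$bp[members])]
    members[1]
  }, integer(1))
  keep <- sort(keep)
  bins <- data.frame(marker = colnames(geno), bin = bin_id,
                     representative = colnames(geno)[
                       vapply(bin_id, function(b) keep[
                         which(bin_id[keep] == b)], integer(1))],
                     stringsAsFactors = FALSE)
  list(keep = colnames(geno)[keep], bins = bins,
       geno = geno[, keep, drop = FALSE])
}

#' Estimate the recombination fraction between two markers
#'
#' `R` is the recombinant fraction among lines with homozygous calls at
#' both markers (het/missing excluded), capped just below 0.5; the meiotic
#' fraction is recovered by inverting the selfed-RIL expectation,
#' `r = R / (2 - 2R)`.
#'
#' @param geno call matrix.
#' @param m1,m2 marker ids (columns of `geno`).
#' @param min_informative minimum informative lines (default 20).
#' @return List: `R` (observed line-level fraction), `r` (meiotic),
#'   `n_informative`, `capped` (TRUE when R hit the 0.4999 cap).
#' @export
estimate_recombination <- function(geno, m1, m2, min_informative = 20) {
  g1 <- geno[, m1]; g2 <- geno[, m2]
  inf <- g1 %in% c(0L, 2L) & g2 %in% c(0L, 2L)
  n <- sum(inf)
  if (n < min_informative) {
    stop("too few informative lines (", n, " < ", min_informative, ")")
  }
  R_raw <- mean(g1[inf] != g2[inf])
  capped <- R_raw >= 0.4999
  R <- min(R_raw, 0.4999)
  list(R = R, r = ril_r(R), n_informative = n, capped = capped)
}

#' Build a Kosambi genetic map from cleaned, binned genotypes
#'
#' Marker order is fixed by physical position (no de novo ordering);
#' adjacent-pair recombination fractions are estimated on the selfed-RIL
#' scale and converted to cM with the Kosambi function; positions are the
#' cumulative distances from the chromosome start.
#'
#' @param geno cleaned, binned call matrix.
#' @param phys_map marker map with `marker`, `chrom`, `bp` (the `cm`
#'   column, if present, is ignored and re-estimated).
#' @param min_informative passed to [estimate_recombination()].
#' @return List: `map` (data.frame `marker`, `chrom`, `bp`, `cm`,
#'   `capped`), `lengths` (named cM length per chromosome),
#'   `total_length_cm`.
#' @export
build_map <- function(geno, phys_map, min_informative = 20) {
  phys_map <- phys_map[match(colnames(geno), phys_map$marker), ]
  rows <- list()
  lengths <- c()
  for (chrom in unique(phys_map$chrom)) {
    idx <- which(phys_map$chrom == chrom)
    if (length(idx) < 2) stop("chromosome ", chrom, " has < 2 markers")
    idx <- idx[order(phys_map$bp[idx])]
    cm <- numeric(length(idx))
    capped <- logical(length(idx))
    for (j in seq_len(length(idx) - 1)) {
      est <- estimate_recombination(geno, phys_map$marker[idx[j]],
                                    phys_map$marker[idx[j + 1]],
                                    min_informative)
      cm[j + 1] <- cm[j] + kosambi_cm(est$r)
      capped[j + 1] <- est$capped
    }
    rows[[chrom]] <- data.frame(marker = phys_map$marker[idx],
                                chrom = chrom, bp = phys_map$bp[idx],
                                cm = cm, capped = capped,
                                stringsAsFactors = FALSE)
    lengths[chrom] <- max(cm)
  }
  map <- do.call(rbind, rows)
  rownames(map) <- NULL
  list(map = map, lengths = lengths, total_length_cm = sum(lengths))
}
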