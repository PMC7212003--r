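#' Define a linkage-map specification for simulation
#'
#' A map specification lists chromosomes with their genetic lengths and
#' marker counts, plus the rule converting genetic to physical position.
#' Markers are placed evenly in cM by default; physical positions follow a
#' constant bp-per-cM scale (maize averages roughly 1.5 Mbp/cM genome-wide).
#'
#' @param chromosomes data.frame with columns `chrom` (character),
#'   `length_cm` (> 0) and `n_markers` (>= 2).
#' @param bp_per_cm physical scale, base pairs per cM (default 1.5e6).
#' @return An object of class `map_spec`: the input table plus the scale.
#' @export
map_spec <- function(chromosomes, bp_per_cm = 1.5e6) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_cm", "n_markers") %in% names(chromosomes)))
  if (any(chromosomes$length_cm <= 0)) stop("chromosome lengths must be > 0")
  if (any(chromosomes$n_markers < 2)) stop("need >= 2 markers per chromosome")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  structure(list(chromosomes = chromosomes, bp_per_cm = bp_per_cm),
            class = "map_spec")
}

#' Lay out marker positions from a map specification
#'
#' Markers are spaced evenly from 0 cM to the chromosome length; physical bp
#' is the cM position times the bp-per-cM scale (1-based, rounded up).
#'
#' @param spec a [map_spec()].
#' @return data.frame with columns `marker`, `chrom`, `bp`, `cm` — the marker
#'   map schema used throughout the package.
#' @export
marker_map <- function(spec) {
  stopifnot(inherits(spec, "map_spec"))
  chr <- spec$chromosomes
  out <- do.call(rbind, lapply(seq_len(nrow(chr)), function(i) {
    cm <- seq(0, chr$length_cm[i], length.out = chr$n_markers[i])
    data.frame(
      marker = sprintf("m%s_%03d", chr$chrom[i], seq_along(cm)),
      chrom  = chr$chrom[i],
      bp     = pmax(1, ceiling(cm * spec$bp_per_cm)),
      cm     = cm,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Map specifications emulating the three study RIL populations
#'
#' Three biparental maize RIL populations with 102, 237 and 178 lines and
#' 10 chromosomes; total map lengths around 1,315, 1,207 and 1,474 cM.
#' Chromosome lengths taper from longest (chromosome 1) to shortest
#' (chromosome 10) and are scaled to the population's total length.
#' Marker counts follow a target spacing; the 0.7 cM default reproduces
#' the density of a binned SNP-chip map (one to two thousand informative
#' markers per population).
#'
#' @param marker_spacing_cm target adjacent-marker spacing in cM
#'   (default 0.7).
#' @return Named list of three elements (`Tx740xNC356`, `Ki3xNC356`,
#'   `LH82xLAMA`), each with `n_lines` and a `map_spec`.
#' @export
default_populations <- function(marker_spacing_cm = 0.7) {
  totals <- c(Tx740xNC356 = 1315, Ki3xNC356 = 1207, LH82xLAMA = 1474)
  lines  <- c(Tx740xNC356 = 102,  Ki3xNC356 = 237,  LH82xLAMA = 178)
  # relative chromosome sizes taper roughly like the maize genome
  rel <- seq(1.45, 0.65, length.out = 10)
  rel <- rel / sum(rel)
  lapply(names(totals), function(p) {
    len <- round(rel * totals[[p]], 1)
    chroms <- data.frame(
      chrom = as.character(1:10),
      length_cm = len,
      n_markers = pmax(2, round(len / marker_spacing_cm) + 1)
    )
    list(name = p, n_lines = lines[[p]],
         spec = map_spec(chroms))
  }) |> stats::setNames(names(totals))
}
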