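#' Day-by-day QTL scans over imputed daily heights
#'
#' Runs the ICIM-ADD (or plain interval-mapping) scan once per day column
#' of the imputed daily-height matrix, producing one LOD profile per day.
#'
#' @param daily matrix of imputed heights, entries x days (column names
#'   `d1`, `d2`, ... as from [impute_daily_heights()]).
#' @param geno marker call matrix (needed for the ICIM background step).
#' @param gp a [genotype_probabilities()] object.
#' @param method `"icim"` (default) or `"im"` (no background adjustment;
#'   all days share one vectorized regression pass).
#' @param pin,pout ICIM stepwise thresholds.
#' @return List of class `daily_scans`: `profiles` (list of `lod_profile`,
#'   one per day, named by day), `days` (integer DAS vector), `positions`.
#' @export
scan_all_days <- function(daily, geno, gp, method = c("icim", "im"),
                          pin = 0.001, pout = 2 * pin) {
  method <- match.arg(method)
  stopifnot(inherits(gp, "genoprobs"))
  days <- as.integer(sub("^d", "", colnames(daily)))
  if (anyNA(days)) stop("daily matrix columns must be named d<DAS>")
  lines <- intersect(rownames(daily), rownames(gp$score))
  if (length(lines) < 20) stop("need >= 20 informative lines")
  Y <- daily[lines, , drop = FALSE]

  profiles <- vector("list", length(days))
  names(profiles) <- colnames(daily)
  if (method == "im") {
    S <- gp$score[lines, , drop = FALSE]
    sdy <- apply(Y, 2, stats::sd)
    sc <- .hk_scan(Y, S)
    for (t in seq_along(days)) {
      flat <- sdy[t] < 1e-12
      pr <- data.frame(gp$positions,
                       lod = if (flat) 0 else sc$lod[t, ],
                       additive = if (flat) 0 else sc$additive[t, ],
                       pve = if (flat) 0 else sc$pve[t, ],
                       n = length(lines))
      class(pr) <- c("lod_profile", "data.frame")
      attr(pr, "flat") <- flat
      profiles[[t]] <- pr
    }
  } else {
    for (t in seq_along(days)) {
      y <- stats::setNames(Y[, t], lines)
      profiles[[t]] <- icim_scan(y, geno, gp, pin = pin, pout = pout)
    }
  }
  structure(list(profiles = profiles, days = days,
                 positions = gp$positions),
            class = "daily_scans")
}

#' Cluster per-day QTL calls into temporal QTL
#'
#' Calls QTL on every daily profile, then single-linkage-clusters the
#' daily peaks chromosome by chromosome: two daily calls join one temporal
#' QTL when their peaks lie within `window_cm`. Onset/offset are the first
#' and last significant day of the cluster, with gaps of up to
#' `bridge_days` non-significant days bridged (longer gaps split the
#' cluster in time). The consensus peak is the LOD-weighted mean of the
#' member peaks; full-season LOD / additive-effect / PVE trajectories are
#' extracted at the scan position nearest the consensus peak.
#'
#' @param scans a `daily_scans` object.
#' @param window_cm clustering window (default 10 cM).
#' @param lod_min,pve_min daily calling thresholds (defaults 2.0, 0.03).
#' @param bridge_days maximum gap of non-significant days kept inside one
#'   cluster (default 2).
#' @return List of class `temporal_qtl_set`: `qtl` (data.frame: `name`,
#'   `chrom`, `peak_cm`, `onset`, `offset`, `peak_das`, `max_lod`,
#'   `max_pve`, `effect_at_peak`, `sign_switch`, `n_days`),
#'   `trajectories` (long data.frame: `name`, `das`, `lod`, `additive`,
#'   `pve`), `daily_calls`.
#' @export
cluster_temporal <- function(scans, window_cm = 10, lod_min = 2.0,
                             pve_min = 0.03, bridge_days = 2) {
  stopifnot(inherits(scans, "daily_scans"))
  daily_calls <- do.call(rbind, lapply(seq_along(scans$days), function(t) {
    cl <- call_qtl(scans$profiles[[t]], lod_min = lod_min,
                   pve_min = pve_min)
    if (nrow(cl) == 0) return(NULL)
    cbind(das = scans$days[t], cl)
  }))
  empty <- list(
    qtl = data.frame(name = character(), chrom = character(),
                     peak_cm = numeric(), onset = integer(),
                     offset = integer(), peak_das = integer(),
                     max_lod = numeric(), max_pve = numeric(),
                     effect_at_peak = numeric(), sign_switch = logical(),
                     n_days = integer()),
    trajectories = data.frame(name = character(), das = integer(),
                              lod = numeric(), additive = numeric(),
                              pve = numeric()),
    daily_calls = daily_calls)
  class(empty) <- "temporal_qtl_set"
  if (is.null(daily_calls) || nrow(daily_calls) == 0) return(empty)

  qtl_rows <- list(); traj_rows <- list()
  for (chrom in unique(daily_calls$chrom)) {
    dc <- daily_calls[daily_calls$chrom == chrom, ]
    dc <- dc[order(dc$peak_cm), ]
    # single-linkage in cM: break where the sorted-peak gap exceeds window
    grp <- cumsum(c(1, diff(dc$peak_cm) > window_cm))
    for (g in unique(grp)) {
      mem <- dc[grp == g, ]
      mem <- mem[order(mem$das), ]
      # split in time where the day gap exceeds the bridge
      tgrp <- cumsum(c(1, diff(mem$das) > bridge_days + 1))
      for (tg in unique(tgrp)) {
        m <- mem[tgrp == tg, ]
        peak_cm <- sum(m$peak_cm * m$lod) / sum(m$lod)
        pidx <- which(scans$positions$chrom == chrom)
        pnear <- pidx[which.min(abs(scans$positions$cm[pidx] - peak_cm))]
        traj <- data.frame(
          das = scans$days,
          lod = vapply(scans$profiles, function(p) p$lod[pnear],
                       numeric(1)),
          additive = vapply(scans$profiles, function(p) p$additive[pnear],
                            numeric(1)),
          pve = vapply(scans$profiles, function(p) p$pve[pnear],
                       numeric(1)))
        rownames(traj) <- NULL
        name <- sprintf("q%s_%d", chrom, round(peak_cm))
        sw <- .sign_switch_days(traj, lod_min)
        qtl_rows[[length(qtl_rows) + 1]] <- data.frame(
          name = name, chrom = chrom, peak_cm = peak_cm,
          onset = min(m$das), offset = max(m$das),
          peak_das = m$das[which.max(m$lod)],
          max_lod = max(m$lod), max_pve = max(m$pve),
          effect_at_peak = m$additive[which.max(m$lod)],
          sign_switch = length(sw) > 0, n_days = nrow(m),
          stringsAsFactors = FALSE)
        traj_rows[[length(traj_rows) + 1]] <- cbind(name = name, traj)
      }
    }
  }
  qtl <- do.call(rbind, qtl_rows)
  # disambiguate clusters that round to the same name
  dup <- duplicated(qtl$name) | duplicated(qtl$name, fromLast = TRUE)
  if (any(dup)) {
    for (nm in unique(qtl$name[dup])) {
      w <- which(qtl$name == nm)
      suffix <- paste0(".", seq_along(w))
      qtl$name[w] <- paste0(nm, suffix)
      for (k in seq_along(w)) {
        traj_rows[[w[k]]]$name <- qtl$name[w[k]]
      }
    }
  }
  rownames(qtl) <- NULL
  out <- list(qtl = qtl,
              trajectories = do.call(rbind, c(traj_rows,
                                              make.row.names = FALSE)),
              daily_calls = daily_calls)
  class(out) <- "temporal_qtl_set"
  out
}

# first days at which the additive effect crosses zero between two
# significant days
.sign_switch_days <- function(traj, lod_min) {
  sig <- traj$lod > lod_min
  s <- sign(traj$additive)
  switches <- c()
  sig_idx <- which(sig & s != 0)
  if (length(sig_idx) < 2) return(switches)
  for (k in seq_len(length(sig_idx) - 1)) {
    i <- sig_idx[k]; j <- sig_idx[k + 1]
    if (s[i] != s[j]) switches <- c(switches, traj$das[j])
  }
  switches
}

#' Detect additive-effect sign switches in a temporal QTL
#'
#' A temporal QTL "switches direction" when its additive effect changes
#' sign between two days on both of which the locus is significant
#' (LOD above threshold); sign changes while the locus is below threshold
#' do not count.
#'
#' @param trajectory data.frame with `das`, `lod`, `additive` (one QTL's
#'   trajectory, e.g. a subset of `cluster_temporal()$trajectories`).
#' @param lod_min significance threshold (default 2.0).
#' @return List: `switched` (logical), `switch_das` (DAS of the first
#'   significant day after each crossing; empty when none).
#' @export
detect_sign_switch <- function(trajectory, lod_min = 2.0) {
  sw <- .sign_switch_days(trajectory, lod_min)
  list(switched = length(sw) > 0, switch_das = sw)
}

#' Co-localize QTL across traits
#'
#' Pairs QTL from different trait lists when they sit on the same
#' chromosome within `window_cm` of each other.
#'
#' @param qtl_by_trait named list of QTL call data.frames (each with
#'   `name`, `chrom`, `peak_cm`).
#' @param window_cm pairing window (default 10 cM).
#' @return data.frame: `trait1`, `qtl1`, `trait2`, `qtl2`, `chrom`,
#'   `distance_cm`.
#' @export
colocalize <- function(qtl_by_trait, window_cm = 10) {
  traits <- names(qtl_by_trait)
  stopifnot(!is.null(traits), length(traits) >= 2)
  rows <- list()
  for (a in seq_len(length(traits) - 1)) {
    for (b in (a + 1):length(traits)) {
      qa <- qtl_by_trait[[a]]; qb <- qtl_by_trait[[b]]
      if (nrow(qa) == 0 || nrow(qb) == 0) next
      for (i in seq_len(nrow(qa))) {
        for (j in seq_len(nrow(qb))) {
          if (qa$chrom[i] != qb$chrom[j]) next
          d <- abs(qa$peak_cm[i] - qb$peak_cm[j])
          if (d <= window_cm) {
            rows[[length(rows) + 1]] <- data.frame(
              trait1 = traits[a], qtl1 = qa$name[i],
              trait2 = traits[b], qtl2 = qb$name[j],
              chrom = qa$chrom[i], distance_cm = d,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(trait1 = character(), qtl1 = character(),
                      trait2 = character(), qtl2 = character(),
                      chrom = character(), distance_cm = numeric()))
  }
  do.call(rbind, rows)
}

#' Distance from QTL interval centers to the nearest candidate gene
#'
#' For each QTL, takes the physical center of its confidence interval and
#' finds the nearest gene on the same chromosome: distance 0 when the
#' center falls inside the gene span, otherwise the bp gap to the nearer
#' span edge. Also reports how many QTL fall within 1 Mbp and 5 Mbp of a
#' gene.
#'
#' @param qtl data.frame with `name`, `chrom`, `bp_lo`, `bp_hi`.
#' @param genes data.frame with `name`, `chrom`, `start`, `end`
#'   (bp; BED-like 0-based half-open intervals are accepted as-is).
#' @return List: `distances` (data.frame `qtl`, `chrom`, `center_bp`,
#'   `gene`, `distance_bp`; gene/distance `NA` when the chromosome has no
#'   gene), `n_within_1mb`, `n_within_5mb`.
#' @export
candidate_gene_distance <- function(qtl, genes) {
  stopifnot(all(c("name", "chrom", "bp_lo", "bp_hi") %in% names(qtl)),
            all(c("name", "chrom", "start", "end") %in% names(genes)))
  rows <- lapply(seq_len(nrow(qtl)), function(i) {
    center <- (qtl$bp_lo[i] + qtl$bp_hi[i]) / 2
    g <- genes[genes$chrom == qtl$chrom[i], ]
    if (nrow(g) == 0) {
      return(data.frame(qtl = qtl$name[i], chrom = qtl$chrom[i],
                        center_bp = center, gene = NA_character_,
                        distance_bp = NA_real_))
    }
    d <- ifelse(center >= g$start & center <= g$end, 0,
                pmin(abs(center - g$start), abs(center - g$end)))
    k <- which.min(d)
    data.frame(qtl = qtl$name[i], chrom = qtl$chrom[i], center_bp = center,
               gene = g$name[k], distance_bp = d[k],
               stringsAsFactors = FALSE)
  })
  distances <- do.call(rbind, rows)
  list(distances = distances,
       n_within_1mb = sum(distances$distance_bp < 1e6, na.rm = TRUE),
       n_within_5mb = sum(distances$distance_bp < 5e6, na.rm = TRUE))
}
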