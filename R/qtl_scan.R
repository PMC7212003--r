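#' Conditional QTL-genotype probabilities on a 1 cM scan grid
#'
#' For each line and each grid position (every `step_cm` along the
#' chromosome, plus every marker position), computes the probability of the
#' two homozygous RIL classes conditional on the nearest non-missing
#' flanking marker calls. The genotype process along a selfed-RIL
#' chromosome is treated as a two-state Markov chain with line-level
#' transition probability `R = 2r/(1+2r)` over an interval whose meiotic
#' `r` comes from inverting the Kosambi cM distance — matching the
#' simulator and map construction. At an observed marker the probability
#' is 1 on the observed class; with no informative flank the prior is
#' (0.5, 0.5).
#'
#' @param geno cleaned RIL call matrix (calls in `{-1, 0, 2}`; het set
#'   missing beforehand).
#' @param map marker map (`marker`, `chrom`, `bp`, `cm`) covering the
#'   columns of `geno`.
#' @param step_cm scan step (default 1 cM).
#' @return Object of class `genoprobs`: `positions` (data.frame `chrom`,
#'   `cm`), `pB` (matrix lines x positions, probability of the parent-B
#'   homozygote), `score` (`2*pB - 1`, the expected additive score in
#'   `[-1, 1]`), `map`.
#' @export
genotype_probabilities <- function(geno, map, step_cm = 1.0) {
  map <- map[match(colnames(geno), map$marker), ]
  n <- nrow(geno)
  pos_list <- list(); pB_list <- list()
  for (chrom in unique(map$chrom)) {
    idx <- which(map$chrom == chrom)
    cm <- map$cm[idx]
    grid <- sort(unique(c(seq(min(cm), max(cm), by = step_cm), cm)))
    G <- matrix(0.5, n, length(grid))
    calls <- geno[, idx, drop = FALSE]
    for (li in seq_len(n)) {
      obs <- which(calls[li, ] %in% c(0L, 2L))
      if (length(obs) == 0) next
      ocm <- cm[obs]
      sB <- as.numeric(calls[li, obs] == 2L)   # 1 if parent-B hom observed
      left <- findInterval(grid, ocm)          # index of obs marker at/left
      right <- length(obs) - findInterval(-grid, rev(-ocm)) + 1L
      pB <- numeric(length(grid))
      has_l <- left >= 1; has_r <- right <= length(obs)
      both <- has_l & has_r
      if (any(both)) {
        RL <- ril_R(kosambi_r(grid[both] - ocm[left[both]]))
        RR <- ril_R(kosambi_r(ocm[right[both]] - grid[both]))
        sL <- sB[left[both]]; sR <- sB[right[both]]
        wB <- ifelse(sL == 1, 1 - RL, RL) * ifelse(sR == 1, 1 - RR, RR)
        wA <- ifelse(sL == 0, 1 - RL, RL) * ifelse(sR == 0, 1 - RR, RR)
        pB[both] <- wB / (wA + wB)
      }
      onlyl <- has_l & !has_r
      if (any(onlyl)) {
        RL <- ril_R(kosambi_r(grid[onlyl] - ocm[left[onlyl]]))
        pB[onlyl] <- ifelse(sB[left[onlyl]] == 1, 1 - RL, RL)
      }
      onlyr <- !has_l & has_r
      if (any(onlyr)) {
        RR <- ril_R(kosambi_r(ocm[right[onlyr]] - grid[onlyr]))
        pB[onlyr] <- ifelse(sB[right[onlyr]] == 1, 1 - RR, RR)
      }
      pB[!has_l & !has_r] <- 0.5
      G[li, ] <- pB
    }
    pos_list[[chrom]] <- data.frame(chrom = chrom, cm = grid)
    pB_list[[chrom]] <- G
  }
  positions <- do.call(rbind, pos_list)
  rownames(positions) <- NULL
  pB <- do.call(cbind, pB_list)
  rownames(pB) <- rownames(geno)
  structure(list(positions = positions, pB = pB, score = 2 * pB - 1,
                 map = map),
            class = "genoprobs")
}

# core Haley-Knott regression of one or more phenotype vectors on the
# expected-score matrix; Y: n x t, S: n x p. Returns t x p matrices.
.hk_scan <- function(Y, S) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  Sc <- sweep(S, 2, colMeans(S))
  sxx <- colSums(Sc^2)
  sxy <- crossprod(Yc, Sc)                  # t x p
  ok <- sxx > 1e-12
  slope <- sxy
  slope[, ok] <- sweep(sxy[, ok, drop = FALSE], 2, sxx[ok], "/")
  slope[, !ok] <- 0
  rss0 <- colSums(Yc^2)                     # length t
  rss1 <- pmax(rss0 - slope * sxy, 1e-300)
  lod <- (n / 2) * log10(rss0 / rss1)
  lod[rss0 <= 1e-300, ] <- 0
  pve <- 1 - rss1 / rss0
  pve[rss0 <= 1e-300, ] <- 0
  list(lod = lod, additive = slope, pve = pve, n = n)
}

#' Single-trait interval-mapping scan
#'
#' Regresses the phenotype on the expected additive genotype score
#' (`P(BB) - P(AA)`) at every scan position (Haley-Knott regression; for
#' the two homozygous RIL classes this is near-identical to the
#' normal-mixture scan, and exactly the single-marker regression at fully
#' informative markers). `LOD = (n/2) log10(RSS0/RSS1)`; the additive
#' effect is the slope (half the difference between homozygous class
#' means; positive when the parent-B allele increases the trait); PVE is
#' `1 - RSS1/RSS0`.
#'
#' @param pheno named numeric vector (names = line ids).
#' @param gp a [genotype_probabilities()] object.
#' @return data.frame of class `lod_profile`: `chrom`, `cm`, `lod`,
#'   `additive`, `pve`, `n`; attribute `flat = TRUE` when the phenotype has
#'   zero variance.
#' @export
interval_mapping_scan <- function(pheno, gp) {
  stopifnot(inherits(gp, "genoprobs"))
  lines <- intersect(names(pheno), rownames(gp$score))
  if (length(lines) < 20) stop("need >= 20 informative lines")
  y <- pheno[lines]
  S <- gp$score[lines, , drop = FALSE]
  flat <- stats::sd(y) < 1e-12
  if (flat) {
    out <- data.frame(gp$positions, lod = 0, additive = 0, pve = 0,
                      n = length(y))
  } else {
    sc <- .hk_scan(matrix(y, ncol = 1), S)
    out <- data.frame(gp$positions, lod = sc$lod[1, ],
                      additive = sc$additive[1, ], pve = sc$pve[1, ],
                      n = length(y))
  }
  class(out) <- c("lod_profile", "data.frame")
  attr(out, "flat") <- flat
  out
}

# forward-backward stepwise marker selection at entry threshold pin and
# removal threshold pout. X: n x m mean-imputed marker score matrix.
.stepwise_select <- function(y, X, pin, pout, max_sel) {
  n <- length(y)
  sel <- integer(0)
  repeat {
    changed <- FALSE
    # forward: best candidate partial p-value given current model
    Z <- cbind(1, X[, sel, drop = FALSE])
    qr_z <- qr(Z)
    ry <- qr.resid(qr_z, y)
    cand <- setdiff(seq_len(ncol(X)), sel)
    if (length(cand) > 0 && sum(ry^2) > 1e-12) {
      RX <- qr.resid(qr_z, X[, cand, drop = FALSE])
      sxx <- colSums(RX^2)
      ok <- sxx > 1e-10
      df2 <- n - length(sel) - 2
      if (df2 > 0 && any(ok)) {
        bhat <- colSums(RX * ry) / pmax(sxx, 1e-300)
        rss1 <- sum(ry^2) - bhat^2 * sxx
        Fst <- (sum(ry^2) - rss1) / pmax(rss1 / df2, 1e-300)
        p <- stats::pf(Fst, 1, df2, lower.tail = FALSE)
        p[!ok] <- 1
        j <- which.min(p)
        if (p[j] <= pin) {
          sel <- c(sel, cand[j])
          changed <- TRUE
        }
      }
    }
    # backward: drop selected markers whose partial p exceeds pout
    if (length(sel) > 1) {
      repeat {
        Z <- cbind(1, X[, sel, drop = FALSE])
        fit <- stats::lm.fit(Z, y)
        rss <- sum(fit$residuals^2)
        df2 <- n - length(sel) - 1
        pvals <- vapply(seq_along(sel), function(k) {
          Zk <- Z[, -(k + 1), drop = FALSE]
          rssk <- sum(stats::lm.fit(Zk, y)$residuals^2)
          Fst <- (rssk - rss) / pmax(rss / df2, 1e-300)
          stats::pf(Fst, 1, df2, lower.tail = FALSE)
        }, numeric(1))
        worst <- which.max(pvals)
        if (pvals[worst] > pout) {
          sel <- sel[-worst]
          changed <- TRUE
        } else break
        if (length(sel) <= 1) break
      }
    }
    if (length(sel) >= max_sel) {
      stop("stepwise selection chose >= n/2 markers; ",
           "phenotype/marker matrix likely degenerate")
    }
    if (!changed) break
  }
  sel
}

#' ICIM-ADD genome scan
#'
#' Inclusive composite interval mapping for additive QTL: (1) stepwise
#' regression of the phenotype on all markers (mean-imputed scores; entry
#' threshold `pin`, removal threshold `pout`) picks a background set; (2)
#' for every scan position, the phenotype is adjusted by the fitted
#' contributions of the selected markers *excluding the flanking markers*
#' of the interval being scanned, and the adjusted phenotype is regressed
#' on the expected genotype score as in [interval_mapping_scan()]. When no
#' marker passes `pin`, the scan reduces exactly to plain interval mapping.
#'
#' @param pheno named numeric vector.
#' @param geno marker call matrix (for the background regression).
#' @param gp a [genotype_probabilities()] object (scan grid + map).
#' @param pin stepwise entry probability (default 0.001).
#' @param pout stepwise removal probability (default `2 * pin`).
#' @return `lod_profile` data.frame as in [interval_mapping_scan()];
#'   attribute `selected` holds the background marker ids.
#' @export
icim_scan <- function(pheno, geno, gp, pin = 0.001, pout = 2 * pin) {
  stopifnot(inherits(gp, "genoprobs"))
  lines <- intersect(names(pheno), rownames(gp$score))
  if (length(lines) < 20) stop("need >= 20 informative lines")
  y <- pheno[lines]
  if (stats::sd(y) < 1e-12) {
    out <- interval_mapping_scan(pheno, gp)
    attr(out, "selected") <- character(0)
    return(out)
  }
  X <- .marker_scores(geno[lines, , drop = FALSE])
  sel <- .stepwise_select(y, X, pin, pout, max_sel = length(y) / 2)
  map <- gp$map
  if (length(sel) == 0) {
    out <- interval_mapping_scan(pheno, gp)
    attr(out, "selected") <- character(0)
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, X[, sel, drop = FALSE]), y)
  bsel <- fit$coefficients[-1]
  contrib <- sweep(X[, sel, drop = FALSE], 2, bsel, "*")  # n x |sel|
  y_adj_full <- y - rowSums(contrib)

  S <- gp$score[lines, , drop = FALSE]
  pos <- gp$positions
  lod <- additive <- pve <- numeric(nrow(pos))
  sel_names <- colnames(geno)[sel]
  for (chrom in unique(pos$chrom)) {
    pidx <- which(pos$chrom == chrom)
    midx <- which(map$chrom == chrom)
    mcm <- map$cm[midx]
    left <- findInterval(pos$cm[pidx], mcm, rightmost.closed = FALSE)
    left <- pmin(pmax(left, 1), length(midx) - 1)
    # group positions by their flanking-marker interval
    for (iv in unique(left)) {
      ppos <- pidx[left == iv]
      flank <- colnames(geno)[midx[c(iv, iv + 1)]]
      addback <- which(sel_names %in% flank)
      y_adj <- y_adj_full
      if (length(addback) > 0) {
        y_adj <- y_adj + rowSums(contrib[, addback, drop = FALSE])
      }
      sc <- .hk_scan(matrix(y_adj, ncol = 1), S[, ppos, drop = FALSE])
      lod[ppos] <- sc$lod[1, ]
      additive[ppos] <- sc$additive[1, ]
      pve[ppos] <- sc$pve[1, ]
    }
  }
  out <- data.frame(pos, lod = lod, additive = additive, pve = pve,
                    n = length(y))
  class(out) <- c("lod_profile", "data.frame")
  attr(out, "flat") <- FALSE
  attr(out, "selected") <- sel_names
  out
}

# calls -> additive scores: 0 -> -1, 2 -> +1, het -> 0, missing -> column
# mean of the observed scores
.marker_scores <- function(geno) {
  X <- matrix(0, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  X[geno == 0L] <- -1
  X[geno == 2L] <- 1
  mis <- geno == -1L
  if (any(mis)) {
    obs_mean <- colSums(X * !mis) / pmax(colSums(!mis), 1)
    X[mis] <- obs_mean[col(X)[mis]]
  }
  X
}

#' Call QTL from a LOD profile
#'
#' Peaks exceeding both the LOD and PVE thresholds become QTL; two peaks
#' on one chromosome are distinct calls when separated by a dip below the
#' LOD threshold, or by at least `sep_cm` with an intervening valley at
#' least 1 LOD below the smaller peak (the prominence requirement keeps
#' small wiggles on the shoulder of a strong peak from being called
#' twice). The support interval is the contiguous region within 1 LOD of
#' the peak; names follow the `q{chrom}_{rounded peak cM}` convention.
#'
#' @param profile a `lod_profile`.
#' @param lod_min LOD calling threshold (default 2.0, exclusive).
#' @param pve_min minimum PVE (default 0.03, inclusive).
#' @param sep_cm minimum separation of same-segment peaks (default 20 cM).
#' @param map optional marker map; adds flanking markers and their
#'   physical bp interval to each call.
#' @return data.frame, one row per QTL: `name`, `chrom`, `peak_cm`, `lod`,
#'   `pve`, `additive`, `ci_lo_cm`, `ci_hi_cm`, and (with `map`)
#'   `flank_left`, `flank_right`, `bp_lo`, `bp_hi`. Zero rows when nothing
#'   exceeds the thresholds.
#' @export
call_qtl <- function(profile, lod_min = 2.0, pve_min = 0.03, sep_cm = 20,
                     map = NULL) {
  calls <- list()
  for (chrom in unique(profile$chrom)) {
    pr <- profile[profile$chrom == chrom, ]
    pr <- pr[order(pr$cm), ]
    above <- pr$lod > lod_min & pr$pve >= pve_min
    if (!any(above)) next
    seg_id <- cumsum(c(1, diff(above)) == 1 & above) * above
    for (sid in setdiff(unique(seg_id), 0)) {
      seg <- which(seg_id == sid)
      # local maxima within the segment, strongest first
      lm_idx <- seg[vapply(seg, function(i) {
        lft <- if (i > 1) pr$lod[i - 1] else -Inf
        rgt <- if (i < nrow(pr)) pr$lod[i + 1] else -Inf
        pr$lod[i] >= lft && pr$lod[i] >= rgt
      }, logical(1))]
      lm_idx <- lm_idx[order(-pr$lod[lm_idx])]
      acc <- c()
      for (i in lm_idx) {
        ok <- TRUE
        for (j in acc) {
          if (abs(pr$cm[i] - pr$cm[j]) < sep_cm) { ok <- FALSE; break }
          valley <- min(pr$lod[min(i, j):max(i, j)])
          if (valley > min(pr$lod[i], pr$lod[j]) - 1) { ok <- FALSE; break }
        }
        if (ok) acc <- c(acc, i)
      }
      for (i in acc) {
        thr <- pr$lod[i] - 1
        lo <- i; while (lo > 1 && pr$lod[lo - 1] >= thr) lo <- lo - 1
        hi <- i; while (hi < nrow(pr) && pr$lod[hi + 1] >= thr) hi <- hi + 1
        row <- data.frame(
          name = sprintf("q%s_%d", chrom, round(pr$cm[i])),
          chrom = chrom, peak_cm = pr$cm[i], lod = pr$lod[i],
          pve = pr$pve[i], additive = pr$additive[i],
          ci_lo_cm = pr$cm[lo], ci_hi_cm = pr$cm[hi],
          stringsAsFactors = FALSE)
        if (!is.null(map)) {
          mc <- map[map$chrom == chrom, ]
          mc <- mc[order(mc$cm), ]
          li <- max(which(mc$cm <= row$ci_lo_cm), 1)
          ri <- min(c(which(mc$cm >= row$ci_hi_cm), nrow(mc)))
          row$flank_left <- mc$marker[li]
          row$flank_right <- mc$marker[ri]
          row$bp_lo <- mc$bp[li]
          row$bp_hi <- mc$bp[ri]
        }
        calls[[length(calls) + 1]] <- row
      }
    }
  }
  if (length(calls) == 0) {
    out <- data.frame(name = character(), chrom = character(),
                      peak_cm = numeric(), lod = numeric(), pve = numeric(),
                      additive = numeric(), ci_lo_cm = numeric(),
                      ci_hi_cm = numeric())
    if (!is.null(map)) {
      out$flank_left <- character(); out$flank_right <- character()
      out$bp_lo <- numeric(); out$bp_hi <- numeric()
    }
    return(out)
  }
  out <- do.call(rbind, calls)
  out <- out[order(out$chrom, out$peak_cm), ]
  rownames(out) <- NULL
  out
}
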