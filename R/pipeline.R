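#' Default end-to-end pipeline configuration
#'
#' One place for every tunable the pipeline uses: population and trial
#' specifications, trait architecture, and the analysis thresholds
#' (stepwise entry probability PIN = 0.001, scan step 1 cM, calling
#' thresholds LOD > 2.0 and PVE >= 3%, daily grid 1-85 DAS,
#' alpha = 0.05), all defaulted to the study conditions.
#'
#' The default trait architecture places, per population, a handful of
#' additive loci on the growth parameters with effects in the ranges seen
#' in maize RIL trials (2-5 cm on the asymptote, 0.2-0.5 d on the
#' inflection point, 0.2-0.3 on the shape), plus one time-windowed
#' "opportunistic" height locus, over a polygenic background.
#'
#' @param populations as from [default_populations()].
#' @param design a [trial_design()].
#' @param architectures named list of [trait_architecture()], one per
#'   population (default: a fixed per-population QTL layout).
#' @param seed integer seed for the whole run.
#' @param outdir output directory (created if missing).
#' @param pin,step_cm,lod_min,pve_min,window_cm,alpha analysis thresholds.
#' @param day_range daily imputation/scan range, within `[1, 200]`.
#' @param scan_method `"icim"` or `"im"`.
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(populations = default_populations(),
                            design = trial_design(),
                            architectures = NULL,
                            seed = 1,
                            outdir = "results",
                            pin = 0.001, step_cm = 1.0,
                            lod_min = 2.0, pve_min = 0.03,
                            window_cm = 10, alpha = 0.05,
                            day_range = c(1, 85),
                            scan_method = "icim") {
  stopifnot(day_range[1] >= 1, day_range[2] <= 200,
            day_range[1] < day_range[2])
  if (is.null(architectures)) {
    architectures <- lapply(populations, function(p) {
      len <- p$spec$chromosomes$length_cm
      trait_architecture(qtl = data.frame(
        chrom = c("1", "3", "5", "6", "2"),
        pos_cm = round(len[c(1, 3, 5, 6, 2)] * c(0.85, 0.55, 0.75,
                                                 0.25, 0.45)),
        param = c("L", "x0", "L", "b", "height"),
        effect = c(0.04, 0.5, 0.03, 0.25, 0.03),
        window_start = c(NA, NA, NA, NA, 40),
        window_end = c(NA, NA, NA, NA, 70)))
    })
    names(architectures) <- names(populations)
  }
  structure(list(populations = populations, design = design,
                 architectures = architectures, seed = seed,
                 outdir = outdir, pin = pin, step_cm = step_cm,
                 lod_min = lod_min, pve_min = pve_min,
                 window_cm = window_cm, alpha = alpha,
                 day_range = day_range, scan_method = scan_method),
            class = "pipeline_config")
}

#' Pearson correlation report among trait columns
#'
#' Pairwise-complete Pearson correlations with two-sided tests of r = 0.
#' Constant columns yield `NA` correlations and are flagged.
#'
#' @param traits data.frame of numeric trait columns.
#' @return List: `r` (symmetric matrix, unit diagonal), `p` (p-value
#'   matrix), `n` (pairwise n), `constant` (names of zero-variance
#'   columns).
#' @export
correlation_report <- function(traits) {
  traits <- as.data.frame(traits)
  num <- vapply(traits, is.numeric, logical(1))
  traits <- traits[num]
  k <- ncol(traits)
  if (k < 2) stop("need >= 2 numeric trait columns")
  nms <- names(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(r) <- 1; diag(p) <- 0
  const <- nms[vapply(traits, function(v) {
    stats::sd(v, na.rm = TRUE) < 1e-12
  }, logical(1))]
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i >= j) next
      ok <- stats::complete.cases(traits[[i]], traits[[j]])
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3 || nms[i] %in% const || nms[j] %in% const) next
      ct <- stats::cor.test(traits[[i]][ok], traits[[j]][ok])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n, constant = const)
}

#' Run the full simulation-to-temporal-QTL pipeline
#'
#' Stages: simulate (RIL genotypes + multi-flight trial per population) ->
#' blup (per-flight REML variance components, H2, entry BLUPs per
#' environment) -> fitgrowth (per-entry Weibull fits to BLUP trajectories,
#' goodness-of-fit filter, daily imputation) -> buildmap (genotype QC,
#' double-recombinant cleaning, marker binning, Kosambi map) -> scan
#' (functional-parameter QTL + day-by-day scans clustered into temporal
#' QTL) -> report (correlations among growth parameters, terminal height
#' and a flowering proxy; co-localizations). Every table is written under
#' `config$outdir` with a metadata header carrying the seed; the run is
#' deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with all in-memory results per population
#'   (`sim`, `blup`, `fits`, `daily`, `map`, `temporal`, `param_qtl`,
#'   `coloc`, `correlations`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(package = "uasqtl",
               version = as.character(utils::packageVersion("uasqtl")),
               seed = config$seed)
  say <- function(...) if (!quiet) message(...)
  res <- list()
  pop_seed <- config$seed

  for (pn in names(config$populations)) {
    pop_cfg <- config$populations[[pn]]
    arch <- config$architectures[[pn]]
    pop_seed <- pop_seed + 1
    say("[", pn, "] simulate")
    pop <- simulate_ril_population(pop_cfg$spec, pop_cfg$n_lines,
                                   seed = pop_seed)
    trial <- simulate_trial(pop, arch, config$design,
                            seed = pop_seed + 1000)
    write_genotype_csv(pop$geno, file.path(config$outdir,
                                           paste0(pn, "_geno.csv")))
    write_table_meta(pop$map,
                     file.path(config$outdir, paste0(pn, "_physmap.csv")),
                     meta)
    write_table_meta(trial$obs,
                     file.path(config$outdir, paste0(pn, "_pheno.csv")),
                     meta)
    jsonlite::write_json(
      trial$truth[c("entry_params", "qtl", "variance_components")],
      file.path(config$outdir, paste0(pn, "_truth.json")),
      digits = NA, dataframe = "columns")

    say("[", pn, "] blup")
    bl <- blup_by(trial$obs, by = c("das", "env"))
    write_table_meta(bl$varcomp,
                     file.path(config$outdir, paste0(pn, "_varcomp.csv")),
                     meta)
    write_table_meta(bl$blup,
                     file.path(config$outdir, paste0(pn, "_blup.csv")),
                     meta)

    say("[", pn, "] fitgrowth + impute")
    resid_sd <- sqrt(stats::aggregate(
      estimate ~ env, data = bl$varcomp[bl$varcomp$component == "residual", ],
      FUN = mean)$estimate)
    names(resid_sd) <- unique(bl$varcomp$env)
    fits_rows <- list(); daily_env <- list()
    for (env in config$design$environments) {
      be <- bl$blup[bl$blup$env == env, ]
      sigma_entry <- resid_sd[[env]] / sqrt(config$design$n_reps)
      entries <- unique(be$entry)
      daily_mat <- matrix(
        NA_real_, length(entries),
        config$day_range[2] - config$day_range[1] + 1,
        dimnames = list(entries,
                        paste0("d", seq(config$day_range[1],
                                        config$day_range[2]))))
      for (en in entries) {
        tr <- be[be$entry == en, ]
        fit <- fit_weibull(tr$das, tr$predicted)
        keep <- fit$converged &&
          goodness_of_fit_filter(fit, sigma_entry, config$alpha)
        fits_rows[[paste(env, en)]] <- data.frame(
          pop = pn, env = env, entry = en, L = fit$L, x0 = fit$x0,
          b = fit$b, r2 = fit$r2, rmse = fit$rmse,
          converged = fit$converged, gof_keep = keep)
        if (keep) {
          daily_mat[en, ] <- impute_daily_heights(fit, config$day_range)
        }
      }
      daily_env[[env]] <- daily_mat[!is.na(daily_mat[, 1]), , drop = FALSE]
    }
    fits <- do.call(rbind, c(fits_rows, make.row.names = FALSE))
    write_table_meta(fits,
                     file.path(config$outdir, paste0(pn, "_fits.csv")),
                     meta)

    say("[", pn, "] buildmap")
    qc <- filter_missing(pop$geno)
    g <- set_het_missing(qc$geno)
    cln <- clean_double_recombinants(g, pop$map)
    bins <- bin_redundant_markers(cln$geno, pop$map)
    lmap <- build_map(bins$geno, pop$map)
    write_table_meta(lmap$map,
                     file.path(config$outdir, paste0(pn, "_linkmap.csv")),
                     meta)

    say("[", pn, "] scan + temporal")
    gp <- genotype_probabilities(bins$geno, lmap$map,
                                 step_cm = config$step_cm)
    temporal_env <- list(); param_qtl_env <- list()
    for (env in config$design$environments) {
      daily <- daily_env[[env]]
      scans <- scan_all_days(daily, bins$geno, gp,
                             method = config$scan_method,
                             pin = config$pin)
      tq <- cluster_temporal(scans, window_cm = config$window_cm,
                             lod_min = config$lod_min,
                             pve_min = config$pve_min)
      temporal_env[[env]] <- tq
      fe <- fits[fits$env == env & fits$gof_keep, ]
      pq <- lapply(c(L = "L", x0 = "x0", b = "b"), function(par) {
        y <- stats::setNames(fe[[par]], fe$entry)
        call_qtl(icim_scan(y, bins$geno, gp, pin = config$pin),
                 lod_min = config$lod_min, pve_min = config$pve_min,
                 map = lmap$map)
      })
      param_qtl_env[[env]] <- pq
      if (nrow(tq$qtl) > 0) {
        write_table_meta(
          cbind(pop = pn, env = env, tq$qtl),
          file.path(config$outdir,
                    paste0(pn, "_", env, "_temporal_qtl.csv")), meta)
        write_table_meta(
          cbind(pop = pn, env = env, tq$trajectories),
          file.path(config$outdir,
                    paste0(pn, "_", env, "_trajectories.csv")), meta)
      }
    }

    say("[", pn, "] report")
    truth <- trial$truth$entry_params
    # manual terminal height and flowering-time proxies for the
    # correlation report (synthetic ground-truth analogues)
    fe_all <- fits[fits$gof_keep, ]
    tr_key <- paste(truth$entry, truth$env)
    fe_key <- paste(fe_all$entry, fe_all$env)
    tr <- truth[match(fe_key, tr_key), ]
    prox_seed <- pop_seed + 2000
    set.seed(prox_seed)
    terminal <- tr$L + 0.5 + stats::rnorm(nrow(tr), 0, 0.05)
    flowering <- tr$x0 + 7 + stats::rnorm(nrow(tr), 0, 2)
    agr <- vapply(seq_len(nrow(fe_all)), function(i) {
      agr_max(fe_all[i, c("L", "x0", "b")])$agr_max
    }, numeric(1))
    traits <- data.frame(L = fe_all$L, x0 = fe_all$x0, b = fe_all$b,
                         max_agr = agr, terminal_height = terminal,
                         flowering = flowering)
    corr <- correlation_report(traits)
    write_table_meta(as.data.frame(corr$r),
                     file.path(config$outdir,
                               paste0(pn, "_correlations.csv")), meta)

    coloc <- lapply(config$design$environments, function(env) {
      lists <- c(param_qtl_env[[env]],
                 list(temporal = temporal_env[[env]]$qtl))
      colocalize(lists, window_cm = config$window_cm)
    })
    names(coloc) <- config$design$environments

    res[[pn]] <- list(sim = trial, pop = pop, blup = bl, fits = fits,
                      daily = daily_env, map = lmap,
                      temporal = temporal_env, param_qtl = param_qtl_env,
                      coloc = coloc, correlations = corr)
  }
  invisible(res)
}
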