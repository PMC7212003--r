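#!/usr/bin/env Rscript
# Stage 5: QTL scans.
#
# ICIM-ADD (stepwise background markers at PIN = 0.001, then Haley-Knott
# regression of the adjusted phenotype on expected genotype scores at a
# 1 cM step) is run per population x environment: once per functional
# growth parameter (L, x0, b) and once per imputed day 1-85 DAS. Daily
# calls (LOD > 2, PVE >= 3%) are clustered into temporal QTL (10 cM
# single-linkage window, 2-day gap bridging); effect-sign switches,
# cross-trait co-localizations, and distances to a synthetic candidate
# gene list are reported.

suppressPackageStartupMessages(library(uasqtl))

outdir <- "results/analysis"
pops <- c("Tx740xNC356", "Ki3xNC356", "LH82xLAMA")
meta <- list(stage = "temporal_qtl")
envs <- c("irrigated", "non_irrigated")

# synthetic candidate-gene table: 40 genes scattered over the 10
# chromosomes (stand-in for a curated height-gene list)
set.seed(2718)
genes <- data.frame(
  name = sprintf("gene%02d", 1:40),
  chrom = as.character(sample(1:10, 40, replace = TRUE)),
  start = round(runif(40, 1e6, 280e6)))
genes$end <- genes$start + round(runif(40, 2e3, 8e4))
write_table_meta(genes, file.path(outdir, "synthetic_candidate_genes.csv"),
                 meta)

n_unique_total <- 0
for (pn in pops) {
  g <- read_genotype_csv(file.path(outdir, paste0(pn, "_geno_clean.csv")))
  lmap <- read_table_meta(file.path(outdir, paste0(pn, "_linkmap.csv")))
  lmap$chrom <- as.character(lmap$chrom)
  fits <- read_table_meta(file.path(outdir, paste0(pn, "_fits.csv")))
  gp <- genotype_probabilities(g, lmap)
  for (env in envs) {
    daily_df <- read_table_meta(
      file.path(outdir, paste0(pn, "_", env, "_daily.csv")))
    daily <- as.matrix(daily_df[, -1])
    rownames(daily) <- daily_df$entry
    scans <- scan_all_days(daily, g, gp, method = "icim")
    tq <- cluster_temporal(scans)
    n_unique_total <- n_unique_total + nrow(tq$qtl)
    write_table_meta(tq$qtl,
                     file.path(outdir,
                               paste0(pn, "_", env, "_temporal_qtl.csv")),
                     meta)
    write_table_meta(tq$trajectories,
                     file.path(outdir,
                               paste0(pn, "_", env, "_trajectories.csv")),
                     meta)
    fe <- fits[fits$env == env & fits$gof_keep, ]
    pq <- lapply(c(asymptote = "L", inflection = "x0", growth_rate = "b"),
                 function(par) {
                   y <- setNames(fe[[par]], fe$entry)
                   call_qtl(icim_scan(y, g, gp), map = lmap)
                 })
    coloc <- colocalize(c(pq, list(temporal = tq$qtl)))
    write_table_meta(coloc,
                     file.path(outdir, paste0(pn, "_", env, "_coloc.csv")),
                     meta)
    if (nrow(tq$qtl) > 0) {
      tq_phys <- call_qtl(scans$profiles[[which.max(
        vapply(scans$profiles, function(p) max(p$lod), numeric(1)))]],
        map = lmap)
      gd <- if (nrow(tq_phys) > 0) {
        candidate_gene_distance(tq_phys, genes)
      } else NULL
      n_sw <- sum(tq$qtl$sign_switch)
      cat(sprintf(
        "%s %s: %d temporal QTL (onsets %s) | %d with sign switch | %d param QTL | %d co-localizations\n",
        pn, env, nrow(tq$qtl),
        paste(range(tq$qtl$onset), collapse = "-"), n_sw,
        sum(vapply(pq, nrow, numeric(1))), nrow(coloc)))
      if (!is.null(gd)) {
        cat(sprintf("  peak-day QTL within 1 Mb of a candidate gene: %d/%d\n",
                    gd$n_within_1mb, nrow(gd$distances)))
        write_table_meta(gd$distances,
                         file.path(outdir,
                                   paste0(pn, "_", env,
                                          "_gene_distances.csv")), meta)
      }
    } else {
      cat(sprintf("%s %s: no temporal QTL called\n", pn, env))
    }
  }
}
cat("total unique temporal QTL across populations and environments:",
    n_unique_total, "\n")
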