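#!/usr/bin/env Rscript
# Stage 2: per-flight mixed models.
#
# For every flight date x environment x population, fit
# height = mu + G + Rep + Range + Row + error by REML; report variance
# components, their percent-of-total decomposition, entry-mean
# heritability, and extract entry BLUPs for the growth-curve stage.

suppressPackageStartupMessages(library(uasqtl))

outdir <- "results/analysis"
pops <- c("Tx740xNC356", "Ki3xNC356", "LH82xLAMA")
meta <- list(stage = "blup")

for (pn in pops) {
  obs <- read_table_meta(file.path(outdir, paste0(pn, "_pheno.csv")))
  bl <- blup_by(obs, by = c("das", "env"))
  write_table_meta(bl$varcomp,
                   file.path(outdir, paste0(pn, "_varcomp.csv")), meta)
  write_table_meta(bl$blup,
                   file.path(outdir, paste0(pn, "_blup.csv")), meta)
  g_share <- bl$varcomp[bl$varcomp$component == "G", ]
  late <- g_share[g_share$das > 35, ]
  cat(sprintf(
    "%s: genetic share of variance %0.f%% (mean over flights > 35 DAS); H2 %.2f-%.2f\n",
    pn, mean(late$share_pct), min(late$H2), max(late$H2)))
}
cat("wrote variance components and BLUPs to", outdir, "\n")
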