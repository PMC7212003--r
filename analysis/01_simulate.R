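#!/usr/bin/env Rscript
# Stage 1: simulate the three RIL populations and their field trials.
#
# Three biparental maize RIL populations (102, 237, 178 lines; 10
# chromosomes; ~1,315 / 1,207 / 1,474 cM maps at binned-SNP density) are
# grown in two environments (irrigated, non-irrigated) as an RCBD with two
# replicates and range/row spatial effects, and flown on eight dates
# (35, 43, 57, 62, 65, 69, 100, 117 DAS). Each population carries a small
# set of additive loci on the Weibull growth parameters plus one
# time-windowed height locus, over a polygenic background.

suppressPackageStartupMessages(library(uasqtl))

seed <- 42
outdir <- "results/analysis"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
cfg <- pipeline_config(seed = seed, outdir = outdir)
meta <- list(stage = "simulate", seed = seed)

for (pn in names(cfg$populations)) {
  p <- cfg$populations[[pn]]
  seed <- seed + 1
  pop <- simulate_ril_population(p$spec, p$n_lines, seed = seed)
  trial <- simulate_trial(pop, cfg$architectures[[pn]], cfg$design,
                          seed = seed + 1000)
  write_genotype_csv(pop$geno, file.path(outdir, paste0(pn, "_geno.csv")))
  write_table_meta(pop$map, file.path(outdir, paste0(pn, "_physmap.csv")),
                   meta)
  write_table_meta(trial$obs, file.path(outdir, paste0(pn, "_pheno.csv")),
                   meta)
  jsonlite::write_json(
    trial$truth[c("entry_params", "qtl", "variance_components")],
    file.path(outdir, paste0(pn, "_truth.json")),
    digits = NA, dataframe = "columns")
  cat(sprintf(
    "%s: %d lines x %d markers, %d plot-flight observations, %d true QTL\n",
    pn, nrow(pop$geno), ncol(pop$geno), nrow(trial$obs),
    nrow(trial$truth$qtl)))
}
cat("wrote genotypes, physical maps, phenotypes and truth to", outdir, "\n")
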