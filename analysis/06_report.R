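#!/usr/bin/env Rscript
# Stage 6: trait correlations and run summary.
#
# Pearson correlations among the functional growth parameters, the
# maximum absolute growth rate, and the synthetic manual ground-truth
# analogues (terminal height = true asymptote + measurement bias + noise;
# flowering proxy = true inflection point + offset + noise), per
# population; plus a one-screen summary of the whole run.

suppressPackageStartupMessages(library(uasqtl))

outdir <- "results/analysis"
pops <- c("Tx740xNC356", "Ki3xNC356", "LH82xLAMA")
meta <- list(stage = "report")
set.seed(3141)

for (pn in pops) {
  fits <- read_table_meta(file.path(outdir, paste0(pn, "_fits.csv")))
  truth <- jsonlite::read_json(file.path(outdir, paste0(pn, "_truth.json")),
                               simplifyVector = TRUE)
  tp <- as.data.frame(truth$entry_params)
  fe <- fits[fits$gof_keep, ]
  tr <- tp[match(paste(fe$entry, fe$env), paste(tp$entry, tp$env)), ]
  terminal <- tr$L + 0.5 + rnorm(nrow(tr), 0, 0.05)
  flowering <- tr$x0 + 7 + rnorm(nrow(tr), 0, 2)
  corr <- correlation_report(data.frame(
    L = fe$L, x0 = fe$x0, b = fe$b, max_agr = fe$max_agr_mm_day,
    terminal_height = terminal, flowering = flowering))
  write_table_meta(cbind(trait = rownames(corr$r), as.data.frame(corr$r)),
                   file.path(outdir, paste0(pn, "_correlations.csv")),
                   meta)
  cat(sprintf(
    "%s: r(L, terminal) = %.2f | r(x0, flowering) = %.2f | r(max AGR, terminal) = %.2f\n",
    pn, corr$r["L", "terminal_height"], corr$r["x0", "flowering"],
    corr$r["max_agr", "terminal_height"]))
}

cat("\n-- run summary --\n")
for (pn in pops) {
  vc <- read_table_meta(file.path(outdir, paste0(pn, "_varcomp.csv")))
  gshare <- vc[vc$component == "G" & vc$das > 35, "share_pct"]
  rep_json <- jsonlite::read_json(
    file.path(outdir, paste0(pn, "_map_report.json")))
  n_tq <- 0
  for (env in c("irrigated", "non_irrigated")) {
    f <- file.path(outdir, paste0(pn, "_", env, "_temporal_qtl.csv"))
    if (file.exists(f)) n_tq <- n_tq + nrow(read_table_meta(f))
  }
  cat(sprintf(
    "%s: genetic variance %0.f%% | map %0.f cM | %d temporal QTL\n",
    pn, mean(gshare), rep_json$total_length_cm, n_tq))
}
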