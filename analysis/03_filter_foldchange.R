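#!/usr/bin/env Rscript
# Filter cascade (never-sequenced, low-coverage, ambiguous lacI,
# uncomputable fold changes), log2 fold changes against the steady-state
# mean, two-fold regulation classification under both normalizations, and
# the top-100 regulated gene lists.

library(spikeseq)

fx <- file.path("results/fixture", c("counts.tsv", "annotation.tsv",
                                     "samples_qc.tsv"))
x <- read_counts(fx[1], fx[2], fx[3])

summaries <- list(); tops <- list()
for (norm in list(normalize_rpksp(x), normalize_rpkm(x))) {
  fc <- apply_filters(norm)
  cat(norm$method, "filter outcome:\n")
  print(table(fc$filter_status))
  tab <- data.frame(gene_id = rownames(fc$log2_fc),
                    filter_status = as.character(fc$filter_status),
                    steady_mean = fc$steady_mean, fc$log2_fc,
                    check.names = FALSE)
  names(tab)[-(1:3)] <- paste0("log2fc_", fc$meta$sample_id)
  write.table(tab, sprintf("results/fold_changes_%s.tsv",
                           tolower(norm$method)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in c(10, 80))
    summaries[[paste(norm$method, t)]] <- classify_regulation(fc, t, 2)
  if (norm$method == "RPKSP")
    for (dir in c("up", "down"))
      tops[[dir]] <- top_regulated(fc, c(10, 80), 100, dir)
}
reg <- do.call(rbind, summaries)
rownames(reg) <- NULL
write.table(reg, "results/regulation_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (dir in names(tops))
  write.table(tops[[dir]], sprintf("results/top100_%s_rpksp.tsv", dir),
              sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nTwo-fold regulation calls:\n")
print(reg)
d <- reg[reg$time_min == 80, ]
cat(sprintf("\nAt 80 min, depth normalization misses %.0f%% of the
down-regulated calls and overcalls up-regulation by %.0f%%.\n",
  100 * (d$n_down[d$method == "RPKSP"] - d$n_down[d$method == "RPKM"]) /
    d$n_down[d$method == "RPKSP"],
  100 * (d$n_up[d$method == "RPKM"] - d$n_up[d$method == "RPKSP"]) /
    d$n_up[d$method == "RPKSP"]))
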