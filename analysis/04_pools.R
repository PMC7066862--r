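#!/usr/bin/env Rscript
# Class-level RNA pool profiles (16S/23S/5S rRNA, tRNA, total mRNA) under
# both normalizations, relative to the pre-starvation mean, including the
# rifampicin tail.

library(spikeseq)

fx <- file.path("results/fixture", c("counts.tsv", "annotation.tsv",
                                     "samples_qc.tsv"))
x <- read_counts(fx[1], fx[2], fx[3])
mset <- mrna_gene_set(x$annotation)

pools <- list()
for (norm in list(normalize_rpksp(x), normalize_rpkm(x))) {
  for (cl in c("rRNA_16S", "rRNA_23S", "rRNA_5S", "tRNA")) {
    p <- pool_profile(norm, classes = cl)
    p$method <- norm$method
    pools[[paste(norm$method, cl)]] <- p
  }
  p <- pool_profile(norm, genes = mset, label = "mRNA")
  p$method <- norm$method
  pools[[paste(norm$method, "mRNA")]] <- p
}
tab <- do.call(rbind, pools)
rownames(tab) <- NULL
write.table(tab, "results/pool_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

show <- function(lab, meth, t, cond = "starvation")
  round(100 * tab$relative[tab$label == lab & tab$method == meth &
                             tab$time_min == t & tab$condition == cond], 1)
cat("Pool remaining at 80 min starvation (% of pre-starvation):\n")
cat(sprintf("  16S+23S rRNA: RPKSP %s%% / %s%%  vs RPKM %s%% / %s%%\n",
            show("rRNA_16S", "RPKSP", 80), show("rRNA_23S", "RPKSP", 80),
            show("rRNA_16S", "RPKM", 80), show("rRNA_23S", "RPKM", 80)))
cat(sprintf("  total mRNA:  RPKSP %s%% (10 min: %s%%)\n",
            show("mRNA", "RPKSP", 80), show("mRNA", "RPKSP", 10)))
cat(sprintf("  tRNA at rifampicin endpoint: %s%%\n",
            show("tRNA", "RPKSP", 125, "rifampicin")))
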