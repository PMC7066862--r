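# spikeseq

Whole-cell spike-in normalization and analysis of bacterial RNA-seq count
data.

## The problem

When *Escherichia coli* runs into amino-acid starvation, the stringent
response (via the alarmone ppGpp) shuts down stable-RNA synthesis and
existing ribosomal RNA is degraded. Because rRNA is the overwhelming
majority of cellular RNA, the *total* RNA per cell mass drops by tens of
percent within the first hour. Conventional depth-based normalization
(RPKM and relatives) assumes that total is constant, so under these
conditions it systematically under-calls down-regulation and over-calls
up-regulation.

The whole-cell spike-in design fixes this: a reference culture expressing
three transcripts absent from the experimental strain (*qrr2*, *bla*,
antisense-*lacI*, from a plasmid) is mixed into every sample **before RNA
extraction**, dosed at a fixed fraction of the sampled cell mass by
optical density,

    V_spike = f · V_sample · OD_sample / OD_spike        (f = 0.01).

All extraction, library and depth variation then cancels in the ratio of
gene reads to spike-in reads. The package implements both normalizations
for a gene of length `L` kb with reads `r` in a sample:

    RPKSP = (r / L) / (S / 10^4)      S = spike-in reads per kb (pooled features)
    RPKM  = (r / T · 10^6) / L        T = chromosome-mapped total reads

RPKSP measures abundance per cell mass; RPKM measures share of sequenced
RNA. Within a sample they differ by one constant, which is exactly the
source of the fold-change bias the package quantifies.

`spikeseq` is for microbial transcriptomics researchers who have per-gene
count matrices from a spike-in design (or want to evaluate one): it covers
validated count/annotation/metadata I/O, spike-in dosing, both
normalizations, expression filtering, fold-change classification,
RNA-class pool profiles (rRNA, tRNA, total mRNA), spike-in read-ratio QC
with outlier flagging, temporal-profile PCA with Fisher-exact/BH gene-set
enrichment, qRT-PCR (2^−ΔΔCt) and northern-blot calculators, and a
synthetic experiment generator with recorded ground truth.

## Worked example

Simulate the default synthetic experiment (3 steady-state replicates,
starvation samples at 5–80 min, 89% rRNA read share, a decaying total-RNA
pool and a mid-series sampling outlier), run QC, and compare the two
normalizations:

```r
library(spikeseq)

sim <- simulate_experiment(synth_config(seed = 1))
qc  <- flag_outliers(spikein_fraction_qc(sim$counts))
attr(qc, "flagged")
#> [1] "t20"

x     <- mark_outliers(sim$counts, attr(qc, "flagged"))
rpksp <- normalize_rpksp(x)
rpkm  <- normalize_rpkm(x)
rbind(classify_regulation(apply_filters(rpksp), 80),
      classify_regulation(apply_filters(rpkm),  80))
#>   time_min method n_up n_down n_unchanged n_na
#> 1       80  RPKSP  179   1171         738 2123
#> 2       80   RPKM  293    862         926 2130
```

The 20-min sample deviates from the spike-ratio trend and is flagged; at
80 min, depth normalization (RPKM) reports 862 of the 1171 two-fold
down-regulated genes found with spike-in normalization — it misses ~26% of
the down-calls and inflates the up-calls — even though both methods see
the identical counts. The rRNA pool tells the same story directly:

```r
p <- subset(pool_profile(rpksp, classes = c("rRNA_16S", "rRNA_23S")),
            condition == "starvation", c(sample_id, time_min, relative))
p$relative <- round(p$relative, 3)
print(p, row.names = FALSE)
#>  sample_id time_min relative
#>        t05        5    0.978
#>        t10       10    0.945
#>        t20       20    0.612
#>        t40       40    0.776
#>        t80       80    0.708
```

Per cell mass, ~70% of the 16S+23S rRNA pool remains after 80 min of
starvation (the generator programmed 0.70; the flagged 20-min sample shows
its injected sampling artifact). The same genes under RPKM stay flat near
1.0 — the decline is invisible to depth normalization.

The numbered scripts under `analysis/` run the full study in order —
`01_simulate.R` (fixture with ground truth), `02_normalize_qc.R`,
`03_filter_foldchange.R`, `04_pools.R` (including the rifampicin tail
where the tRNA read signal falls to ~2%), `05_pca_enrichment.R` (two
temporal archetypes dominate the profile PCA; planted gene groups enrich
in the 10% extreme subsets), `06_assays.R` (northern-blot cross-check of
the rRNA decay) — writing their tables under `results/`.

See `vignettes/spikeseq-methods.Rmd` for the model, parameter defaults and
their rationale, numerical choices, and what the synthetic data do and do
not emulate.

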