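test_that("simulation is reproducible and conserves read depth", {
  a <- simulate_experiment(small_config(seed = 13))
  b <- simulate_experiment(small_config(seed = 13))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_experiment(small_config(seed = 14))
  expect_false(identical(a$counts$counts, c_$counts$counts))

  # multinomial conservation: column sums equal the drawn depths exactly
  expect_equal(unname(colSums(a$counts$counts)),
               a$truth$samples$depth[match(colnames(a$counts$counts),
                                           a$truth$samples$sample_id)])
  rng <- small_config(seed = 13)$read_depth_range
  expect_true(all(a$truth$samples$depth >= rng[1] &
                    a$truth$samples$depth <= rng[2]))
})

test_that("the null simulation is flat and yields no regulation calls", {
  cfg <- small_config(seed = 21, rrna_retention_curve = flat_curve,
                      mrna_pool_curve = flat_curve, trna_curve = flat_curve,
                      fraction_up = 0, fraction_down = 0,
                      outlier_injection = NULL,
                      read_depth_range = c(2.2e7, 2.9e7))
  sim <- simulate_experiment(cfg)
  expect_true(all(sim$truth$genes$regulated == "none"))
  r <- normalize_rpksp(sim$counts)
  for (cl in c("rRNA_16S", "tRNA", "mRNA")) {
    p <- pool_profile(r, classes = cl)
    expect_equal(p$relative, rep(1, nrow(p)), tolerance = 0.1)
  }
  fc <- apply_filters(r)
  s <- classify_regulation(fc, 80, 2)
  # only sampling noise on weak genes can cross the 2-fold line
  expect_lt((s$n_up + s$n_down) / (s$n_up + s$n_down + s$n_unchanged), 0.05)
})

test_that("ground-truth pool curves propagate to expected class abundances", {
  sim <- simulate_experiment(small_config(seed = 31))
  tg <- sim$truth$genes
  w <- tg$baseline_weight
  for (t in c(10, 80)) {
    rel <- tg[[paste0("rel_", t)]]
    m <- tg$rna_class == "mRNA"
    expect_equal(sum(w[m] * rel[m]) / sum(w[m]),
                 unname(sim$config$mrna_pool_curve[as.character(t)]),
                 tolerance = 1e-12)
    r16 <- tg$rna_class == "rRNA_16S"
    expect_equal(unique(rel[r16]),
                 unname(sim$config$rrna_retention_curve[as.character(t)]))
  }
  # steady-state relative abundance is 1 by construction for every gene
  expect_true(all(abs(log2(tg$rel_10[tg$regulated == "none" &
                                       tg$rna_class == "mRNA"]) -
                        tg$log2fc_10[tg$regulated == "none" &
                                       tg$rna_class == "mRNA"]) < 1e-12))
})

test_that("fixtures round-trip through the counts reader", {
  sim <- simulate_experiment(small_config(seed = 17))
  d <- withr::local_tempdir()
  paths <- write_fixture(d, sim)
  x <- read_counts(paths["counts"], paths["annotation"], paths["meta"])
  expect_identical(x$counts, sim$counts$counts)
  expect_identical(x$annotation, sim$counts$annotation)
  truth <- read.delim(paths[["truth_genes"]])
  expect_identical(nrow(truth), nrow(sim$counts$counts))
  # regenerating from the same seed reproduces identical files
  d2 <- withr::local_tempdir()
  paths2 <- write_fixture(d2, simulate_experiment(small_config(seed = 17)))
  for (k in names(paths))
    expect_identical(readLines(paths2[[k]]), readLines(paths[[k]]))
})

test_that("rifampicin tail decays synthesis-dependent classes only", {
  sim <- simulate_experiment(small_config(seed = 19))
  ext <- simulate_rifampicin_tail(sim)
  expect_identical(ncol(ext$counts$counts), 12L)
  expect_identical(unique(ext$counts$meta$condition[9:12]), "rifampicin")
  tg <- ext$truth$genes
  # programmed endpoints: tRNA at trna_tail_end, rRNA undisturbed
  expect_equal(unique(tg$rel_rif_125[tg$rna_class == "tRNA"]), 0.02)
  expect_equal(unique(tg$rel_rif_125[tg$rna_class == "rRNA_23S"]),
               unname(sim$config$rrna_retention_curve["80"]))
  # mRNA keeps decaying below its 80-min level
  m <- tg$rna_class == "mRNA" & tg$category == "regular"
  expect_true(all(tg$rel_rif_90[m] < tg$rel_80[m] + 1e-12))

  expect_error(simulate_rifampicin_tail(sim, tail_times = c(70, 90)),
               "after the last starvation")
  ext2 <- simulate_rifampicin_tail(sim)
  expect_identical(ext$counts$counts, ext2$counts$counts)
})

test_that("a tail continuing the 80-min state is statistically unchanged", {
  # freeze all classes at their 80-min level; the appended sample should
  # look like an extra 80-min replicate up to multinomial noise
  sim <- simulate_experiment(small_config(seed = 23,
                                          outlier_injection = NULL,
                                          read_depth_range = c(2e5, 2e5)))
  curve80 <- sim$config$rrna_retention_curve[["80"]]
  ext <- simulate_rifampicin_tail(
    sim, tail_times = 90,
    trna_tail_end = sim$config$trna_curve[["80"]],
    mrna_halflife_min = 1e9, srna_halflife_min = 1e9)
  r <- normalize_rpksp(ext$counts)
  p <- pool_profile(r, classes = "mRNA")
  expect_equal(p$pooled[p$sample_id == "rif10"],
               p$pooled[p$sample_id == "t80"], tolerance = 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(fraction_up = 0.7, fraction_down = 0.5),
               "exceed 1")
  expect_error(small_config(read_depth_range = c(100, 200)), "10x")
  expect_error(small_config(rrna_retention_curve = c(`5` = 1)), "named by")
  expect_error(small_config(rrna_read_fraction_steady = 1.2), "fraction")
})
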