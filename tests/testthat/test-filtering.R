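# value grids are in normalized units; sample layout: 3 steady + starvation
mk_vals <- function(rows, times = c(-15, -10, -5, 5, 10, 40, 80)) {
  m <- do.call(rbind, rows)
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  m
}

test_that("filter i removes exactly the never-sequenced genes", {
  rows <- c(lapply(1:3, function(i) rep(0, 8)),          # all-zero
            lapply(4:9, function(i) c(rep(5, 3), rep(2, 5))),
            list(c(rep(0, 7), 1)))                       # single late read
  m <- mk_vals(rows, times = c(-15, -10, -5, 5, 10, 20, 40, 80))
  rownames(m) <- paste0("g", 1:10)
  norm <- make_norm(m, times = c(-15, -10, -5, 5, 10, 20, 40, 80))
  norm <- filter_unexpressed(norm)
  expect_identical(sum(norm$filter_status == "removed_filter_i"), 3L)
  expect_identical(unname(norm$filter_status[["g10"]] == "kept"), TRUE)
})

test_that("filter ii removes genes low in both phases only", {
  m <- rbind(g_low_both = c(0, 0, 0, 0.1, 0.1, 0.1, 0.1),
             g_burst    = c(0, 0, 0, 50, 50, 50, 50),
             g_steady   = c(9, 9, 9, 0, 0, 0, 0),
             g_fine     = c(5, 5, 5, 4, 4, 4, 4))
  colnames(m) <- paste0("s", 1:7)
  norm <- make_norm(m, times = c(-15, -10, -5, 5, 10, 40, 80))
  out <- filter_low_coverage(norm, low_threshold = 1)
  expect_identical(as.character(out$filter_status[["g_low_both"]]),
                   "removed_filter_ii")
  expect_true(all(out$filter_status[c("g_burst", "g_steady", "g_fine")] ==
                    "kept"))

  # threshold 0: removal only on exact zeros in both phases
  out0 <- filter_low_coverage(norm, low_threshold = 0)
  expect_true(all(out0$filter_status == "kept"))
  expect_error(filter_low_coverage(norm, -1), "non-negative")

  # outlier-flagged starvation samples are excluded from the average
  m2 <- rbind(g = c(0, 0, 0, 100, 0, 0, 0))
  colnames(m2) <- paste0("s", 1:7)
  norm2 <- make_norm(m2, times = c(-15, -10, -5, 5, 10, 40, 80),
                     is_outlier = c(rep(FALSE, 3), TRUE, rep(FALSE, 3)))
  out2 <- filter_low_coverage(norm2, low_threshold = 1)
  expect_identical(as.character(out2$filter_status[["g"]]),
                   "removed_filter_ii")
})

test_that("ambiguous-gene exclusion flags listed genes, warns on absent ids", {
  m <- rbind(lacI = rep(5, 4), g2 = rep(5, 4))
  colnames(m) <- paste0("s", 1:4)
  norm <- make_norm(m, times = c(-5, 5, 10, 80))
  out <- exclude_ambiguous(norm, "lacI")
  expect_identical(as.character(out$filter_status[["lacI"]]),
                   "excluded_ambiguous")
  expect_identical(exclude_ambiguous(norm, character(0))$filter_status,
                   init_filter_status(norm)$filter_status)
  expect_warning(out2 <- exclude_ambiguous(norm, "ghost"), "ghost")
  expect_true(all(out2$filter_status == "kept"))
})

test_that("log2 fold changes use the steady mean and flag uncomputable", {
  m <- rbind(g_up   = c(1, 1, 1, 4),
             g_flat = c(3, 3, 3, 3),
             g_na   = c(0, 0, 0, 7))
  colnames(m) <- paste0("s", 1:4)
  norm <- make_norm(m, times = c(-15, -10, -5, 10))
  fc <- log2_fold_changes(norm)
  expect_equal(unname(fc$log2_fc["g_up", 1]), 2)
  expect_equal(unname(fc$log2_fc["g_flat", 1]), 0)
  expect_true(is.na(fc$log2_fc["g_na", 1]))
  expect_equal(unname(fc$steady_mean), c(1, 3, 0))

  none <- make_norm(m, times = c(5, 10, 20, 40))
  expect_error(log2_fold_changes(none), "steady")
})

test_that("filter iii removes genes uncomputable at every listed time", {
  m <- rbind(g_both_na = c(2, 2, 2, 5, 0, 3, 0),
             g_one_ok  = c(2, 2, 2, 0, 4, 0, 0),
             g_fine    = c(2, 2, 2, 2, 2, 2, 2))
  colnames(m) <- paste0("s", 1:7)
  norm <- make_norm(m, times = c(-15, -10, -5, 5, 10, 40, 80))
  fc <- log2_fold_changes(init_filter_status(norm))
  out <- filter_uncomputable(fc, timepoints = c(10, 80))
  expect_identical(as.character(out$filter_status[["g_both_na"]]),
                   "removed_filter_iii")
  expect_identical(as.character(out$filter_status[["g_one_ok"]]), "kept")
  expect_error(filter_uncomputable(fc, timepoints = 33), "33")

  # single-time variant agrees with a direct scan
  out80 <- filter_uncomputable(fc, timepoints = 80)
  direct <- is.na(fc$log2_fc[, fc$meta$time_min == 80])
  expect_identical(unname(out80$filter_status == "removed_filter_iii"),
                   unname(direct))
})

test_that("regulation classification partitions the universe, boundary inclusive", {
  # log2 fc at t=10: +2, +1, 0, -1, -2, NA; plus a 1.98-fold gene
  m <- rbind(g1 = c(4, 4, 4, 16), g2 = c(4, 4, 4, 8), g3 = c(4, 4, 4, 4),
             g4 = c(4, 4, 4, 2), g5 = c(4, 4, 4, 1), g6 = c(0, 0, 0, 9),
             g7 = c(50, 50, 50, 99))
  colnames(m) <- paste0("s", 1:4)
  norm <- make_norm(m, times = c(-15, -10, -5, 10))
  fc <- log2_fold_changes(init_filter_status(norm))
  s <- classify_regulation(fc, 10, threshold = 2)
  expect_identical(s$n_up, 2L)          # +2 and +1 (>= 2-fold inclusive)
  expect_identical(s$n_down, 2L)
  expect_identical(s$n_unchanged, 2L)   # 0 and the 1.98-fold gene
  expect_identical(s$n_na, 1L)
  expect_identical(s$n_up + s$n_down + s$n_unchanged + s$n_na, nrow(m))
  expect_error(classify_regulation(fc, 10, threshold = 1), "> 1")

  # universe accounting: filtered genes count as N/A
  s2 <- classify_regulation(fc, 10, universe_size = 20)
  expect_identical(s2$n_na, 20L - 6L)
})

test_that("top_regulated ranks by mean fold change with lexicographic ties", {
  m <- rbind(b_gene = c(2, 2, 2, 8, 8), a_gene = c(2, 2, 2, 8, 8),
             c_gene = c(2, 2, 2, 16, 16), d_gene = c(2, 2, 2, 1, 0))
  colnames(m) <- paste0("s", 1:5)
  norm <- make_norm(m, times = c(-15, -10, -5, 10, 80))
  fc <- log2_fold_changes(init_filter_status(norm))
  top <- top_regulated(fc, c(10, 80), n = 3, direction = "up")
  expect_identical(top$gene_id, c("c_gene", "a_gene", "b_gene"))
  expect_identical(top_regulated(fc, c(10, 80), 1, "up")$gene_id, "c_gene")
  # d_gene has NA at 80 -> excluded from ranking; request beyond supply
  expect_message(all_up <- top_regulated(fc, c(10, 80), 10, "up"),
                 "rankable")
  expect_identical(nrow(all_up), 3L)
  down <- top_regulated(fc, c(10, 80), 1, direction = "down")
  expect_identical(down$gene_id, "a_gene")  # lexicographic among ties
})

test_that("filter cascade attributes each gene to its first filter", {
  m <- rbind(g_silent = rep(0, 7),
             g_low    = c(0.2, 0.2, 0.2, 0.1, 0.1, 0.1, 0.1),
             lacI     = rep(5, 7),
             g_na     = c(2, 2, 2, 5, 0, 4, 0),
             g_ok     = c(2, 2, 2, 8, 8, 8, 8))
  colnames(m) <- paste0("s", 1:7)
  norm <- make_norm(m, times = c(-15, -10, -5, 5, 10, 40, 80))
  fc <- apply_filters(norm)
  expect_identical(as.character(fc$filter_status[c("g_silent", "g_low",
                                                   "lacI", "g_na", "g_ok")]),
                   c("removed_filter_i", "removed_filter_ii",
                     "excluded_ambiguous", "removed_filter_iii", "kept"))
  expect_identical(sum(table(fc$filter_status)), 5L)
})

test_that("steady-detectability helper counts replicates with signal", {
  m <- rbind(g_all = c(1, 2, 3, 0), g_two = c(1, 2, 0, 0),
             g_one = c(1, 0, 0, 9), g_none = c(0, 0, 0, 1))
  colnames(m) <- paste0("s", 1:4)
  norm <- make_norm(m, times = c(-15, -10, -5, 10))
  expect_identical(detectable_in_steady(norm, 2), c("g_all", "g_two"))
  expect_identical(detectable_in_steady(norm, 1),
                   c("g_all", "g_two", "g_one"))
})
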