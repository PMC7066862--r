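# Fixture builders shared across the suite. Everything is constructed in
# code; no binary or stored data.

# Hand-assembled count matrix: `chrom` is a genes x samples integer matrix
# (rownames = gene ids), `spike` likewise for plasmid features.
make_cm <- function(chrom, spike,
                    lengths_bp = NULL, spike_lengths_bp = NULL,
                    classes = NULL, times = NULL, conditions = NULL) {
  n_s <- ncol(chrom)
  if (is.null(lengths_bp)) lengths_bp <- rep(1000L, nrow(chrom))
  if (is.null(spike_lengths_bp)) spike_lengths_bp <- rep(1000L, nrow(spike))
  if (is.null(classes)) classes <- rep("mRNA", nrow(chrom))
  if (is.null(times)) times <- c(rep(-10, 1), seq_len(n_s - 1) * 10)
  if (is.null(conditions))
    conditions <- ifelse(times <= 0, "steady_state", "starvation")
  ann <- data.frame(
    gene_id = c(rownames(chrom), rownames(spike)),
    length_bp = c(lengths_bp, spike_lengths_bp),
    rna_class = c(classes, rep("spike_in_feature", nrow(spike))),
    origin = c(rep("chromosome", nrow(chrom)), rep("plasmid", nrow(spike))),
    stringsAsFactors = FALSE)
  if (is.null(colnames(chrom)))
    colnames(chrom) <- colnames(spike) <- paste0("s", seq_len(n_s))
  meta <- data.frame(sample_id = colnames(chrom), time_min = times,
                     condition = conditions, od_at_harvest = 0.5,
                     stringsAsFactors = FALSE)
  count_matrix(rbind(chrom, spike), ann, meta)
}

# A norm_matrix built directly from a value grid (unit test surface for the
# filter/fold-change/pool operations, which consume the documented fields).
make_norm <- function(values, times, conditions = NULL, method = "RPKSP",
                      classes = NULL, lengths_bp = NULL, is_outlier = FALSE) {
  if (is.null(conditions))
    conditions <- ifelse(times <= 0, "steady_state", "starvation")
  if (is.null(classes)) classes <- rep("mRNA", nrow(values))
  if (is.null(lengths_bp)) lengths_bp <- rep(1000L, nrow(values))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  ann <- data.frame(gene_id = rownames(values), length_bp = lengths_bp,
                    rna_class = classes, origin = "chromosome",
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = colnames(values), time_min = times,
                     condition = conditions, od_at_harvest = 0.5,
                     is_outlier = is_outlier, stringsAsFactors = FALSE)
  structure(list(method = method, values = values, annotation = ann,
                 meta = meta), class = "norm_matrix")
}

# Scaled-down generator configuration for fast tests (same structure as the
# default study configuration, ~360 genes).
small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_mrna = 300, n_silent = 10, n_low = 20, n_trna = 12,
         n_srna = 5, n_other_nc = 2, rrna_copies = 2,
         read_depth_range = c(2e4, 5e4), seed = seed),
    list(...), keep.null = TRUE)
  do.call(synth_config, args)
}

flat_curve <- c(`5` = 1, `10` = 1, `20` = 1, `40` = 1, `80` = 1)

# Expected-value (noise-free) profile matrix from a simulation's ground
# truth, for the genes and samples of a given profile_matrix.
truth_profiles <- function(sim, profiles) {
  tg <- sim$truth$genes
  meta <- attr(profiles, "meta")
  sv <- meta$condition == "starvation"
  E <- cbind(matrix(1, nrow(tg), sum(!sv)),
             as.matrix(tg[, paste0("rel_", meta$time_min[sv]), drop = FALSE]))
  rownames(E) <- tg$gene_id
  E <- E[rownames(profiles), , drop = FALSE]
  colnames(E) <- meta$sample_id
  E / rowMeans(E)
}

# First principal axis of a set of expected centered profiles: the planted
# archetype direction in profile space (independent of run_pca).
archetype_axis <- function(expected_profiles, ids) {
  ec <- scale(expected_profiles, center = TRUE, scale = FALSE)
  sub <- ec[intersect(rownames(ec), ids), , drop = FALSE]
  svd(sub)$v[, 1]
}

orthogonalize <- function(v, against) {
  a <- against / sqrt(sum(against^2))
  o <- v - sum(v * a) * a
  o / sqrt(sum(o^2))
}
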