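#' Configuration for the synthetic spike-in RNA-seq experiment
#'
#' Defaults describe a bacterial amino-acid-starvation time course measured
#' with whole-cell spike-in RNA-seq: ~4,000 chromosomal genes dominated by
#' rRNA (89% of steady-state reads), three plasmid spike-in features at a
#' constant dose per OD unit, three steady-state replicates plus five
#' starvation time points (5, 10, 20, 40, 80 min), an rRNA pool decaying to
#' 70% of the pre-starvation level by 80 min, a total-mRNA pool at 70% by
#' 10 min and 50% by 80 min, a rapidly vanishing tRNA read signal (capture
#' of mature tRNA is poor, so reads track the small hypomodified fraction),
#' per-gene regulation drawn on two temporal archetypes (sustained step vs
#' 5-min spike-and-recover), variable sequencing depth, and a mid-series
#' sampling outlier at 20 min.
#'
#' @param n_mrna well-expressed protein-coding genes (besides `lacI`).
#' @param n_silent genes with zero expression in all samples.
#' @param n_low genes expressed too weakly for fold-change analysis.
#' @param n_trna,n_srna,n_other_nc noncoding gene counts.
#' @param rrna_copies rRNA operon copies (each contributes one 16S, 23S
#'   and 5S gene).
#' @param rrna_lengths lengths (bp) of the three rRNA species.
#' @param spike_features data.frame `gene_id`, `length_bp`, `weight`
#'   (relative expression among the plasmid features).
#' @param read_depth_range min/max reads per sample (drawn uniformly).
#' @param rrna_read_fraction_steady,trna_read_fraction_steady,srna_read_fraction_steady,other_read_fraction_steady,spike_read_fraction_steady
#'   steady-state read composition; the mRNA share is the remainder.
#' @param steady_times,starvation_times sampling times in minutes
#'   (steady-state times are non-positive).
#' @param rrna_retention_curve,mrna_pool_curve,trna_curve named per-time
#'   fractions of the pre-starvation pool remaining (names = starvation
#'   times).
#' @param fraction_up,fraction_down fractions of the well-expressed mRNA
#'   genes regulated up/down.
#' @param fc_meanlog,fc_sdlog lognormal parameters of the per-gene
#'   |log2 fold change| amplitude.
#' @param profile_mixture probabilities of the `step` and `spike` temporal
#'   archetypes among regulated genes.
#' @param spike_archetype named activation profile of the spike-and-recover
#'   archetype over the starvation times (step archetype is 1 throughout).
#' @param outlier_injection `NULL`, or list with `sample_id` and
#'   `deflation`: the chromosomal read share of that sample is deflated by
#'   the given fraction, emulating a sampling error that inflates the
#'   spike-in read ratio.
#' @param baseline_sdlog lognormal spread of mRNA baseline expression.
#' @param length_meanlog,length_sdlog lognormal parameters of mRNA gene
#'   length (bp).
#' @param dirichlet_concentration optional over-dispersion: per-sample gene
#'   proportions are drawn from a Dirichlet with this concentration before
#'   the multinomial read draw (`NULL` = pure multinomial).
#' @param trna_capture optional per-class capture probability applied to
#'   the tRNA read share (models reverse-transcription bias; `NULL` = the
#'   configured read fraction is used as-is).
#' @param seed integer seed; all randomness derives from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_mrna = 3919,
                         n_silent = 50,
                         n_low = 112,
                         n_trna = 86,
                         n_srna = 20,
                         n_other_nc = 2,
                         rrna_copies = 7,
                         rrna_lengths = c(rRNA_16S = 1542, rRNA_23S = 2904,
                                          rRNA_5S = 120),
                         spike_features = data.frame(
                           gene_id = c("qrr2", "bla", "anti_lacI"),
                           length_bp = c(110, 861, 1083),
                           weight = c(0.6, 0.3, 0.1),
                           stringsAsFactors = FALSE),
                         read_depth_range = c(1e5, 1e6),
                         rrna_read_fraction_steady = 0.89,
                         trna_read_fraction_steady = 0.005,
                         srna_read_fraction_steady = 0.008,
                         other_read_fraction_steady = 0.002,
                         spike_read_fraction_steady = 0.01,
                         steady_times = c(-15, -10, -5),
                         starvation_times = c(5, 10, 20, 40, 80),
                         rrna_retention_curve = c(`5` = 0.97, `10` = 0.94,
                                                  `20` = 0.88, `40` = 0.80,
                                                  `80` = 0.70),
                         mrna_pool_curve = c(`5` = 0.85, `10` = 0.70,
                                             `20` = 0.63, `40` = 0.57,
                                             `80` = 0.50),
                         trna_curve = c(`5` = 0.35, `10` = 0.25, `20` = 0.18,
                                        `40` = 0.12, `80` = 0.08),
                         fraction_up = 0.25,
                         fraction_down = 0.59,
                         fc_meanlog = 0.3,
                         fc_sdlog = 0.6,
                         profile_mixture = c(step = 0.8, spike = 0.2),
                         spike_archetype = c(`5` = 1, `10` = 0.4, `20` = 0.2,
                                             `40` = 0.1, `80` = 0),
                         outlier_injection = list(sample_id = "t20",
                                                  deflation = 0.3),
                         baseline_sdlog = 1.5,
                         length_meanlog = log(900),
                         length_sdlog = 0.45,
                         dirichlet_concentration = NULL,
                         trna_capture = NULL,
                         seed = 1L) {
  cfg <- as.list(environment())
  validate_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_config <- function(cfg) {
  fr <- c(cfg$rrna_read_fraction_steady, cfg$trna_read_fraction_steady,
          cfg$srna_read_fraction_steady, cfg$other_read_fraction_steady,
          cfg$spike_read_fraction_steady)
  if (any(fr < 0) || any(fr > 1) || sum(fr) >= 1)
    stop("read fractions must lie in [0,1] and leave room for mRNA")
  for (nm in c("rrna_retention_curve", "mrna_pool_curve", "trna_curve")) {
    curve <- cfg[[nm]]
    if (!identical(sort(as.numeric(names(curve))), sort(cfg$starvation_times)))
      stop(nm, " must be named by the starvation times")
    if (any(curve <= 0) || any(curve > 1.5))
      stop(nm, " values must be positive pool fractions")
  }
  if (cfg$fraction_up + cfg$fraction_down > 1)
    stop("fraction_up + fraction_down must not exceed 1")
  if (abs(sum(cfg$profile_mixture) - 1) > 1e-8 ||
      !all(c("step", "spike") %in% names(cfg$profile_mixture)))
    stop("profile_mixture must be probabilities named step, spike")
  n_genes <- cfg$n_mrna + cfg$n_silent + cfg$n_low + 1 + cfg$n_trna +
    cfg$n_srna + cfg$n_other_nc + 3 * cfg$rrna_copies +
    nrow(cfg$spike_features)
  if (cfg$read_depth_range[1] < 10 * n_genes)
    stop("minimum read depth must be at least 10x the gene count (",
         10 * n_genes, ")")
  if (any(cfg$steady_times > 0)) stop("steady_times must be <= 0")
  if (is.unsorted(cfg$starvation_times, strictly = TRUE))
    stop("starvation_times must be strictly increasing")
  invisible(cfg)
}

# normalized lognormal weights summing to `total`
lnorm_weights <- function(n, sdlog, total) {
  if (n == 0 || total == 0) return(rep(0, n))
  w <- stats::rlnorm(n, 0, sdlog)
  w / sum(w) * total
}

#' Simulate a whole-cell spike-in RNA-seq experiment
#'
#' Generates a raw count matrix, gene annotation and sample metadata with
#' the statistical structure described by the [synth_config()], together
#' with the full ground truth. Expected per-gene abundance (per OD unit of
#' culture) at each time is baseline expression x class pool curve x
#' gene-specific regulation; the mRNA class is rescaled so its summed
#' expected abundance follows the programmed mRNA pool curve exactly.
#' Spike-in features keep a constant expected abundance per OD. Reads are
#' drawn multinomially over genes with probabilities proportional to
#' expected abundance, at a per-sample depth drawn uniformly from the
#' configured range, so column sums equal the drawn depths exactly and the
#' spike-in read share grows as cellular RNA declines.
#'
#' @param config a [synth_config()].
#' @return A `spikeseq_sim`: list with `counts` (a [count_matrix()]),
#'   `truth` (`genes` and `samples` data.frames), and `config`.
#' @export
simulate_experiment <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  validate_config(config)
  set.seed(config$seed)
  cfg <- config

  ## ---- annotation ----------------------------------------------------
  n_m_all <- cfg$n_mrna + cfg$n_silent + cfg$n_low
  mrna_ids <- sprintf("mRNA_%04d", seq_len(n_m_all))
  rrna <- do.call(rbind, lapply(names(cfg$rrna_lengths), function(sp) {
    data.frame(gene_id = sprintf("%s_copy%d", sub("rRNA_", "rr", sp),
                                 seq_len(cfg$rrna_copies)),
               length_bp = unname(cfg$rrna_lengths[sp]),
               rna_class = sp, stringsAsFactors = FALSE)
  }))
  ann <- rbind(
    data.frame(gene_id = mrna_ids,
               length_bp = pmax(60, round(stats::rlnorm(
                 n_m_all, cfg$length_meanlog, cfg$length_sdlog))),
               rna_class = "mRNA", stringsAsFactors = FALSE),
    data.frame(gene_id = "lacI", length_bp = 1083, rna_class = "mRNA",
               stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("tRNA_%02d", seq_len(cfg$n_trna)),
               length_bp = sample(76:90, cfg$n_trna, replace = TRUE),
               rna_class = "tRNA", stringsAsFactors = FALSE),
    rrna,
    data.frame(gene_id = sprintf("sRNA_%02d", seq_len(cfg$n_srna)),
               length_bp = sample(60:300, cfg$n_srna, replace = TRUE),
               rna_class = "sRNA", stringsAsFactors = FALSE),
    data.frame(gene_id = sprintf("ncRNA_%02d", seq_len(cfg$n_other_nc)),
               length_bp = sample(150:400, cfg$n_other_nc, replace = TRUE),
               rna_class = "other_ncRNA", stringsAsFactors = FALSE))
  ann$origin <- "chromosome"
  spike <- data.frame(gene_id = cfg$spike_features$gene_id,
                      length_bp = cfg$spike_features$length_bp,
                      rna_class = "spike_in_feature", origin = "plasmid",
                      stringsAsFactors = FALSE)
  ann <- rbind(ann, spike)

  ## ---- baseline weights (steady-state expected read fractions) -------
  mrna_frac <- 1 - cfg$rrna_read_fraction_steady -
    cfg$trna_read_fraction_steady - cfg$srna_read_fraction_steady -
    cfg$other_read_fraction_steady - cfg$spike_read_fraction_steady
  trna_frac <- cfg$trna_read_fraction_steady
  if (!is.null(cfg$trna_capture)) trna_frac <- trna_frac * cfg$trna_capture
  w <- stats::setNames(numeric(nrow(ann)), ann$gene_id)

  # low genes get absolute weights small enough that their expected
  # normalized signal stays below the filter-ii threshold
  is_low <- seq(cfg$n_mrna + cfg$n_silent + 1, n_m_all)
  is_silent <- seq(cfg$n_mrna + 1, cfg$n_mrna + cfg$n_silent)
  w_low <- stats::runif(cfg$n_low, 1e-7, 4e-7)
  reg_ids <- mrna_ids[seq_len(cfg$n_mrna)]
  w[reg_ids] <- lnorm_weights(cfg$n_mrna, cfg$baseline_sdlog,
                              mrna_frac * 0.98 - sum(w_low))
  w["lacI"] <- mrna_frac * 0.02
  w[mrna_ids[is_low]] <- w_low
  w[mrna_ids[is_silent]] <- 0
  sp_len <- cfg$rrna_lengths / sum(cfg$rrna_lengths)
  for (sp in names(cfg$rrna_lengths)) {
    ids <- ann$gene_id[ann$rna_class == sp]
    w[ids] <- cfg$rrna_read_fraction_steady * sp_len[[sp]] / length(ids)
  }
  w[ann$gene_id[ann$rna_class == "tRNA"]] <-
    lnorm_weights(cfg$n_trna, 0.3, trna_frac)
  w[ann$gene_id[ann$rna_class == "sRNA"]] <-
    lnorm_weights(cfg$n_srna, 0.8, cfg$srna_read_fraction_steady)
  w[ann$gene_id[ann$rna_class == "other_ncRNA"]] <-
    lnorm_weights(cfg$n_other_nc, 0.3, cfg$other_read_fraction_steady)
  w[spike$gene_id] <- cfg$spike_read_fraction_steady *
    cfg$spike_features$weight / sum(cfg$spike_features$weight)

  ## ---- per-gene regulation ------------------------------------------
  n_up <- round(cfg$fraction_up * cfg$n_mrna)
  n_down <- round(cfg$fraction_down * cfg$n_mrna)
  reg_pick <- sample(reg_ids, n_up + n_down)
  direction <- stats::setNames(rep("none", nrow(ann)), ann$gene_id)
  direction[reg_pick[seq_len(n_up)]] <- "up"
  direction[reg_pick[n_up + seq_len(n_down)]] <- "down"
  archetype <- stats::setNames(rep(NA_character_, nrow(ann)), ann$gene_id)
  archetype[reg_pick] <- sample(names(cfg$profile_mixture),
                                length(reg_pick), replace = TRUE,
                                prob = cfg$profile_mixture)
  amplitude <- stats::setNames(rep(0, nrow(ann)), ann$gene_id)
  amplitude[reg_pick] <- stats::rlnorm(length(reg_pick), cfg$fc_meanlog,
                                       cfg$fc_sdlog)

  ## ---- expected relative abundance per starvation time ---------------
  tp <- cfg$starvation_times
  tpc <- as.character(tp)
  rel <- matrix(1, nrow(ann), length(tp),
                dimnames = list(ann$gene_id, tpc))
  pi_step <- stats::setNames(rep(1, length(tp)), tpc)
  pi_spike <- cfg$spike_archetype[tpc]
  for (g in reg_pick) {
    prof <- if (archetype[g] == "step") pi_step else pi_spike
    s <- if (direction[g] == "up") 1 else -1
    rel[g, ] <- 2^(s * amplitude[g] * prof)
  }
  mcls <- ann$rna_class == "mRNA"
  for (j in seq_along(tp)) {
    raw_pool <- sum(w[mcls] * rel[mcls, j])
    scale_j <- cfg$mrna_pool_curve[tpc[j]] * sum(w[mcls]) / raw_pool
    rel[mcls, j] <- rel[mcls, j] * scale_j
  }
  for (sp in c("rRNA_16S", "rRNA_23S", "rRNA_5S"))
    rel[ann$rna_class == sp, ] <-
      rep(cfg$rrna_retention_curve[tpc], each = sum(ann$rna_class == sp))
  rel[ann$rna_class == "tRNA", ] <-
    rep(cfg$trna_curve[tpc], each = cfg$n_trna)
  # sRNA / other ncRNA pools held flat; spike-in constant per OD

  ## ---- samples and counts -------------------------------------------
  meta <- data.frame(
    sample_id = c(sprintf("ss%d", seq_along(cfg$steady_times)),
                  sprintf("t%02d", tp)),
    time_min = c(cfg$steady_times, tp),
    condition = rep(c("steady_state", "starvation"),
                    c(length(cfg$steady_times), length(tp))),
    od_at_harvest = c(0.45 + 0.025 * seq_along(cfg$steady_times),
                      rep(0.54, length(tp))),
    is_outlier = FALSE, stringsAsFactors = FALSE)

  u <- cbind(matrix(w, nrow(ann), length(cfg$steady_times),
                    dimnames = list(ann$gene_id, NULL)),
             w * rel)
  colnames(u) <- meta$sample_id
  chrom <- ann$origin == "chromosome"
  if (!is.null(cfg$outlier_injection)) {
    oid <- cfg$outlier_injection$sample_id
    if (!oid %in% meta$sample_id)
      stop("outlier_injection sample_id not in sample set: ", oid)
    u[chrom, oid] <- u[chrom, oid] * (1 - cfg$outlier_injection$deflation)
  }
  depths <- round(stats::runif(nrow(meta), cfg$read_depth_range[1],
                               cfg$read_depth_range[2]))
  counts <- draw_counts(u, depths, cfg$dirichlet_concentration)

  truth_genes <- data.frame(
    gene_id = ann$gene_id, rna_class = ann$rna_class,
    category = ifelse(ann$gene_id %in% mrna_ids[is_silent], "silent",
               ifelse(ann$gene_id %in% mrna_ids[is_low], "low", "regular")),
    regulated = unname(direction), archetype = unname(archetype),
    amplitude_log2 = unname(amplitude),
    baseline_weight = unname(w), stringsAsFactors = FALSE)
  for (j in seq_along(tp)) {
    truth_genes[[paste0("rel_", tp[j])]] <- unname(rel[, j])
    truth_genes[[paste0("log2fc_", tp[j])]] <- unname(log2(rel[, j]))
  }
  truth_samples <- data.frame(
    sample_id = meta$sample_id, depth = depths,
    total_scale = colSums(u[chrom, , drop = FALSE]) / sum(w[chrom]),
    stringsAsFactors = FALSE)

  structure(list(counts = count_matrix(counts, ann, meta),
                 truth = list(genes = truth_genes, samples = truth_samples),
                 config = cfg),
            class = "spikeseq_sim")
}

draw_counts <- function(u, depths, dirichlet_concentration) {
  counts <- matrix(0, nrow(u), ncol(u), dimnames = dimnames(u))
  for (j in seq_len(ncol(u))) {
    p <- u[, j] / sum(u[, j])
    if (!is.null(dirichlet_concentration)) {
      g <- stats::rgamma(length(p), shape = p * dirichlet_concentration)
      if (sum(g) > 0) p <- g / sum(g)
    }
    counts[, j] <- stats::rmultinom(1, depths[j], p)
  }
  counts
}

#' Append a rifampicin-treatment tail to a simulated experiment
#'
#' Rifampicin blocks transcription initiation, so RNA classes that depend
#' on new synthesis decay further after the last starvation sample, while
#' the rRNA pool stays near its 80-min level. Default tail curves: the
#' tRNA read signal decays geometrically from its last starvation value to
#' `trna_tail_end` (0.02 of pre-starvation) at the final tail point; mRNA
#' decays with a 5-min half-life; sRNA with a 30-min half-life; rRNA is
#' held at its last starvation value; the spike-in stays constant per OD.
#'
#' @param sim a `spikeseq_sim` from [simulate_experiment()].
#' @param tail_times sampling times in minutes; all must fall after the
#'   last starvation time. Defaults to 10, 15, 25 and 45 min after an
#'   80-min starvation series.
#' @param trna_tail_end programmed tRNA signal at the final tail point,
#'   as a fraction of the pre-starvation level.
#' @param mrna_halflife_min,srna_halflife_min decay half-lives (minutes).
#' @return The `spikeseq_sim` with tail samples appended to counts, meta
#'   and ground truth.
#' @export
simulate_rifampicin_tail <- function(sim, tail_times = c(90, 95, 105, 125),
                                     trna_tail_end = 0.02,
                                     mrna_halflife_min = 5,
                                     srna_halflife_min = 30) {
  stopifnot(inherits(sim, "spikeseq_sim"))
  cfg <- sim$config
  t_last <- max(cfg$starvation_times)
  if (any(tail_times <= t_last))
    stop("tail times must all fall after the last starvation time (",
         t_last, " min)")
  if (is.unsorted(tail_times, strictly = TRUE))
    stop("tail_times must be strictly increasing")
  set.seed(cfg$seed + 1000003L)
  ann <- sim$counts$annotation
  w <- baseline_weights_from_truth(sim)
  tpc_last <- as.character(t_last)
  rel_last <- as.matrix(sim$truth$genes[, paste0("rel_", cfg$starvation_times),
                                        drop = FALSE])
  rownames(rel_last) <- sim$truth$genes$gene_id
  rel80 <- rel_last[, ncol(rel_last)]

  dt <- tail_times - t_last
  dt_max <- max(dt)
  trna_start <- cfg$trna_curve[tpc_last]
  rel_tail <- matrix(1, nrow(ann), length(tail_times),
                     dimnames = list(ann$gene_id, as.character(tail_times)))
  cls <- ann$rna_class
  for (j in seq_along(dt)) {
    rel_tail[cls %in% c("rRNA_16S", "rRNA_23S", "rRNA_5S"), j] <-
      rel80[cls %in% c("rRNA_16S", "rRNA_23S", "rRNA_5S")]
    rel_tail[cls == "tRNA", j] <-
      exp(log(trna_start) + (log(trna_tail_end) - log(trna_start)) *
            dt[j] / dt_max)
    rel_tail[cls == "mRNA", j] <-
      rel80[cls == "mRNA"] * 2^(-dt[j] / mrna_halflife_min)
    rel_tail[cls == "sRNA", j] <- 2^(-dt[j] / srna_halflife_min)
    rel_tail[cls == "other_ncRNA", j] <- 2^(-dt[j] / srna_halflife_min)
  }

  u <- w * rel_tail
  depths <- round(stats::runif(length(tail_times), cfg$read_depth_range[1],
                               cfg$read_depth_range[2]))
  new_counts <- draw_counts(u, depths, cfg$dirichlet_concentration)
  colnames(new_counts) <- sprintf("rif%02d", dt)

  meta <- rbind(sim$counts$meta,
                data.frame(sample_id = colnames(new_counts),
                           time_min = tail_times, condition = "rifampicin",
                           od_at_harvest = 0.54, is_outlier = FALSE,
                           stringsAsFactors = FALSE))
  counts <- cbind(sim$counts$counts, new_counts)
  sim$counts <- count_matrix(counts, ann, meta)
  for (j in seq_along(tail_times)) {
    sim$truth$genes[[paste0("rel_rif_", tail_times[j])]] <- rel_tail[, j]
    sim$truth$genes[[paste0("log2fc_rif_", tail_times[j])]] <-
      log2(rel_tail[, j])
  }
  chrom <- ann$origin == "chromosome"
  sim$truth$samples <- rbind(
    sim$truth$samples,
    data.frame(sample_id = colnames(new_counts), depth = depths,
               total_scale = colSums(u[chrom, , drop = FALSE]) /
                 sum(w[chrom]), stringsAsFactors = FALSE))
  sim
}

# steady-state expected abundance weights, recorded in the ground truth
baseline_weights_from_truth <- function(sim) {
  stats::setNames(sim$truth$genes$baseline_weight, sim$truth$genes$gene_id)
}

#' Write a simulated experiment to fixture files
#'
#' Writes the counts/annotation/metadata TSVs (readable by
#' [read_counts()]) plus two ground-truth TSVs.
#'
#' @param dir_path output directory (created if needed).
#' @param sim a `spikeseq_sim`.
#' @return Named character vector of the file paths, invisibly.
#' @export
write_fixture <- function(dir_path, sim) {
  stopifnot(inherits(sim, "spikeseq_sim"))
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir_path, "counts.tsv"),
             annotation = file.path(dir_path, "annotation.tsv"),
             meta = file.path(dir_path, "samples.tsv"),
             truth_genes = file.path(dir_path, "truth_genes.tsv"),
             truth_samples = file.path(dir_path, "truth_samples.tsv"))
  write_counts(sim$counts, paths["counts"], paths["annotation"],
               paths["meta"])
  write_tsv(sim$truth$genes, paths["truth_genes"])
  write_tsv(sim$truth$samples, paths["truth_samples"])
  invisible(paths)
}

#' @export
print.spikeseq_sim <- function(x, ...) {
  cat("spikeseq_sim (seed ", x$config$seed, ")\n", sep = "")
  print(x$counts)
  invisible(x)
}
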