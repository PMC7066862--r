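#' Default pipeline configuration
#'
#' @param counts_path,annotation_path,meta_path input TSV paths (see
#'   [read_counts()]).
#' @param out_dir output directory for stage tables.
#' @param methods normalization methods to run (`"RPKSP"`, `"RPKM"`).
#' @param low_threshold filter-ii cutoff (normalized read units).
#' @param ambiguous_ids gene ids excluded for ambiguous read assignment.
#' @param fc_threshold fold-change classification cutoff.
#' @param fc_timepoints starvation times (minutes) for fold-change
#'   classification and for filter iii.
#' @param outlier_cutoff QC trend-deviation cutoff for outlier flagging.
#' @param pca_fraction tail fraction for extreme-score gene subsets.
#' @param pool_classes RNA classes profiled as pools (the total-mRNA pool
#'   is always added).
#' @return A `run_config` list.
#' @export
run_config <- function(counts_path, annotation_path, meta_path,
                       out_dir = NULL,
                       methods = c("RPKSP", "RPKM"),
                       low_threshold = 1,
                       ambiguous_ids = "lacI",
                       fc_threshold = 2,
                       fc_timepoints = c(10, 80),
                       outlier_cutoff = 0.2,
                       pca_fraction = 0.1,
                       pool_classes = list("rRNA_16S", "rRNA_23S", "rRNA_5S",
                                           "tRNA")) {
  stopifnot(fc_threshold > 1, outlier_cutoff >= 0, low_threshold >= 0,
            pca_fraction > 0, pca_fraction <= 0.5,
            all(methods %in% c("RPKSP", "RPKM")))
  structure(as.list(environment()), class = "run_config")
}

#' Run the full spike-in analysis workflow
#'
#' Composes the stages in their natural order: read and validate the
#' inputs, spike-in read-ratio QC with outlier flagging, RPKSP/RPKM
#' normalization, the filter cascade, fold-change classification at the
#' configured time points, RNA-class pool profiles, and temporal-profile
#' PCA. Deterministic given inputs and configuration. When `out_dir` is
#' set, every stage table is written as TSV together with a `summary.tsv`
#' of key quantities and the serialized configuration (`config.yaml`).
#'
#' @param config a [run_config()], or the path to a YAML file holding its
#'   fields.
#' @return A list with elements `qc`, `norm` (per method), `fc` (per
#'   method), `regulation`, `pools`, `pca`, `summary`, invisibly when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    fields <- yaml::read_yaml(config)
    config <- do.call(run_config, fields)
  }
  stopifnot(inherits(config, "run_config"))
  x <- read_counts(config$counts_path, config$annotation_path,
                   config$meta_path)

  qc <- flag_outliers(spikein_fraction_qc(x), config$outlier_cutoff)
  flagged <- attr(qc, "flagged")
  if (length(flagged)) x <- mark_outliers(x, flagged)

  norms <- list()
  if ("RPKSP" %in% config$methods) norms$RPKSP <- normalize_rpksp(x)
  if ("RPKM" %in% config$methods) norms$RPKM <- normalize_rpkm(x)

  fcs <- lapply(norms, function(nm)
    apply_filters(nm, low_threshold = config$low_threshold,
                  ambiguous_ids = config$ambiguous_ids,
                  fc_timepoints = config$fc_timepoints))
  regulation <- do.call(rbind, unlist(lapply(fcs, function(fc)
    lapply(config$fc_timepoints, function(tmin)
      classify_regulation(fc, tmin, config$fc_threshold))),
    recursive = FALSE))
  rownames(regulation) <- NULL

  ref_fc <- fcs[[1]]
  kept <- names(ref_fc$filter_status)[ref_fc$filter_status == "kept"]
  pools <- list()
  for (nm in names(norms)) {
    norm <- norms[[nm]]
    norm$filter_status <- ref_fc$filter_status
    cls_pools <- lapply(config$pool_classes, function(cl)
      pool_profile(norm, classes = cl))
    mset <- mrna_gene_set(x$annotation, kept)
    pool_tab <- rbind(do.call(rbind, cls_pools),
                      pool_profile(norm, genes = mset, label = "mRNA"))
    pool_tab$method <- nm
    pools[[nm]] <- pool_tab
  }
  pools <- do.call(rbind, pools)
  rownames(pools) <- NULL

  pca_norm <- norms[[1]]
  pca_norm$filter_status <- ref_fc$filter_status
  profiles <- suppressMessages(profile_normalize(pca_norm))
  pca <- run_pca(profiles)
  extremes <- list(
    pc1 = select_extremes(pca, 1, config$pca_fraction),
    pc2 = select_extremes(pca, 2, config$pca_fraction))

  summary <- build_summary(regulation, pools, pca, qc,
                           ref_fc$filter_status)
  res <- list(qc = qc, norm = norms, fc = fcs, regulation = regulation,
              pools = pools, pca = pca, extremes = extremes,
              summary = summary, config = config)
  if (!is.null(config$out_dir)) {
    write_pipeline_output(res, config)
    return(invisible(res))
  }
  res
}

build_summary <- function(regulation, pools, pca, qc, filter_status) {
  stat <- table(filter_status)
  rows <- data.frame(key = character(0), value = numeric(0))
  add <- function(rows, key, value)
    rbind(rows, data.frame(key = key, value = as.numeric(value)))
  for (lv in names(stat)) rows <- add(rows, paste0("n_", lv), stat[[lv]])
  for (i in seq_len(nrow(regulation))) {
    r <- regulation[i, ]
    for (f in c("n_up", "n_down", "n_unchanged", "n_na"))
      rows <- add(rows, sprintf("%s_%s_t%g", f, r$method, r$time_min), r[[f]])
  }
  ends <- pools[pools$condition == "starvation" & !pools$is_outlier, ]
  last_t <- max(ends$time_min)
  for (i in which(ends$time_min == last_t))
    rows <- add(rows, sprintf("pool_%s_%s_t%g_relative", ends$label[i],
                              ends$method[i], last_t), ends$relative[i])
  ef <- pca$explained_fraction
  for (j in seq_len(min(3, length(ef))))
    rows <- add(rows, sprintf("pca_pc%d_explained", j), ef[j])
  rows <- add(rows, "n_qc_outliers", sum(qc$is_outlier))
  rows
}

write_pipeline_output <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  qc_df <- as.data.frame(res$qc)
  write_tsv(qc_df, out("qc_spikein_ratio.tsv"))
  for (nm in names(res$norm)) {
    v <- res$norm[[nm]]$values
    write_tsv(data.frame(gene_id = rownames(v), v, check.names = FALSE),
              out(sprintf("normalized_%s.tsv", tolower(nm))))
  }
  for (nm in names(res$fc)) {
    fc <- res$fc[[nm]]
    tab <- data.frame(gene_id = rownames(fc$log2_fc),
                      filter_status = as.character(fc$filter_status),
                      steady_mean = fc$steady_mean, fc$log2_fc,
                      check.names = FALSE)
    names(tab)[-(1:3)] <- paste0("log2fc_", fc$meta$sample_id)
    write_tsv(tab, out(sprintf("fold_changes_%s.tsv", tolower(nm))))
  }
  write_tsv(res$regulation, out("regulation_summary.tsv"))
  write_tsv(res$pools, out("pool_profiles.tsv"))
  write_tsv(data.frame(component = seq_along(res$pca$explained_fraction),
                       explained_fraction = res$pca$explained_fraction,
                       steady_spread = res$pca$steady_spread),
            out("pca_explained.tsv"))
  write_tsv(data.frame(gene_id = rownames(res$pca$scores), res$pca$scores,
                       check.names = FALSE), out("pca_scores.tsv"))
  write_tsv(data.frame(sample_id = res$pca$meta$sample_id,
                       time_min = res$pca$meta$time_min, res$pca$vectors,
                       check.names = FALSE), out("pca_vectors.tsv"))
  write_tsv(res$summary, out("summary.tsv"))
  cfg <- res$config
  cfg_list <- unclass(cfg)
  yaml::write_yaml(cfg_list, out("config.yaml"))
  invisible(res)
}
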