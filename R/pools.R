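#' Class-level RNA pool profile
#'
#' Sums normalized values over the member genes of an RNA class (or an
#' explicit gene list) per sample, and expresses the series relative to the
#' mean of the steady-state samples -- the "fraction of the pre-starvation
#' pool remaining" view. Under RPKSP this tracks the absolute per-cell-mass
#' pool; under RPKM it tracks only the pool's share of total reads.
#'
#' @param norm a `norm_matrix`.
#' @param classes character vector of `rna_class` labels to pool (e.g.
#'   `c("rRNA_16S", "rRNA_23S")`); ignored when `genes` is given.
#' @param genes explicit gene ids to pool (e.g. from [mrna_gene_set()]).
#' @param use_filter restrict to genes whose `filter_status` is `kept`
#'   (when a filter status is present on `norm`).
#' @param label optional class label for the output.
#' @return data.frame with `label`, `sample_id`, `time_min`, `condition`,
#'   `is_outlier`, `pooled`, `relative`.
#' @export
pool_profile <- function(norm, classes = NULL, genes = NULL,
                         use_filter = TRUE, label = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (is.null(genes)) {
    if (is.null(classes)) stop("give either classes or genes")
    genes <- norm$annotation$gene_id[norm$annotation$rna_class %in% classes]
    if (is.null(label)) label <- paste(classes, collapse = "+")
  } else if (is.null(label)) label <- "custom"
  if (use_filter && !is.null(norm$filter_status))
    genes <- intersect(genes, kept_genes(norm))
  if (!length(genes)) stop("empty member gene set for pool '", label, "'")
  pooled <- colSums(norm$values[genes, , drop = FALSE])
  ss <- norm$meta$condition == "steady_state"
  if (!any(ss)) stop("no steady-state samples to anchor the relative pool")
  ref <- mean(pooled[ss])
  if (ref == 0) stop("steady-state pool is zero for '", label, "'")
  data.frame(label = label, sample_id = norm$meta$sample_id,
             time_min = norm$meta$time_min, condition = norm$meta$condition,
             is_outlier = norm$meta$is_outlier,
             pooled = as.numeric(pooled), relative = as.numeric(pooled / ref),
             stringsAsFactors = FALSE)
}

#' The mRNA gene set
#'
#' Kept genes minus all noncoding classes (rRNA species, tRNA, sRNA and
#' other ncRNA such as the RNA component of RNase P).
#'
#' @param annotation gene annotation data.frame.
#' @param kept_genes gene ids surviving filtering (default: all chromosomal
#'   genes in the annotation).
#' @return Character vector of mRNA gene ids.
#' @export
mrna_gene_set <- function(annotation, kept_genes = NULL) {
  annotation <- validate_annotation(annotation)
  if (is.null(kept_genes))
    kept_genes <- annotation$gene_id[annotation$origin == "chromosome"]
  nc <- annotation$gene_id[annotation$rna_class %in% NONCODING_CLASSES |
                             annotation$origin == "plasmid"]
  setdiff(kept_genes, nc)
}

#' Spike-in read-fraction quality control
#'
#' Computes, per sample, the ratio of plasmid (spike-in) reads to total
#' reads. Because the spike-in dose is constant per OD unit while cellular
#' RNA declines during starvation, this ratio should rise smoothly along
#' the time series; a sample that departs from the smooth trend indicates
#' erroneous sampling. The deviation of each sample is measured against a
#' leave-one-out linear interpolation of `log(ratio)` over time (steady
#' replicates are compared with the mean of the other replicates).
#'
#' @param x a [count_matrix()] with plasmid features.
#' @return A `qc_ratio` data.frame with `sample_id`, `time_min`,
#'   `condition`, `plasmid_reads`, `total_reads`, `ratio`,
#'   `deviation_from_trend`, `is_outlier` (all `FALSE`; see
#'   [flag_outliers()]).
#' @export
spikein_fraction_qc <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  plasmid <- x$annotation$gene_id[x$annotation$origin == "plasmid"]
  if (!length(plasmid)) stop("no plasmid spike-in features in annotation")
  p_reads <- colSums(x$counts[plasmid, , drop = FALSE])
  total <- colSums(x$counts)
  if (any(total == 0)) stop("zero total reads in sample ",
                            colnames(x$counts)[total == 0][1])
  qc <- data.frame(sample_id = x$meta$sample_id, time_min = x$meta$time_min,
                   condition = x$meta$condition,
                   plasmid_reads = as.numeric(p_reads),
                   total_reads = as.numeric(total),
                   ratio = as.numeric(p_reads / total),
                   stringsAsFactors = FALSE)
  qc$deviation_from_trend <- qc_deviation(qc, suspects = character(0))
  qc$is_outlier <- FALSE
  class(qc) <- c("qc_ratio", "data.frame")
  qc
}

# Leave-one-out trend deviations. Steady samples: relative departure from
# the mean ratio of the other (non-suspect) steady replicates. Time-series
# samples (starvation + any later treatment): log(ratio) predicted at the
# sample's time from a least-squares line fitted to all other non-suspect
# series points plus a steady-state anchor at time 0. A global line (rather
# than neighbor interpolation) keeps one contaminated point from dominating
# the prediction for the series endpoints.
qc_deviation <- function(qc, suspects) {
  dev <- rep(NA_real_, nrow(qc))
  sus <- qc$sample_id %in% suspects
  ss <- qc$condition == "steady_state"
  for (i in which(ss)) {
    others <- ss & !sus & seq_len(nrow(qc)) != i
    if (any(others)) dev[i] <- qc$ratio[i] / mean(qc$ratio[others]) - 1
  }
  anchor_ok <- any(ss & !sus)
  idx <- which(!ss)
  for (i in idx) {
    good <- setdiff(idx[!sus[idx]], i)
    tt <- qc$time_min[good]; yy <- log(qc$ratio[good])
    if (anchor_ok) {
      tt <- c(0, tt)
      yy <- c(log(mean(qc$ratio[ss & !sus])), yy)
    }
    if (!length(tt)) next
    pred <- if (length(tt) == 1 || stats::var(tt) == 0) mean(yy) else {
      b <- stats::cov(tt, yy) / stats::var(tt)
      mean(yy) + b * (qc$time_min[i] - mean(tt))
    }
    dev[i] <- qc$ratio[i] / exp(pred) - 1
  }
  dev
}

#' Flag trend outliers in the spike-in read-ratio series
#'
#' Iteratively marks the sample with the largest absolute deviation from
#' the trend as suspect, recomputes the leave-suspects-out trend, and
#' repeats until no unflagged sample deviates more than `deviation_cutoff`.
#' Reported deviations are against the final suspect-free trend.
#'
#' @param qc a `qc_ratio` from [spikein_fraction_qc()].
#' @param deviation_cutoff relative deviation above which a sample is an
#'   outlier. Default 0.2: steady replicates typically agree to ~1%, while
#'   a mis-sampled time point departs by tens of percent. A cutoff of 0
#'   flags every sample not exactly on the trend (degenerate but allowed).
#' @return The `qc_ratio` with updated `deviation_from_trend` and
#'   `is_outlier`; the flagged sample ids are in
#'   `attr(, "flagged")`.
#' @export
flag_outliers <- function(qc, deviation_cutoff = 0.2) {
  stopifnot(inherits(qc, "qc_ratio"))
  if (!is.finite(deviation_cutoff) || deviation_cutoff < 0)
    stop("deviation_cutoff must be non-negative")
  if (nrow(qc) < 3) stop("need at least 3 samples to fit a trend")
  suspects <- character(0)
  repeat {
    dev <- qc_deviation(qc, suspects)
    cand <- which(!qc$sample_id %in% suspects & !is.na(dev) &
                    abs(dev) > deviation_cutoff)
    if (!length(cand)) break
    worst <- cand[which.max(abs(dev[cand]))]
    suspects <- c(suspects, qc$sample_id[worst])
  }
  qc$deviation_from_trend <- qc_deviation(qc, suspects)
  qc$is_outlier <- qc$sample_id %in% suspects
  attr(qc, "flagged") <- suspects
  qc
}
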