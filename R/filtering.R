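#' Initialize per-gene filter status on a normalized matrix
#'
#' Adds a `filter_status` factor (one level per gene) to the matrix. Each
#' gene is attributed to the first filter that removes it; later filters
#' only examine genes still `kept`.
#'
#' @param norm a `norm_matrix`.
#' @return `norm` with a `filter_status` element.
#' @export
init_filter_status <- function(norm) {
  stopifnot(inherits(norm, "norm_matrix"))
  norm$filter_status <- factor(rep("kept", nrow(norm$values)),
                               levels = FILTER_LEVELS)
  names(norm$filter_status) <- rownames(norm$values)
  norm
}

ensure_status <- function(norm) {
  if (is.null(norm$filter_status)) init_filter_status(norm) else norm
}

#' Filter i: remove genes never sequenced
#'
#' Genes with zero normalized signal in every sample (hence zero reads in
#' steady state and in starvation alike) are flagged `removed_filter_i`.
#'
#' @param norm a `norm_matrix`.
#' @return `norm` with updated `filter_status`.
#' @export
filter_unexpressed <- function(norm) {
  norm <- ensure_status(norm)
  hit <- rowSums(norm$values) == 0 & norm$filter_status == "kept"
  norm$filter_status[hit] <- "removed_filter_i"
  norm
}

#' Filter ii: remove genes with low coverage in both phases
#'
#' Genes whose steady-state average normalized signal is below
#' `low_threshold` (or zero) *and* whose starvation average is also below
#' it are flagged `removed_filter_ii`: such genes cannot yield a meaningful
#' fold difference between the two phases. Outlier-flagged starvation
#' samples are excluded from the starvation average.
#'
#' @param norm a `norm_matrix` (filter i normally applied first).
#' @param low_threshold non-negative cutoff in normalized read units; the
#'   default of 1 demands on average at least one normalized read-unit in
#'   at least one phase.
#' @return `norm` with updated `filter_status`.
#' @export
filter_low_coverage <- function(norm, low_threshold = 1) {
  if (!is.finite(low_threshold) || low_threshold < 0)
    stop("low_threshold must be non-negative")
  norm <- ensure_status(norm)
  ss <- norm$meta$condition == "steady_state"
  sv <- norm$meta$condition == "starvation" & !norm$meta$is_outlier
  if (!any(ss) || !any(sv))
    stop("filter ii needs steady-state and starvation samples")
  m_ss <- rowMeans(norm$values[, ss, drop = FALSE])
  m_sv <- rowMeans(norm$values[, sv, drop = FALSE])
  hit <- m_ss < low_threshold & m_sv < low_threshold &
    norm$filter_status == "kept"
  norm$filter_status[hit] <- "removed_filter_ii"
  norm
}

#' Exclude genes with ambiguous read assignment
#'
#' Genes listed in `ambiguous_ids` are flagged `excluded_ambiguous`. The
#' canonical case is a chromosomal gene that is also present on the
#' spike-in plasmid (e.g. *lacI* opposite the plasmid's antisense-*lacI*),
#' whose reads cannot be attributed to either source. Ids absent from the
#' matrix produce a warning, not an error.
#'
#' @param norm a `norm_matrix`.
#' @param ambiguous_ids character vector of gene ids.
#' @return `norm` with updated `filter_status`.
#' @export
exclude_ambiguous <- function(norm, ambiguous_ids) {
  norm <- ensure_status(norm)
  if (!length(ambiguous_ids)) return(norm)
  absent <- setdiff(ambiguous_ids, rownames(norm$values))
  if (length(absent))
    warning("ambiguous id(s) not in matrix: ", paste(absent, collapse = ", "))
  hit <- rownames(norm$values) %in% ambiguous_ids & norm$filter_status == "kept"
  norm$filter_status[hit] <- "excluded_ambiguous"
  norm
}

#' Log2 fold changes relative to the steady-state average
#'
#' For every non-steady sample, computes
#' `log2(value / mean over steady-state replicates)` per gene. The ratio
#' is only defined where both the steady mean and the sample value are
#' positive; elsewhere the entry is `NA`, meaning *not computable* (the
#' workflow handles these by filtering, never by pseudocounts).
#'
#' @param norm a `norm_matrix` with at least one steady-state sample.
#' @return An `fc_table`: list with `log2_fc` (genes x non-steady samples,
#'   `NA` = not computable), `steady_mean`, `filter_status`, `meta` (rows
#'   for the non-steady samples), `annotation`.
#' @export
log2_fold_changes <- function(norm) {
  norm <- ensure_status(norm)
  ss <- norm$meta$condition == "steady_state"
  if (!any(ss)) stop("no steady-state samples")
  steady_mean <- rowMeans(norm$values[, ss, drop = FALSE])
  other <- !ss
  v <- norm$values[, other, drop = FALSE]
  fc <- log2(sweep(v, 1, steady_mean, "/"))
  fc[v == 0 | steady_mean == 0] <- NA_real_
  structure(list(log2_fc = fc, steady_mean = steady_mean,
                 filter_status = norm$filter_status,
                 meta = norm$meta[other, , drop = FALSE],
                 annotation = norm$annotation,
                 method = norm$method),
            class = "fc_table")
}

fc_col_for_time <- function(fc, timepoint) {
  i <- which(fc$meta$time_min == timepoint & fc$meta$condition == "starvation")
  if (!length(i)) stop("no starvation sample at time ", timepoint, " min")
  i
}

#' Filter iii: remove genes with no computable fold change at key times
#'
#' Genes (still kept) whose fold change is not computable at *every* one of
#' the listed starvation time points are flagged `removed_filter_iii`.
#'
#' @param fc an `fc_table` from [log2_fold_changes()].
#' @param timepoints starvation times (minutes) that must all be
#'   uncomputable for removal; default the 10 and 80 min comparison points.
#' @return `fc` with updated `filter_status`.
#' @export
filter_uncomputable <- function(fc, timepoints = c(10, 80)) {
  stopifnot(inherits(fc, "fc_table"))
  cols <- vapply(timepoints, function(t) fc_col_for_time(fc, t), integer(1))
  all_na <- rowSums(!is.na(fc$log2_fc[, cols, drop = FALSE])) == 0
  hit <- all_na & fc$filter_status == "kept"
  fc$filter_status[hit] <- "removed_filter_iii"
  fc
}

#' Classify regulation at one time point
#'
#' Counts genes up-regulated at least `threshold`-fold
#' (`log2_fc >= log2(threshold)`, boundary inclusive), down-regulated at
#' least `threshold`-fold, changed less than `threshold`-fold, and not
#' analyzable (removed by a filter, excluded, or with no computable fold
#' change at this time point). The four categories partition the
#' `universe_size` exactly.
#'
#' @param fc an `fc_table`.
#' @param timepoint starvation time in minutes.
#' @param threshold fold-change cutoff (> 1); default 2.
#' @param universe_size total genes to account for; defaults to all genes
#'   in the table (the annotated chromosomal gene set).
#' @return data.frame with `time_min`, `method`, `n_up`, `n_down`,
#'   `n_unchanged`, `n_na`.
#' @export
classify_regulation <- function(fc, timepoint, threshold = 2,
                                universe_size = NULL) {
  stopifnot(inherits(fc, "fc_table"))
  if (!is.finite(threshold) || threshold <= 1) stop("threshold must be > 1")
  if (is.null(universe_size)) universe_size <- nrow(fc$log2_fc)
  col <- fc_col_for_time(fc, timepoint)
  v <- fc$log2_fc[, col]
  ok <- fc$filter_status == "kept" & !is.na(v)
  lt <- log2(threshold)
  n_up <- sum(v[ok] >= lt)
  n_down <- sum(v[ok] <= -lt)
  n_unchanged <- sum(ok) - n_up - n_down
  data.frame(time_min = timepoint, method = fc$method,
             n_up = as.integer(n_up), n_down = as.integer(n_down),
             n_unchanged = as.integer(n_unchanged),
             n_na = as.integer(universe_size - sum(ok)))
}

#' Most strongly regulated genes
#'
#' Ranks kept genes by their mean log2 fold change over the given time
#' points; genes with a non-computable fold change at any of those times
#' are excluded from the ranking. Ties are broken by gene id
#' (lexicographic) for determinism.
#'
#' @param fc an `fc_table`.
#' @param timepoints starvation times (minutes) to average over.
#' @param n number of genes to return.
#' @param direction `"up"` (largest fold change first) or `"down"`.
#' @return data.frame with `gene_id` and `mean_log2_fc`, `n` rows (fewer,
#'   with a message, if fewer genes are rankable).
#' @export
top_regulated <- function(fc, timepoints, n = 100,
                          direction = c("up", "down")) {
  stopifnot(inherits(fc, "fc_table"), n >= 1)
  direction <- match.arg(direction)
  cols <- vapply(timepoints, function(t) fc_col_for_time(fc, t), integer(1))
  sub <- fc$log2_fc[, cols, drop = FALSE]
  m <- rowMeans(sub)
  ok <- fc$filter_status == "kept" & !is.na(m)
  ids <- rownames(sub)[ok]
  m <- m[ok]
  ord <- if (direction == "up") order(-m, ids) else order(m, ids)
  if (n > length(ids)) {
    message("only ", length(ids), " rankable genes; returning all")
    n <- length(ids)
  }
  sel <- ord[seq_len(n)]
  data.frame(gene_id = ids[sel], mean_log2_fc = m[sel],
             stringsAsFactors = FALSE)
}

#' Run the standard filter cascade
#'
#' Applies, in order: filter i (never sequenced), filter ii (low coverage
#' in both phases), the ambiguous-gene exclusion, fold-change computation,
#' and filter iii (fold change uncomputable at the key time points). The
#' order matters: counts per filter are disjoint because each gene is
#' attributed to the first filter that removes it.
#'
#' @param norm a `norm_matrix`.
#' @param low_threshold cutoff for filter ii.
#' @param ambiguous_ids gene ids to exclude (default `"lacI"`).
#' @param fc_timepoints time points for filter iii.
#' @return The `fc_table` with final `filter_status`.
#' @export
apply_filters <- function(norm, low_threshold = 1, ambiguous_ids = "lacI",
                          fc_timepoints = c(10, 80)) {
  norm <- filter_unexpressed(init_filter_status(norm))
  norm <- filter_low_coverage(norm, low_threshold)
  norm <- suppressWarnings(exclude_ambiguous(norm, ambiguous_ids))
  fc <- log2_fold_changes(norm)
  filter_uncomputable(fc, fc_timepoints)
}

#' Genes detectable in a minimum number of steady-state replicates
#'
#' Support set for variance analyses that need repeated detection: keeps
#' genes with a nonzero normalized value in at least `min_samples` of the
#' steady-state replicates.
#'
#' @param norm a `norm_matrix`.
#' @param min_samples minimum steady-state replicates with signal.
#' @return Character vector of gene ids.
#' @export
detectable_in_steady <- function(norm, min_samples = 2) {
  ss <- norm$meta$condition == "steady_state"
  hits <- rowSums(norm$values[, ss, drop = FALSE] > 0)
  rownames(norm$values)[hits >= min_samples]
}
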