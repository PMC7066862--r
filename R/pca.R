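#' Temporal profile matrix: each gene scaled to its own mean
#'
#' To analyze the *shape* of each gene's temporal response rather than its
#' absolute expression level, every gene's normalized values across the
#' included samples are divided by that gene's mean over those samples.
#' Rows with zero mean carry no profile information and are dropped with a
#' report.
#'
#' @param norm a `norm_matrix`.
#' @param include_samples sample ids to include; default: all steady-state
#'   and starvation samples not flagged as outliers (rifampicin-treatment
#'   samples are excluded).
#' @param genes gene ids to include; default: kept genes if a filter status
#'   is present, otherwise all genes.
#' @return A `profile_matrix`: numeric matrix (genes x samples, every row
#'   mean 1) with the sample metadata in `attr(, "meta")` and the ids of
#'   dropped zero-mean genes in `attr(, "dropped")`.
#' @export
profile_normalize <- function(norm, include_samples = NULL, genes = NULL) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (is.null(include_samples))
    include_samples <- norm$meta$sample_id[
      norm$meta$condition %in% c("steady_state", "starvation") &
        !norm$meta$is_outlier]
  unknown <- setdiff(include_samples, norm$meta$sample_id)
  if (length(unknown)) stop("unknown sample id: ", unknown[1])
  if (length(include_samples) < 2) stop("need at least 2 included samples")
  if (is.null(genes)) genes <- kept_genes(norm)
  m <- norm$values[genes, include_samples, drop = FALSE]
  rm_ <- rowMeans(m)
  dropped <- rownames(m)[rm_ == 0]
  if (length(dropped))
    message(length(dropped), " zero-mean gene(s) dropped from profile matrix")
  m <- m[rm_ > 0, , drop = FALSE] / rm_[rm_ > 0]
  meta <- norm$meta[match(include_samples, norm$meta$sample_id), , drop = FALSE]
  structure(m, meta = meta, dropped = dropped, class = "profile_matrix")
}

#' Principal component analysis of temporal profiles
#'
#' Covariance PCA of the mean-1 profile matrix with genes as observations
#' and time points as variables: columns are mean-centered (no variance
#' scaling) and eigen-decomposed via [stats::prcomp()]. Without centering,
#' the leading component would be the trivial all-ones direction shared by
#' every mean-1 row; with it, PC1/PC2 capture the dominant temporal
#' response shapes.
#'
#' Component signs are fixed deterministically: PC1 points so that its
#' value at the last starvation time exceeds its steady-state mean ("high
#' PC1 = up in starvation"); PC2 points so that its value at the first
#' starvation time is positive (the early surge); remaining components so
#' that their largest-magnitude coordinate is positive.
#'
#' @param profiles a `profile_matrix` from [profile_normalize()].
#' @return A `pca_result`: list with `explained_fraction` (non-increasing,
#'   sums to 1), `scores` (genes x components), `vectors` (time points x
#'   components), `meta`, and `steady_spread` -- per component, the sd of
#'   the component vector over the steady-state coordinates divided by its
#'   sd over all coordinates (a large value, as typically seen for PC3,
#'   indicates a component dominated by steady-replicate sampling error).
#' @export
run_pca <- function(profiles) {
  stopifnot(inherits(profiles, "profile_matrix"))
  m <- unclass(profiles)
  attr(m, "meta") <- NULL; attr(m, "dropped") <- NULL
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 genes and >= 2 time points")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  if (tot == 0) stop("degenerate profile matrix: no variance to decompose")
  meta <- attr(profiles, "meta")
  ss <- meta$condition == "steady_state"
  sv <- which(meta$condition == "starvation")
  vectors <- p$rotation
  scores <- p$x
  for (j in seq_len(ncol(vectors))) {
    v <- vectors[, j]
    s <- if (j == 1 && length(sv) && any(ss)) {
      v[sv[length(sv)]] - mean(v[ss])
    } else if (j == 2 && length(sv)) {
      v[sv[1]]
    } else v[which.max(abs(v))]
    if (!is.na(s) && s < 0) {
      vectors[, j] <- -vectors[, j]
      scores[, j] <- -scores[, j]
    }
  }
  spread <- apply(vectors, 2, function(v)
    if (sum(ss) >= 2) stats::sd(v[ss]) / stats::sd(v) else NA_real_)
  structure(list(explained_fraction = p$sdev^2 / tot,
                 scores = scores, vectors = vectors, center = p$center,
                 meta = meta, steady_spread = spread),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  ef <- x$explained_fraction
  cat("pca_result:", nrow(x$scores), "genes,", length(ef), "components\n")
  cat("  explained:", paste(sprintf("PC%d=%.1f%%", seq_along(ef), 100 * ef),
                            collapse = " "), "\n")
  invisible(x)
}

#' Genes with extreme component scores
#'
#' The top and bottom `ceiling(fraction * N)` genes by score on one
#' component, ties broken lexicographically by gene id.
#'
#' @param result a `pca_result`.
#' @param component component number (default 1).
#' @param fraction fraction of genes per tail, in (0, 0.5].
#' @return list with character vectors `top` and `bottom`.
#' @export
select_extremes <- function(result, component = 1, fraction = 0.1) {
  stopifnot(inherits(result, "pca_result"))
  if (component > ncol(result$scores)) stop("no such component")
  if (!is.finite(fraction) || fraction <= 0 || fraction > 0.5)
    stop("fraction must be in (0, 0.5]")
  sc <- result$scores[, component]
  ids <- rownames(result$scores)
  k <- ceiling(fraction * length(ids))
  top <- ids[order(-sc, ids)][seq_len(k)]
  bottom <- ids[order(sc, ids)][seq_len(k)]
  list(top = top, bottom = bottom)
}

#' Gene-set over-representation by one-sided Fisher exact test
#'
#' For each gene set, tests whether the subset (e.g. the 10% of genes with
#' the highest PC1 scores) contains more members of the set than expected
#' by chance, via the one-sided Fisher exact test on the 2x2 table of
#' (in/out of subset) x (in/out of set) over the universe, with
#' Benjamini-Hochberg adjustment across all tested sets.
#'
#' @param subset character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param gene_sets named list of character vectors (sets are intersected
#'   with the universe before testing).
#' @param universe character vector of all genes under consideration.
#' @return data.frame, one row per set, with `set_id`, `overlap`,
#'   `set_size`, `subset_size`, `universe_size`, `odds_ratio`, `p_value`,
#'   `p_adjust`, ordered by `p_value`.
#' @export
enrich <- function(subset, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  if (length(setdiff(subset, universe)))
    stop("subset contains genes outside the universe")
  subset <- unique(subset)
  n <- length(subset); N <- length(universe)
  rows <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(gene_sets[[id]]), universe)
    K <- length(set)
    a <- length(intersect(set, subset))
    b <- n - a              # subset, not in set
    cc <- K - a             # set, not in subset
    d <- N - K - b          # neither
    p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
    or <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
    data.frame(set_id = id, overlap = a, set_size = K, subset_size = n,
               universe_size = N, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set_id), , drop = FALSE]
}
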