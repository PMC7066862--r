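#' Spike-in culture volume for a sample
#'
#' Whole-cell spike-in dosing: the volume of spike-in culture that carries
#' the target fraction of the sampled cell mass, with cell mass measured by
#' optical density,
#' \deqn{V_{spike} = f \; V_{sample} \; OD_{sample} / OD_{spike}.}
#' With the default `fraction = 0.01` the spike-in cells amount to 1% of
#' the sampled cells, the dose used throughout this workflow.
#'
#' @param v_sample sample volume (any unit; the result is in the same unit).
#' @param od_sample optical density of the sampled culture at harvest.
#' @param od_spike optical density of the spike-in culture.
#' @param fraction target spike-in cell mass as a fraction of sample cell
#'   mass, in (0, 1).
#' @return Spike-in volume in the units of `v_sample`.
#' @examples
#' spike_in_volume(100, 0.5, 1.0)   # 0.5 ml of spike culture per 100 ml sample
#' @export
spike_in_volume <- function(v_sample, od_sample, od_spike, fraction = 0.01) {
  vals <- c(v_sample = v_sample, od_sample = od_sample,
            od_spike = od_spike, fraction = fraction)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dosing inputs must be positive: ",
         paste(names(vals)[!is.finite(vals) | vals <= 0], collapse = ", "))
  fraction * v_sample * od_sample / od_spike
}

#' Spike-in reads per kilobase, per sample
#'
#' Sums the raw reads over the plasmid spike-in features in each sample and
#' divides by their summed length in kb, yielding the sample-wide spike-in
#' reference level used by RPKSP. Treating the features as one pooled
#' reference is the default; `per_feature_average = TRUE` instead averages
#' the per-feature reads-per-kb values.
#'
#' @param x a [count_matrix()] whose annotation contains plasmid features.
#' @param per_feature_average average per-feature RPK instead of pooling.
#' @return Named numeric vector, one spike-in RPK per sample.
#' @export
spikein_rpk <- function(x, per_feature_average = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  feats <- x$annotation$gene_id[x$annotation$origin == "plasmid"]
  if (!length(feats)) stop("no plasmid spike-in features in annotation")
  len_kb <- x$annotation$length_bp[match(feats, x$annotation$gene_id)] / 1000
  sub <- x$counts[feats, , drop = FALSE]
  zero <- colSums(sub) == 0
  if (any(zero))
    stop("zero spike-in reads in sample ", colnames(sub)[zero][1],
         "; spike-in normalization undefined")
  if (per_feature_average) colMeans(sub / len_kb) else colSums(sub) / sum(len_kb)
}

new_norm_matrix <- function(method, values, annotation, meta, side) {
  stopifnot(all(is.finite(values)), all(values >= 0))
  structure(c(list(method = method, values = values,
                   annotation = annotation, meta = meta), side),
            class = "norm_matrix")
}

#' RPKSP normalization (reads per kilobase of gene per 10 kb of spike-in)
#'
#' Divides each gene's length-normalized reads by the sample's spike-in
#' reads per kilobase scaled by 1e4:
#' \deqn{RPKSP_{gs} = \frac{reads_{gs} / length_{kb}(g)}{spikeRPK_s / 10^4}.}
#' Because the spike-in enters at a fixed dose per OD unit of culture,
#' RPKSP measures RNA abundance per cell mass: it is invariant to
#' sequencing depth and tracks genuine changes in total cellular RNA.
#' Plasmid features are excluded from the output grid; their aggregate RPK
#' is kept as the `spikein_rpk` side vector.
#'
#' @inheritParams spikein_rpk
#' @return A `norm_matrix` with `method = "RPKSP"`.
#' @export
normalize_rpksp <- function(x, per_feature_average = FALSE) {
  stopifnot(inherits(x, "count_matrix"))
  srpk <- spikein_rpk(x, per_feature_average)
  chrom <- x$annotation$origin == "chromosome"
  ann <- x$annotation[chrom, , drop = FALSE]
  len_kb <- ann$length_bp / 1000
  rpk <- x$counts[ann$gene_id, , drop = FALSE] / len_kb
  values <- sweep(rpk, 2, srpk / 1e4, "/")
  new_norm_matrix("RPKSP", values, ann, x$meta, list(spikein_rpk = srpk))
}

#' RPKM normalization (reads per kilobase per million mapped reads)
#'
#' The conventional depth-based normalization,
#' \deqn{RPKM_{gs} = \frac{reads_{gs} / total_s \times 10^6}{length_{kb}(g)},}
#' with the per-sample total taken over chromosome-mapped reads only
#' (spike-in plasmid reads excluded). RPKM assumes constant total RNA per
#' sample; when the cellular RNA pool shrinks, RPKM silently rescales every
#' gene upward relative to RPKSP.
#'
#' @param x a [count_matrix()].
#' @return A `norm_matrix` with `method = "RPKM"` and per-sample
#'   `total_reads` side vector.
#' @export
normalize_rpkm <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  chrom <- x$annotation$origin == "chromosome"
  ann <- x$annotation[chrom, , drop = FALSE]
  sub <- x$counts[ann$gene_id, , drop = FALSE]
  total <- colSums(sub)
  zero <- total == 0
  if (any(zero)) stop("zero total reads in sample ", colnames(sub)[zero][1])
  len_kb <- ann$length_bp / 1000
  values <- sweep(sub, 2, total, "/") * 1e6 / len_kb
  new_norm_matrix("RPKM", values, ann, x$meta, list(total_reads = total))
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("norm_matrix [%s]: %d genes x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  if (!is.null(x$filter_status)) {
    tab <- table(x$filter_status)
    cat("  filter:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

# genes currently surviving all filters (all genes if no filter run yet)
kept_genes <- function(norm) {
  if (is.null(norm$filter_status)) return(norm$annotation$gene_id)
  norm$annotation$gene_id[norm$filter_status == "kept"]
}
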