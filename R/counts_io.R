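#' Construct and validate a count matrix object
#'
#' Bundles a genes-by-samples matrix of raw read counts with its gene
#' annotation and sample metadata, enforcing the consistency rules the
#' downstream normalizations rely on: integer non-negative counts, a
#' one-to-one match between matrix genes and annotation, samples matching
#' the metadata, and the plasmid/spike-in correspondence.
#'
#' @param counts numeric matrix of non-negative integers, genes as rows
#'   (rownames = gene ids), samples as columns (colnames = sample ids).
#' @param annotation data.frame with columns `gene_id`, `length_bp`,
#'   `rna_class`, `origin`.
#' @param meta data.frame with columns `sample_id`, `time_min`,
#'   `condition`, `od_at_harvest` and optionally `is_outlier`.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `annotation`, `meta`.
#' @export
count_matrix <- function(counts, annotation, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (any(is.na(counts)))
    stop("counts contain missing values; a gene/sample absent from the data is an error, not zero")
  if (any(counts < 0))
    stop("negative count found")
  if (any(counts != floor(counts)))
    stop("non-integer count found")
  storage.mode(counts) <- "double"   # counts can exceed .Machine$integer.max in deep runs
  annotation <- validate_annotation(annotation)
  meta <- validate_meta(meta)

  extra <- setdiff(rownames(counts), annotation$gene_id)
  if (length(extra))
    stop("gene(s) in counts absent from annotation: ",
         paste(utils::head(extra, 5), collapse = ", "))
  missing <- setdiff(annotation$gene_id, rownames(counts))
  if (length(missing))
    stop("annotated gene(s) missing from counts: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!identical(sort(colnames(counts)), sort(meta$sample_id)))
    stop("sample ids in counts do not match metadata")

  # canonical order: annotation order for genes, metadata order for samples
  counts <- counts[annotation$gene_id, meta$sample_id, drop = FALSE]
  structure(list(counts = counts, annotation = annotation, meta = meta),
            class = "count_matrix")
}

validate_annotation <- function(annotation) {
  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  req <- c("gene_id", "length_bp", "rna_class", "origin")
  miss <- setdiff(req, names(annotation))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
  annotation$gene_id <- as.character(annotation$gene_id)
  dup <- annotation$gene_id[duplicated(annotation$gene_id)]
  if (length(dup)) stop("duplicated gene_id in annotation: ", dup[1])
  if (any(is.na(annotation$length_bp)) || any(annotation$length_bp < 1) ||
      any(annotation$length_bp != floor(annotation$length_bp)))
    stop("length_bp must be a positive integer for every gene")
  annotation$length_bp <- as.integer(annotation$length_bp)
  bad <- setdiff(unique(annotation$rna_class), RNA_CLASSES)
  if (length(bad)) stop("unknown rna_class: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(annotation$origin), ORIGINS)
  if (length(bad)) stop("unknown origin: ", paste(bad, collapse = ", "))
  plasmid <- annotation$origin == "plasmid"
  spike <- annotation$rna_class == "spike_in_feature"
  if (any(plasmid != spike))
    stop("origin=plasmid and rna_class=spike_in_feature must coincide (gene ",
         annotation$gene_id[which(plasmid != spike)[1]], ")")
  rownames(annotation) <- NULL
  annotation
}

validate_meta <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "time_min", "condition", "od_at_harvest")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  meta$sample_id <- as.character(meta$sample_id)
  meta$time_min <- as.numeric(meta$time_min)
  meta$od_at_harvest <- as.numeric(meta$od_at_harvest)
  if (anyDuplicated(meta$sample_id)) stop("duplicated sample_id in metadata")
  bad <- setdiff(unique(meta$condition), CONDITIONS)
  if (length(bad)) stop("unknown condition: ", paste(bad, collapse = ", "))
  if (any(meta$od_at_harvest <= 0)) stop("od_at_harvest must be positive")
  ss <- meta$condition == "steady_state"
  if (any(meta$time_min[ss] > 0))
    stop("steady-state samples must carry time_min <= 0")
  tv <- meta$time_min[meta$condition == "starvation"]
  if (length(tv) > 1 && any(diff(tv) <= 0))
    stop("time_min must be strictly increasing within the starvation series")
  if (is.null(meta$is_outlier)) meta$is_outlier <- FALSE
  meta$is_outlier <- as.logical(meta$is_outlier)
  rownames(meta) <- NULL
  meta
}

#' Read a count matrix with annotation and sample metadata
#'
#' All three inputs are tab-separated text with one header row. The counts
#' file carries genes as rows (first column `gene_id`, remaining columns one
#' per sample); the annotation has columns `gene_id`, `length_bp`,
#' `rna_class`, `origin`; the metadata has columns `sample_id`, `time_min`,
#' `condition`, `od_at_harvest` (and optionally `is_outlier`). Validation is
#' strict: unknown genes, duplicated ids, non-integer or negative counts and
#' sample-id mismatches are errors rather than silent repairs.
#'
#' @param counts_path,annotation_path,meta_path paths to the three TSV files.
#' @return A validated [count_matrix()].
#' @seealso [write_counts()] for the inverse operation.
#' @export
read_counts <- function(counts_path, annotation_path, meta_path) {
  for (p in c(counts_path, annotation_path, meta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("counts file must start with a gene_id column")
  dup <- tab$gene_id[duplicated(tab$gene_id)]
  if (length(dup)) stop("duplicated gene_id in counts: ", dup[1])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric count found in ", counts_path)
  rownames(mat) <- tab$gene_id
  annotation <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  count_matrix(mat, annotation, meta)
}

#' Write a count matrix back to its canonical three-file TSV form
#'
#' Writing then re-reading preserves every count, annotation field and
#' metadata field exactly, and writing a freshly read object reproduces the
#' canonical file byte for byte.
#'
#' @param x a [count_matrix()].
#' @param counts_path,annotation_path,meta_path output paths; annotation and
#'   metadata may be omitted to write counts only.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, counts_path, annotation_path = NULL,
                         meta_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  tab <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, counts_path)
  if (!is.null(annotation_path)) write_tsv(x$annotation, annotation_path)
  if (!is.null(meta_path)) write_tsv(x$meta, meta_path)
  invisible(x)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Gene lengths from a GFF3 annotation
#'
#' Convenience for building the `length_bp` annotation column from a
#' standard GFF3 file. Lengths follow the GFF3 1-based inclusive
#' convention, `end - start + 1`. The identifier is taken from the `ID`
#' attribute, falling back to `locus_tag` then `Name`.
#'
#' @param gff_path path to a GFF3 file.
#' @param feature_type optionally restrict to one `type` (e.g. `"gene"`).
#' @return Named integer vector of lengths in bp, one per identifier.
#' @export
read_gff_lengths <- function(gff_path, feature_type = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff_lengths requires the rtracklayer package")
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (!is.null(feature_type)) gr <- gr[gr$type %in% feature_type]
  md <- as.data.frame(gr)
  id <- md$ID
  for (alt in c("locus_tag", "Name"))
    if (alt %in% names(md)) id <- ifelse(is.na(id) | id == "", md[[alt]], id)
  if (any(is.na(id) | id == ""))
    stop("feature without an identifier attribute (ID/locus_tag/Name)")
  len <- md$end - md$start + 1L
  # identical duplicates collapse; conflicting coordinates are an error
  key <- paste(id, md$start, md$end)
  keep <- !duplicated(key)
  id <- id[keep]; len <- len[keep]
  dup <- id[duplicated(id)]
  if (length(dup))
    stop("identifier with conflicting coordinates in GFF3: ", dup[1])
  stats::setNames(as.integer(len), id)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cls <- table(x$annotation$rna_class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "), "\n")
  cat("  samples:", paste(sprintf("%s(%gmin)", x$meta$sample_id, x$meta$time_min),
                          collapse = " "), "\n")
  invisible(x)
}

#' Flag samples as outliers in the embedded metadata
#'
#' @param x a [count_matrix()] or normalized matrix.
#' @param sample_ids sample ids to flag (others are left untouched).
#' @return `x` with `meta$is_outlier` set for the named samples.
#' @export
mark_outliers <- function(x, sample_ids) {
  stopifnot(inherits(x, c("count_matrix", "norm_matrix")))
  unknown <- setdiff(sample_ids, x$meta$sample_id)
  if (length(unknown)) stop("unknown sample id: ", unknown[1])
  x$meta$is_outlier <- x$meta$is_outlier | x$meta$sample_id %in% sample_ids
  x
}
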