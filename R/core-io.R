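#' Construct a CountMatrix
#'
#' A `CountMatrix` holds non-negative integer counts for samples (or cells)
#' in rows and genes in columns, together with unique sample and gene
#' identifiers. Counts are stored sparsely (`Matrix::dgCMatrix`) and the
#' identifiers double as `dimnames`.
#'
#' @param counts Matrix-like, samples/cells x genes, non-negative integers.
#' @param sample_ids Character vector of unique sample identifiers
#'   (defaults to `rownames(counts)`).
#' @param gene_ids Character vector of unique gene identifiers
#'   (defaults to `colnames(counts)`).
#' @return An object of class `CountMatrix`.
#' @examples
#' m <- count_matrix(matrix(0:5, nrow = 3,
#'                          dimnames = list(paste0("s", 1:3), c("g1", "g2"))))
#' dim(m)
#' @export
count_matrix <- function(counts, sample_ids = rownames(counts),
                         gene_ids = colnames(counts)) {
  if (is.null(sample_ids) || is.null(gene_ids)) {
    ps_stop("sample_ids and gene_ids are required (or set dimnames on counts)",
            "ps_missing_ids")
  }
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")
  sample_ids <- as.character(sample_ids)
  gene_ids <- as.character(gene_ids)
  if (length(sample_ids) != nrow(counts)) {
    ps_stop(sprintf("sample axis mismatch: %d ids for %d rows",
                    length(sample_ids), nrow(counts)), "ps_axis_mismatch")
  }
  if (length(gene_ids) != ncol(counts)) {
    ps_stop(sprintf("gene axis mismatch: %d ids for %d columns",
                    length(gene_ids), ncol(counts)), "ps_axis_mismatch")
  }
  if (anyDuplicated(sample_ids)) ps_stop("sample_ids must be unique", "ps_dup_ids")
  if (anyDuplicated(gene_ids)) ps_stop("gene_ids must be unique", "ps_dup_ids")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != round(v)))) {
    ps_stop("counts must be non-negative integers", "ps_bad_counts")
  }
  dimnames(counts) <- list(sample_ids, gene_ids)
  structure(list(counts = counts, sample_ids = sample_ids, gene_ids = gene_ids),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d samples x %d genes (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * Matrix::nnzero(x$counts) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE])
}

#' Read a sparse count matrix with sample/gene metadata
#'
#' Reads a MatrixMarket coordinate file (samples/cells in rows, genes in
#' columns) plus two tab-separated metadata tables. The first column (or a
#' `sample_id` / `gene_id` column if present) supplies identifiers; row
#' counts must match the matrix dimensions.
#'
#' @param path_mtx Path to the `.mtx` file.
#' @param path_samples Path to the sample metadata TSV (one row per matrix row).
#' @param path_genes Path to the gene metadata TSV (one row per matrix column).
#' @return A [count_matrix()] with metadata tables attached as attributes
#'   `sample_meta` and `gene_meta`.
#' @seealso [write_count_matrix()]
#' @export
read_count_matrix <- function(path_mtx, path_samples, path_genes) {
  for (p in c(path_mtx, path_samples, path_genes)) {
    if (!file.exists(p)) ps_stop(paste0("file not found: ", p), "ps_io")
  }
  m <- Matrix::readMM(path_mtx)
  smeta <- utils::read.delim(path_samples, sep = "\t", stringsAsFactors = FALSE)
  gmeta <- utils::read.delim(path_genes, sep = "\t", stringsAsFactors = FALSE)
  if (nrow(smeta) != nrow(m)) {
    ps_stop(sprintf("sample axis mismatch: MTX declares %d rows, samples TSV has %d",
                    nrow(m), nrow(smeta)), "ps_axis_mismatch")
  }
  if (nrow(gmeta) != ncol(m)) {
    ps_stop(sprintf("gene axis mismatch: MTX declares %d columns, genes TSV has %d",
                    ncol(m), nrow(gmeta)), "ps_axis_mismatch")
  }
  sid <- if ("sample_id" %in% names(smeta)) smeta$sample_id else smeta[[1]]
  gid <- if ("gene_id" %in% names(gmeta)) gmeta$gene_id else gmeta[[1]]
  cm <- count_matrix(m, sample_ids = sid, gene_ids = gid)
  attr(cm, "sample_meta") <- smeta
  attr(cm, "gene_meta") <- gmeta
  cm
}

#' Write a CountMatrix as an MTX/TSV bundle
#'
#' Inverse of [read_count_matrix()]: writes `counts.mtx`, `samples.tsv`
#' and `genes.tsv` into `dir`. Round-trips are lossless.
#'
#' @param x A `CountMatrix`.
#' @param dir Output directory (created if needed).
#' @param sample_meta,gene_meta Optional metadata data frames; defaults to the
#'   bare identifier column.
#' @return Invisibly, the three file paths.
#' @export
write_count_matrix <- function(x, dir, sample_meta = NULL, gene_meta = NULL) {
  stopifnot(inherits(x, "CountMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("counts.mtx", "samples.tsv", "genes.tsv"))
  Matrix::writeMM(x$counts, paths[1])
  if (is.null(sample_meta)) sample_meta <- data.frame(sample_id = x$sample_ids)
  if (is.null(gene_meta)) gene_meta <- data.frame(gene_id = x$gene_ids)
  utils::write.table(sample_meta, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gene_meta, paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a differential-expression table
#'
#' Expects a TSV with columns `gene`, `log2fc`, `lfcSE`, `pvalue`, `padj`
#' (one row per gene per contrast). Extra columns are preserved.
#'
#' @param path Path to the TSV.
#' @param source Optional label (perturbed TF / control set) stored in a
#'   `source` column.
#' @return A data frame of class `DETable`.
#' @export
read_de_table <- function(path, source = NULL) {
  de <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  as_de_table(de, source = source)
}

#' Validate a data frame as a DETable
#'
#' @param de Data frame with at least `gene` and `log2fc`; `lfcSE`, `pvalue`
#'   and `padj` are filled with `NA` when absent.
#' @param source Optional contrast label.
#' @return The validated data frame with class `DETable`.
#' @export
as_de_table <- function(de, source = NULL) {
  if (!all(c("gene", "log2fc") %in% names(de))) {
    ps_stop("DE table needs at least 'gene' and 'log2fc' columns", "ps_de_schema")
  }
  for (col in c("lfcSE", "pvalue", "padj")) if (is.null(de[[col]])) de[[col]] <- NA_real_
  bad <- !is.na(de$padj) & (de$padj < 0 | de$padj > 1)
  if (any(bad)) ps_stop("padj values must lie in [0, 1] or be missing", "ps_de_schema")
  if (anyDuplicated(de$gene)) ps_stop("one row per gene per contrast required", "ps_de_schema")
  if (!is.null(source)) de$source <- source
  class(de) <- c("DETable", "data.frame")
  de
}

#' Default bulk-sample quality-control thresholds
#'
#' Samples are discarded when they fall on the failing side of any rule:
#' fewer than 500,000 total reads, under 30% of reads mapped to exons, over
#' 12% ERCC reads, over 5% mitochondrial reads, or fewer than 4,000 genes
#' detected above 10 counts per million. Boundary values pass (the failure
#' conditions are strict inequalities).
#'
#' @param total_reads,exon_fraction,ercc_fraction,mito_fraction,genes_detected
#'   Rule thresholds.
#' @param cpm_detect CPM level at which a gene counts as detected (ties at
#'   exactly this level count as detected).
#' @return A named list of thresholds.
#' @export
qc_thresholds <- function(total_reads = 5e5, exon_fraction = 0.30,
                          ercc_fraction = 0.12, mito_fraction = 0.05,
                          genes_detected = 4000, cpm_detect = 10) {
  list(total_reads = total_reads, exon_fraction = exon_fraction,
       ercc_fraction = ercc_fraction, mito_fraction = mito_fraction,
       genes_detected = genes_detected, cpm_detect = cpm_detect)
}

#' Bulk-sample quality control
#'
#' Applies the per-sample QC rules of [qc_thresholds()]. Read totals and
#' mapping fractions come from `meta`; the number of genes detected above
#' `cpm_detect` counts per million is computed from the raw counts row.
#'
#' @param counts A `CountMatrix`.
#' @param meta Data frame with columns `sample_id`, `total_reads`,
#'   `exon_fraction`, `ercc_fraction`, `mito_fraction` covering every sample.
#' @param thresholds A list from [qc_thresholds()].
#' @return A list with `pass` (named logical), `reasons` (named list of
#'   violated rule names, empty for passing samples), `genes_detected`
#'   (named integer) and `filtered` (the passing `CountMatrix`).
#' @examples
#' cm <- count_matrix(matrix(rpois(40, 50), 4, 10,
#'   dimnames = list(paste0("s", 1:4), paste0("g", 1:10))))
#' meta <- data.frame(sample_id = paste0("s", 1:4), total_reads = c(6e5, 4e5, 6e5, 6e5),
#'                    exon_fraction = 0.5, ercc_fraction = 0.01, mito_fraction = 0.01)
#' sample_qc(cm, meta, qc_thresholds(genes_detected = 5))$pass
#' @export
sample_qc <- function(counts, meta, thresholds = qc_thresholds()) {
  stopifnot(inherits(counts, "CountMatrix"))
  need <- c("sample_id", "total_reads", "exon_fraction", "ercc_fraction",
            "mito_fraction")
  for (f in need) {
    if (is.null(meta[[f]])) ps_stop(paste0("metadata field missing: ", f), "ps_meta")
  }
  missing <- setdiff(counts$sample_ids, meta$sample_id)
  if (length(missing)) {
    ps_stop(paste0("metadata missing for sample: ", missing[1]), "ps_meta")
  }
  meta <- meta[match(counts$sample_ids, meta$sample_id), , drop = FALSE]
  for (f in setdiff(need, "sample_id")) {
    if (anyNA(meta[[f]])) {
      s <- meta$sample_id[which(is.na(meta[[f]]))[1]]
      ps_stop(sprintf("metadata field '%s' missing for sample %s", f, s), "ps_meta")
    }
  }
  prop <- c("exon_fraction", "ercc_fraction", "mito_fraction")
  for (f in prop) {
    if (any(meta[[f]] < 0 | meta[[f]] > 1)) {
      ps_stop(paste0("proportion outside [0,1]: ", f), "ps_meta")
    }
  }
  th <- thresholds
  tot <- Matrix::rowSums(counts$counts)
  cpm <- counts$counts / pmax(tot, 1) * 1e6
  ngene <- Matrix::rowSums(cpm >= th$cpm_detect)

  reasons <- lapply(seq_len(nrow(meta)), function(i) {
    r <- character(0)
    if (meta$total_reads[i] < th$total_reads) r <- c(r, "total_reads")
    if (meta$exon_fraction[i] < th$exon_fraction) r <- c(r, "exon_fraction")
    if (meta$ercc_fraction[i] > th$ercc_fraction) r <- c(r, "ercc_fraction")
    if (meta$mito_fraction[i] > th$mito_fraction) r <- c(r, "mito_fraction")
    if (ngene[i] < th$genes_detected) r <- c(r, "genes_detected")
    r
  })
  names(reasons) <- meta$sample_id
  pass <- lengths(reasons) == 0
  names(pass) <- meta$sample_id
  list(pass = pass, reasons = reasons,
       genes_detected = stats::setNames(as.integer(ngene), meta$sample_id),
       filtered = counts[pass, ])
}

#' Library-size normalise and log-transform counts
#'
#' Scales every sample/cell row to `target_sum` total counts and applies
#' `log(1 + x)`. All-zero rows are left at zero (with a message).
#'
#' @param counts A `CountMatrix` or a plain matrix of counts.
#' @param target_sum Post-scaling row total (default 10,000).
#' @return A dense numeric matrix with the same dimnames.
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  if (target_sum <= 0) ps_stop("target_sum must be positive", "ps_arg")
  m <- if (inherits(counts, "CountMatrix")) counts$counts else counts
  tot <- Matrix::rowSums(m)
  zero <- tot == 0
  if (any(zero)) message(sum(zero), " all-zero row(s) left unnormalised")
  scl <- ifelse(zero, 0, target_sum / tot)
  out <- as.matrix(m * scl)
  log1p(out)
}
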