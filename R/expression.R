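VALID_CALLS <- c("P", "M", "A")

#' Construct an expression matrix with detection calls
#'
#' The container for MAS5-style processed array data is a
#' [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with two assays — `signal` (linear-scale, non-negative) and `call`
#' (Present/Marginal/Absent) — and per-sample metadata columns `strain`,
#' `flora`, `tissue`, `treatment` and `replicate`. Samples belonging to the
#' same (strain, flora, tissue, treatment) combination form a group; each
#' group must have at least two replicates.
#'
#' @param signal numeric matrix, probe sets x samples, linear scale.
#' @param call character matrix of the same dimension with entries in
#'   `P`, `M`, `A`.
#' @param samples `data.frame` with one row per column of `signal` and
#'   columns `sample_id`, `strain`, `flora`, `tissue`, `treatment`,
#'   `replicate`.
#' @param row_data optional `data.frame` of probe annotation
#'   (`gene_name`, `symbol`, `entrez`), one row per probe set.
#' @return A `SummarizedExperiment`.
#' @export
expression_matrix <- function(signal, call, samples, row_data = NULL) {
  signal <- as.matrix(signal)
  call <- as.matrix(call)
  if (!identical(dim(signal), dim(call)))
    stop("signal and call matrices must have identical dimensions")
  if (any(!is.finite(signal)) || any(signal < 0))
    stop("signals must be finite and non-negative")
  bad <- setdiff(unique(as.vector(call)), VALID_CALLS)
  if (length(bad))
    stop("invalid detection call symbol(s): ", paste(bad, collapse = ", "))
  if (is.null(rownames(signal)))
    stop("signal matrix must have probe-set rownames")
  if (anyDuplicated(rownames(signal)))
    stop("duplicate probe_id in expression matrix")
  req <- c("sample_id", "strain", "flora", "tissue", "treatment", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss))
    stop("sample table lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(samples) != ncol(signal))
    stop("sample table must have one row per sample column")
  grp <- sample_groups(samples)
  if (any(table(grp) < 2L))
    stop("every (strain, flora, tissue, treatment) group needs >= 2 replicates")
  colnames(signal) <- colnames(call) <- samples$sample_id
  rownames(call) <- rownames(signal)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signal, call = call),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  if (!is.null(row_data))
    SummarizedExperiment::rowData(se) <- S4Vectors::DataFrame(row_data)
  se
}

# Group label per sample: strain.flora.tissue.treatment
sample_groups <- function(samples) {
  if (methods::is(samples, "SummarizedExperiment"))
    samples <- as.data.frame(SummarizedExperiment::colData(samples))
  interaction(samples$strain, samples$flora, samples$tissue,
              samples$treatment, drop = TRUE)
}

# Logical column selector for one (strain, flora, tissue) condition block.
condition_samples <- function(mat, condition, treatment) {
  cd <- SummarizedExperiment::colData(mat)
  sel <- cd$strain == condition$strain & cd$flora == condition$flora &
    cd$tissue == condition$tissue & cd$treatment == treatment
  if (!any(sel))
    stop(sprintf("no %s samples for condition %s/%s/%s", treatment,
                 condition$strain, condition$flora, condition$tissue))
  sel
}

#' Read an expression table with detection calls from TSV
#'
#' Expects a tab-separated file whose first column is `probe_id`, followed by
#' two columns per sample named `<sample_id>.signal` and `<sample_id>.call`,
#' plus a companion sample-metadata TSV with the columns required by
#' [expression_matrix()]. Written by [write_expression_table()].
#'
#' @param path path to the signal/call TSV.
#' @param samples_path path to the sample metadata TSV.
#' @return A `SummarizedExperiment` (see [expression_matrix()]).
#' @export
read_expression_table <- function(path, samples_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE,
                               comment.char = "#")
  if (names(tab)[[1L]] != "probe_id")
    stop("first column of expression table must be 'probe_id'")
  sig_cols <- paste0(samples$sample_id, ".signal")
  call_cols <- paste0(samples$sample_id, ".call")
  miss <- setdiff(c(sig_cols, call_cols), names(tab))
  if (length(miss))
    stop("expression table lacks column(s): ", paste(miss, collapse = ", "))
  signal <- as.matrix(tab[sig_cols])
  if (!is.numeric(signal)) stop("non-numeric signal values")
  call <- as.matrix(tab[call_cols])
  colnames(signal) <- colnames(call) <- samples$sample_id
  rownames(signal) <- rownames(call) <- tab$probe_id
  ann <- setdiff(names(tab), c("probe_id", sig_cols, call_cols))
  rd <- if (length(ann)) tab[ann] else NULL
  expression_matrix(signal, call, samples, row_data = rd)
}

#' Write an expression matrix (and its sample table) to TSV
#'
#' @param mat a `SummarizedExperiment` from [expression_matrix()].
#' @param path output TSV for signals and calls.
#' @param samples_path output TSV for the sample metadata.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(mat, path, samples_path) {
  sig <- SummarizedExperiment::assay(mat, "signal")
  call <- SummarizedExperiment::assay(mat, "call")
  out <- data.frame(probe_id = rownames(sig), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in colnames(sig)) {
    out[[paste0(s, ".signal")]] <- sig[, s]
    out[[paste0(s, ".call")]] <- call[, s]
  }
  rd <- as.data.frame(SummarizedExperiment::rowData(mat))
  if (ncol(rd)) out <- cbind(out, rd)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(mat))
  utils::write.table(cd, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
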