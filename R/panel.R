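#' Construct an expression panel
#'
#' The panel is the package's central container: a gene x individual x
#' timepoint array of log-scale expression. Each individual contributes one
#' short time series; downstream functions pool these series into a virtual
#' long series after baseline re-referencing.
#'
#' @param values numeric array `[gene, individual, timepoint]`; no missing
#'   values are permitted.
#' @param genes,individuals character identifiers matching the first two
#'   array dimensions.
#' @param timepoints strictly increasing integer time indices (third
#'   dimension), conventionally starting at 0.
#' @param arm arm label, e.g. `"fasted"`, `"fed"` or `"synthetic"`.
#' @return An object of class `expression_panel`.
#' @export
expression_panel <- function(values, genes, individuals, timepoints,
                             arm = "synthetic") {
  values <- as.array(values)
  if (length(dim(values)) != 3L) {
    arg_error("values must be a 3-d array [gene, individual, timepoint]")
  }
  genes <- as.character(genes)
  individuals <- as.character(individuals)
  timepoints <- as.integer(timepoints)
  if (dim(values)[1] != length(genes) ||
      dim(values)[2] != length(individuals) ||
      dim(values)[3] != length(timepoints)) {
    arg_error("array dimensions do not match gene/individual/timepoint labels")
  }
  if (anyDuplicated(genes) || anyDuplicated(individuals)) {
    arg_error("duplicate gene or individual ids")
  }
  if (is.unsorted(timepoints, strictly = TRUE)) {
    arg_error("timepoints must be strictly increasing")
  }
  if (anyNA(values) || !all(is.finite(values))) {
    data_error("panel contains missing or non-finite values")
  }
  dimnames(values) <- list(genes, individuals, as.character(timepoints))
  structure(
    list(values = values, genes = genes, individuals = individuals,
         timepoints = timepoints, arm = as.character(arm)[1]),
    class = "expression_panel"
  )
}

#' @export
print.expression_panel <- function(x, ...) {
  cat(sprintf("Expression panel (%s arm): %d genes x %d individuals x %d timepoints\n",
              x$arm, length(x$genes), length(x$individuals),
              length(x$timepoints)))
  cat(sprintf("  timepoints: %s\n", paste(x$timepoints, collapse = ", ")))
  invisible(x)
}

#' @export
dim.expression_panel <- function(x) dim(x$values)

#' Write a panel as a TSV matrix plus a sample sheet
#'
#' The matrix is genes x samples with a leading `gene_id` column; the sample
#' sheet has columns `sample_id`, `individual_id`, `timepoint`, `arm`. Sample
#' ids are `<individual>_t<timepoint>`.
#'
#' @param panel an `expression_panel`.
#' @param matrix_path,samples_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_panel_tsv <- function(panel, matrix_path, samples_path) {
  stopifnot(inherits(panel, "expression_panel"))
  ni <- length(panel$individuals); nt <- length(panel$timepoints)
  sheet <- data.frame(
    sample_id = paste0(rep(panel$individuals, each = nt), "_t",
                       rep(panel$timepoints, ni)),
    individual_id = rep(panel$individuals, each = nt),
    timepoint = rep(panel$timepoints, ni),
    arm = panel$arm
  )
  mat <- matrix(NA_real_, length(panel$genes), nrow(sheet),
                dimnames = list(panel$genes, sheet$sample_id))
  for (k in seq_len(nrow(sheet))) {
    mat[, k] <- panel$values[, sheet$individual_id[k],
                             as.character(sheet$timepoint[k])]
  }
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sheet, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, samples_path))
}

#' Read a panel from a TSV matrix and sample sheet
#'
#' Validates that every individual has a complete, duplicate-free set of
#' timepoints and that no value is missing; offending samples are named in
#' the error. Input is assumed already log-scale; set `log2_transform` for
#' raw intensity ratios.
#'
#' @param matrix_path TSV of genes x samples with a `gene_id` first column.
#' @param samples_path TSV sample sheet (`sample_id`, `individual_id`,
#'   `timepoint`, `arm`).
#' @param log2_transform apply `log2()` to the matrix on load.
#' @return An `expression_panel`.
#' @export
read_panel_tsv <- function(matrix_path, samples_path, log2_transform = FALSE) {
  mat <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(mat)[1] != "gene_id") data_error("matrix must start with a gene_id column")
  genes <- as.character(mat$gene_id)
  m <- as.matrix(mat[, -1, drop = FALSE])
  rownames(m) <- genes
  sheet <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "individual_id", "timepoint", "arm")
  if (!all(need %in% names(sheet))) {
    data_error(paste0("sample sheet must have columns: ",
                      paste(need, collapse = ", ")))
  }
  missing_samples <- setdiff(sheet$sample_id, colnames(m))
  if (length(missing_samples)) {
    data_error(paste0("samples in sheet but not in matrix: ",
                      paste(missing_samples, collapse = ", ")))
  }
  dup <- duplicated(sheet[, c("individual_id", "timepoint")])
  if (any(dup)) {
    data_error(paste0("duplicate (individual, timepoint) rows: ",
                      paste(sheet$sample_id[dup], collapse = ", ")))
  }
  if (log2_transform) m <- log2(m)
  if (anyNA(m)) data_error("expression matrix contains missing values")

  individuals <- unique(sheet$individual_id)
  timepoints <- sort(unique(sheet$timepoint))
  complete <- vapply(individuals, function(i) {
    setequal(sheet$timepoint[sheet$individual_id == i], timepoints)
  }, logical(1))
  if (!all(complete)) {
    warning(paste0("dropping individual(s) with missing timepoints: ",
                   paste(individuals[!complete], collapse = ", ")))
    individuals <- individuals[complete]
    if (!length(individuals)) data_error("no individual has complete timepoints")
  }
  values <- array(NA_real_, dim = c(length(genes), length(individuals),
                                    length(timepoints)),
                  dimnames = list(genes, individuals, timepoints))
  for (k in seq_len(nrow(sheet))) {
    i <- sheet$individual_id[k]
    if (!(i %in% individuals)) next
    values[, i, as.character(sheet$timepoint[k])] <- m[, sheet$sample_id[k]]
  }
  expression_panel(values, genes, individuals, timepoints,
                   arm = sheet$arm[1])
}

#' Write / read a ground-truth or network edge list as TSV
#'
#' Columns: `parent`, `child`, `slice` (`intra` or `inter`), `coefficient`
#' (or `frequency` for consensus outputs).
#'
#' @param edges data frame of edges.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
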