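#' Construct an expression matrix with stage/replicate metadata
#'
#' Container for log2-scale gene-by-sample expression with an ordered sample
#' sheet. Invariants enforced here: unique gene ids, unique (stage,
#' replicate) pairs, every stage with the same replicate count, and at least
#' two replicates per stage (the paired t-test is undefined otherwise).
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns.
#' @param stage character vector, one stage label per column.
#' @param replicate integer vector, one replicate index per column.
#' @return object of class `expr_matrix`: list with elements `values`
#'   (matrix) and `samples` (data.frame `sample`, `stage`, `replicate`).
#' @export
expression_matrix <- function(values, stage, replicate) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values))) stop("`values` needs gene ids as rownames")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene_id: ", rownames(values)[duplicated(rownames(values))][1])
  }
  if (length(stage) != ncol(values) || length(replicate) != ncol(values)) {
    stop("`stage` and `replicate` must have one entry per sample column")
  }
  replicate <- as.integer(replicate)
  key <- paste(stage, replicate)
  if (anyDuplicated(key)) stop("duplicate (stage, replicate) pair: ", key[duplicated(key)][1])
  tab <- table(stage)
  if (length(unique(as.integer(tab))) != 1L) {
    stop("every stage must have the same replicate count; got ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  if (any(tab < 2)) stop("each stage needs >= 2 replicates")
  samples <- data.frame(sample = paste0(stage, "_rep", replicate),
                        stage = as.character(stage), replicate = replicate,
                        stringsAsFactors = FALSE)
  colnames(values) <- samples$sample
  structure(list(values = values, samples = samples), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d stages x %d replicates)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$stage)),
              max(x$samples$replicate)))
  invisible(x)
}

#' Stages of an expression matrix, in sample order
#' @param expr an `expr_matrix`.
#' @return character vector of unique stage labels.
#' @export
expr_stages <- function(expr) unique(expr$samples$stage)

#' Read a gene-by-sample expression table
#'
#' Tab-delimited, first column `gene_id`, remaining columns one sample each.
#' Sample metadata comes either from the column-naming convention
#' `<stage>_rep<k>` or from a sample sheet (data.frame or TSV path with
#' columns `sample`, `stage`, `replicate`) that remaps arbitrary column
#' names. Values are taken to be log2 scale already; no transform is applied.
#'
#' Duplicate gene rows are an error under `collapse = "none"` and are
#' averaged per sample under `collapse = "mean"` (probe-to-gene collapse at
#' the gene-id level; probe annotation itself is out of scope).
#'
#' @param path file to read.
#' @param collapse `"none"` or `"mean"`.
#' @param sample_sheet optional data.frame or path (see Details).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, collapse = c("none", "mean"),
                            sample_sheet = NULL) {
  collapse <- match.arg(collapse)
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    stop("ragged expression table: rows with ", paste(unique(nf), collapse = "/"),
         " fields")
  }
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  gene_id <- as.character(x[[1]])
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values")

  if (!is.null(sample_sheet)) {
    sheet <- if (is.character(sample_sheet)) read.delim(sample_sheet, stringsAsFactors = FALSE) else sample_sheet
    if (!all(c("sample", "stage", "replicate") %in% names(sheet))) {
      stop("sample sheet needs columns: sample, stage, replicate")
    }
    m <- match(colnames(vals), sheet$sample)
    if (anyNA(m)) stop("sample sheet is missing column(s): ",
                       paste(colnames(vals)[is.na(m)], collapse = ", "))
    stage <- sheet$stage[m]
    replicate <- sheet$replicate[m]
  } else {
    ok <- grepl("^(.+)_rep([0-9]+)$", colnames(vals))
    if (!all(ok)) {
      stop("sample column(s) not named '<stage>_rep<k>' and no sample sheet given: ",
           paste(colnames(vals)[!ok], collapse = ", "))
    }
    stage <- sub("^(.+)_rep([0-9]+)$", "\\1", colnames(vals))
    replicate <- as.integer(sub("^(.+)_rep([0-9]+)$", "\\2", colnames(vals)))
  }

  if (anyDuplicated(gene_id)) {
    if (collapse == "none") {
      stop("duplicate gene_id '", gene_id[duplicated(gene_id)][1],
           "'; use collapse = \"mean\" to average duplicates")
    }
    n <- rowsum(rep(1, length(gene_id)), gene_id, reorder = FALSE)
    vals <- rowsum(vals, gene_id, reorder = FALSE) / as.vector(n)
  } else {
    rownames(vals) <- gene_id
  }
  expression_matrix(vals, stage, replicate)
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, sample columns named `<stage>_rep<k>`, values at
#' six significant digits.
#'
#' @param expr an `expr_matrix`.
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(expr$values))) df[[expr$samples$sample[j]]] <- expr$values[, j]
  write_tsv_file(df, path)
}
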