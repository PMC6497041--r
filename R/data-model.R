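#' Construct an expression matrix
#'
#' The central container of the package: a nonnegative numeric gene-by-sample
#' matrix carrying a gene-class label and a unit tag, so downstream steps can
#' refuse inputs on the wrong scale (e.g. the abundance filter only accepts
#' FPKM, the correlation step only accepts log2-normalized values).
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param gene_class One of `"mRNA"`, `"lncRNA"`, `"miRNA"`.
#' @param unit One of `"counts"`, `"fpkm"`, `"log2norm"`. Counts and FPKM
#'   must be finite and nonnegative.
#' @return An `ExpressionMatrix`: the matrix with `gene_class` and `unit`
#'   attributes.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, "mRNA", "counts")
#' gene_class(em)
#' @export
expression_matrix <- function(values,
                              gene_class = c("mRNA", "lncRNA", "miRNA"),
                              unit = c("counts", "fpkm", "log2norm")) {
  gene_class <- match.arg(gene_class)
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("`values` must have gene ids as rownames and sample ids as colnames")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene ids: ", paste(dup_g, collapse = ", "))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("expression values must be finite and non-missing")
  }
  if (unit %in% c("counts", "fpkm") && any(values < 0)) {
    stop("negative values are not allowed for unit '", unit, "'")
  }
  structure(values, gene_class = gene_class, unit = unit,
            class = c("ExpressionMatrix", "matrix", "array"))
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
gene_class <- function(x) attr(x, "gene_class")

#' @rdname expression_matrix
#' @export
expr_unit <- function(x) attr(x, "unit")

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s genes x %d samples [%s]\n",
              nrow(x), gene_class(x), ncol(x), expr_unit(x)))
  invisible(x)
}

.stopifnot_unit <- function(x, unit) {
  if (!inherits(x, "ExpressionMatrix")) {
    stop("expected an ExpressionMatrix, got ", class(x)[1])
  }
  if (!identical(expr_unit(x), unit)) {
    stop("expected unit '", unit, "' but matrix is '", expr_unit(x), "'")
  }
  invisible(x)
}

#' Read and write expression matrices as TSV
#'
#' On-disk layout is a tab-separated UTF-8 file with a header row: first
#' column `gene_id`, remaining columns one per sample. Reading preserves the
#' file's gene and sample order; write followed by read is the identity.
#'
#' @param path File path.
#' @param gene_class,unit Labels attached to the matrix (see
#'   [expression_matrix()]).
#' @return `read_expression_matrix()` returns an `ExpressionMatrix`;
#'   `write_expression_matrix()` returns `path` invisibly.
#' @export
read_expression_matrix <- function(path,
                                   gene_class = c("mRNA", "lncRNA", "miRNA"),
                                   unit = c("counts", "fpkm", "log2norm")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene_id column plus samples")
  ids <- df[[1]]
  vals <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(vals)))
  bad <- which(is.na(num) & !is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric value at row %d (gene '%s'), column '%s'",
                 bad[1, 1], ids[bad[1, 1]], colnames(vals)[bad[1, 2]]))
  }
  rownames(num) <- ids
  expression_matrix(num, gene_class = gene_class, unit = unit)
}

#' @rdname read_expression_matrix
#' @param x An `ExpressionMatrix` to write.
#' @export
write_expression_matrix <- function(x, path) {
  if (!inherits(x, "ExpressionMatrix")) stop("`x` must be an ExpressionMatrix")
  df <- data.frame(gene_id = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the per-sample clinical table
#'
#' Columns: `sample_id`, `condition` (`normal`/`tumor`), `stage`
#' (`T1`..`T4`, empty for normal samples), `os_time` (overall survival in
#' days, may be empty), `os_event` (0/1, may be empty). Tumor samples must
#' carry a stage; normal samples must not.
#'
#' @param path File path.
#' @return A `data.frame` with class `SampleTable`.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("NA", ""))
  validate_sample_table(df)
}

#' @rdname read_sample_table
#' @param df A data frame with the columns above.
#' @export
validate_sample_table <- function(df) {
  need <- c("sample_id", "condition", "stage", "os_time", "os_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("sample table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$condition <- as.character(df$condition)
  df$stage <- as.character(df$stage)
  df$stage[!is.na(df$stage) & df$stage == ""] <- NA_character_
  df$os_time <- suppressWarnings(as.numeric(df$os_time))
  df$os_event <- suppressWarnings(as.integer(df$os_event))
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample ids: ", paste(dup, collapse = ", "))
  bad_cond <- setdiff(unique(df$condition), c("normal", "tumor"))
  if (length(bad_cond)) stop("unknown condition token(s): ",
                             paste(bad_cond, collapse = ", "))
  tum_nostage <- df$sample_id[df$condition == "tumor" & is.na(df$stage)]
  if (length(tum_nostage)) stop("tumor sample(s) missing stage: ",
                                paste(tum_nostage, collapse = ", "))
  norm_stage <- df$sample_id[df$condition == "normal" & !is.na(df$stage)]
  if (length(norm_stage)) stop("normal sample(s) must not carry a stage: ",
                               paste(norm_stage, collapse = ", "))
  bad_stage <- setdiff(stats::na.omit(unique(df$stage)), paste0("T", 1:4))
  if (length(bad_stage)) stop("unknown stage token(s): ",
                              paste(bad_stage, collapse = ", "))
  if (any(!is.na(df$os_time) & df$os_time <= 0)) {
    stop("os_time must be positive where present")
  }
  if (any(!is.na(df$os_event) & !df$os_event %in% c(0L, 1L))) {
    stop("os_event must be 0 or 1 where present")
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' @rdname read_sample_table
#' @param x A `SampleTable` to write.
#' @export
write_sample_table <- function(x, path) {
  out <- as.data.frame(x)
  out$stage[is.na(out$stage)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read and write the miRNA-target interaction table
#'
#' Columns: `mirna_id`, `target_id`, `target_class` (`mRNA`/`lncRNA`),
#' `source` (free text provenance tag, e.g. the database the edge came
#' from). Duplicate (`mirna_id`, `target_id`) rows are silently merged; the
#' number dropped is reported with a message. A target id appearing with two
#' different classes is an error.
#'
#' @param path File path.
#' @return A `data.frame` with class `InteractionTable`.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  validate_interactions(df)
}

#' @rdname read_interactions
#' @param df A data frame with the columns above.
#' @export
validate_interactions <- function(df) {
  need <- c("mirna_id", "target_id", "target_class", "source")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("interaction table missing columns: ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  bad <- setdiff(unique(df$target_class), c("mRNA", "lncRNA"))
  if (length(bad)) stop("unknown target_class token(s): ",
                        paste(bad, collapse = ", "))
  key <- paste(df$mirna_id, df$target_id, sep = "\r")
  ndup <- sum(duplicated(key))
  if (ndup > 0) {
    message(ndup, " duplicate interaction row(s) removed")
    df <- df[!duplicated(key), , drop = FALSE]
    rownames(df) <- NULL
  }
  cls <- tapply(df$target_class, df$target_id, function(z) length(unique(z)))
  if (any(cls > 1)) {
    stop("inconsistent target_class for target(s): ",
         paste(names(cls)[cls > 1], collapse = ", "))
  }
  class(df) <- c("InteractionTable", "data.frame")
  df
}

#' @rdname read_interactions
#' @param x An `InteractionTable` to write.
#' @export
write_interactions <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write gene lengths
#'
#' Two-column TSV `gene_id`, `length` (bp, integer >= 1). Needed to convert
#' counts to FPKM.
#'
#' @param path File path.
#' @return Named integer vector of lengths.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  need <- c("gene_id", "length")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("gene length table missing columns: ",
                         paste(miss, collapse = ", "))
  len <- as.integer(df$length)
  if (anyNA(len) || any(len < 1)) stop("gene lengths must be integers >= 1")
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup)) stop("duplicate gene ids in lengths: ",
                        paste(dup, collapse = ", "))
  stats::setNames(len, as.character(df$gene_id))
}

#' @rdname read_gene_lengths
#' @param lengths Named integer vector as returned by [read_gene_lengths()].
#' @export
write_gene_lengths <- function(lengths, path) {
  df <- data.frame(gene_id = names(lengths), length = as.integer(lengths),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
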