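#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header holds sample ids. Duplicate gene ids and non-numeric cells are
#' errors (the offending id / coordinates are named).
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression table needs a gene-id column plus samples")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicated gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell at gene '", ids[bad[1L, 1L]], "', sample '",
         colnames(raw)[bad[1L, 2L]], "' (value: \"", raw[bad[1L, , drop = FALSE]], "\")")
  }
  dimnames(num) <- list(ids, colnames(raw))
  validate_expression(num)
}

#' Write an expression matrix as TSV
#'
#' Full double precision (17 significant digits), first column `gene_id`.
#'
#' @param X Expression matrix.
#' @param path Output path.
#' @export
write_expression_table <- function(X, path) {
  X <- validate_expression(X)
  header <- paste(c("gene_id", colnames(X)), collapse = "\t")
  rows <- vapply(seq_len(nrow(X)), function(i) {
    paste(c(rownames(X)[i], sprintf("%.17g", X[i, ])), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' @param path File path; must contain a `sample_id` column.
#' @return Data frame.
#' @export
read_phenotype_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"sample_id" %in% names(df)) stop("phenotype table needs a sample_id column")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in the phenotype table")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Write a phenotype table as CSV
#' @param pheno Data frame with `sample_id`.
#' @param path Output path.
#' @export
write_phenotype_table <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated dialect: set name, description, then gene ids. Empty lines
#' are skipped; duplicate ids within a set are removed with a warning; a set
#' with no ids or a line with fewer than 3 fields is an error naming the
#' line.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  sets <- list()
  for (i in keep) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L) stop("malformed GMT line ", i, ": fewer than 3 fields")
    ids <- fields[-(1:2)]
    ids <- ids[nzchar(ids)]
    if (!length(ids)) stop("gene set '", fields[1L], "' (line ", i, ") has no ids")
    if (anyDuplicated(ids)) {
      warning("duplicate ids in set '", fields[1L], "' were removed")
      ids <- unique(ids)
    }
    sets[[fields[1L]]] <- ids
  }
  sets
}

#' Write gene sets as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of descriptions (recycled).
#' @export
write_gene_sets <- function(sets, path, descriptions = "") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential signature from TSV
#'
#' Columns `gene_id`, `log2fc`, `p_value` (direction is recomputed from the
#' sign of log2fc).
#'
#' @param path File path.
#' @return A `differential_signature` data frame.
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("gene_id", "log2fc", "p_value")
  if (!all(need %in% names(df))) {
    stop("signature table needs columns ", paste(need, collapse = ", "))
  }
  df$gene_id <- as.character(df$gene_id)
  df$direction <- sign(df$log2fc)
  out <- df[, c("gene_id", "log2fc", "p_value", "direction")]
  class(out) <- c("differential_signature", class(out))
  sig_check(out)
}

#' Write a differential signature as TSV
#' @param sig A `differential_signature`.
#' @param path Output path.
#' @export
write_signature <- function(sig, path) {
  sig_check(sig)
  header <- "gene_id\tlog2fc\tp_value\tdirection"
  rows <- sprintf("%s\t%.17g\t%.17g\t%d", sig$gene_id, sig$log2fc,
                  sig$p_value, as.integer(sig$direction))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write a module partition as two-column TSV
#' @param partition A `module_partition`.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(gene_id = names(partition$labels),
                   module_label = unname(partition$labels))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a module partition from TSV
#' @param path File path (columns `gene_id`, `module_label`).
#' @param min_module_size Stored minimum module size (default 30).
#' @return A `module_partition`.
#' @export
read_partition <- function(path, min_module_size = 30L) {
  df <- utils::read.delim(path)
  lab <- as.integer(df$module_label)
  names(lab) <- as.character(df$gene_id)
  out <- list(labels = lab, n_modules = length(unique(lab[lab > 0L])),
              min_module_size = as.integer(min_module_size),
              cut_height = NA_real_, tree = NULL)
  class(out) <- "module_partition"
  out
}
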