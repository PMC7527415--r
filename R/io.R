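# Tab-delimited readers and writers shared by all pipeline stages.
# All tables are written with a header, floats at 6 significant digits,
# deterministic row order; every file is re-readable by these readers.

#' Write a numeric matrix as tab-delimited text
#' @param mat matrix with row and column names.
#' @param path output file.
#' @param row_label header for the row-name column (default "id").
#' @export
write_matrix_tsv <- function(mat, path, row_label = "id") {
  df <- data.frame(id = rownames(mat),
                   signif(as.matrix(mat), 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-delimited numeric matrix
#' @param path file written by [write_matrix_tsv] (first column = row IDs).
#' @return numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write a data.frame as tab-delimited text
#' @param df data.frame.
#' @param path output file.
#' @export
write_table_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-delimited table
#' @param path file.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a one-ID-per-line list file
#' @param path file.
#' @return character vector.
#' @export
read_id_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' Read an expression layer (values + design) from disk
#' @param values_path matrix TSV (genes x samples).
#' @param design_path sample design TSV with a `sample_id` column matching
#'   the matrix columns.
#' @return an [expression_matrix].
#' @export
read_expression <- function(values_path, design_path = NULL) {
  values <- read_matrix_tsv(values_path)
  design <- NULL
  if (!is.null(design_path)) {
    design <- read_table_tsv(design_path)
    if (!"sample_id" %in% names(design))
      stop(design_path, ": design needs a sample_id column")
    m <- match(colnames(values), design$sample_id)
    if (anyNA(m))
      stop(design_path, ": design is missing sample(s) ",
           paste(utils::head(colnames(values)[is.na(m)], 5), collapse = ", "))
    design <- design[m, , drop = FALSE]
    rownames(design) <- design$sample_id
  }
  expression_matrix(values, design)
}

#' Read a methylation layer from disk
#' @param m_path,u_path signal matrix TSVs (probes x samples).
#' @param annotation_path probe annotation TSV (probe_id, gene, region,
#'   chrom, snp, multimap).
#' @param detection_p_path,bead_count_path optional QC matrix TSVs.
#' @return a [methylation_data].
#' @export
read_methylation <- function(m_path, u_path, annotation_path,
                             detection_p_path = NULL,
                             bead_count_path = NULL) {
  ann <- read_table_tsv(annotation_path)
  for (col in c("snp", "multimap"))
    if (col %in% names(ann)) ann[[col]] <- as.logical(ann[[col]])
  methylation_data(
    read_matrix_tsv(m_path), read_matrix_tsv(u_path), ann,
    detection_p = if (!is.null(detection_p_path))
      read_matrix_tsv(detection_p_path),
    bead_count = if (!is.null(bead_count_path))
      read_matrix_tsv(bead_count_path))
}

#' Validate pipeline input files without heavy computation
#'
#' Checks cross-file consistency: shared sample IDs between matrices and
#' design, region vocabulary, annotation coverage, TF list contained in the
#' expression genes. Problems are collected, never thrown.
#'
#' @param expression_path,design_path expression layer files.
#' @param m_path,u_path,annotation_path methylation layer files (optional).
#' @param tf_path TF list file (optional).
#' @return data.frame with columns `file` and `problem` (zero rows when
#'   everything is consistent).
#' @export
validate_inputs <- function(expression_path = NULL, design_path = NULL,
                            m_path = NULL, u_path = NULL,
                            annotation_path = NULL, tf_path = NULL) {
  problems <- list()
  note <- function(file, problem)
    problems[[length(problems) + 1]] <<- data.frame(file = file,
                                                    problem = problem)
  expr_genes <- NULL
  if (!is.null(expression_path)) {
    values <- tryCatch(read_matrix_tsv(expression_path), error = function(e) {
      note(expression_path, conditionMessage(e)); NULL })
    if (!is.null(values)) {
      expr_genes <- rownames(values)
      if (anyDuplicated(expr_genes))
        note(expression_path, "duplicated gene IDs")
      if (anyNA(values)) note(expression_path, "missing values")
      if (!is.null(design_path)) {
        design <- tryCatch(read_table_tsv(design_path), error = function(e) {
          note(design_path, conditionMessage(e)); NULL })
        if (!is.null(design)) {
          if (!"sample_id" %in% names(design)) {
            note(design_path, "no sample_id column")
          } else {
            missing <- setdiff(colnames(values), design$sample_id)
            if (length(missing))
              note(design_path, paste("design missing sample(s):",
                                      paste(missing, collapse = ", ")))
          }
        }
      }
    }
  }
  if (!is.null(annotation_path)) {
    ann <- tryCatch(read_table_tsv(annotation_path), error = function(e) {
      note(annotation_path, conditionMessage(e)); NULL })
    if (!is.null(ann)) {
      bad <- setdiff(unique(ann$region), region_classes())
      if (length(bad))
        note(annotation_path,
             paste("unknown region class(es):", paste(bad, collapse = ", ")))
      if (!is.null(m_path)) {
        M <- tryCatch(read_matrix_tsv(m_path), error = function(e) {
          note(m_path, conditionMessage(e)); NULL })
        if (!is.null(M)) {
          absent <- setdiff(rownames(M), ann$probe_id)
          if (length(absent))
            note(annotation_path,
                 paste("probes missing from annotation:",
                       paste(utils::head(absent, 5), collapse = ", ")))
          if (!is.null(u_path)) {
            U <- tryCatch(read_matrix_tsv(u_path), error = function(e) {
              note(u_path, conditionMessage(e)); NULL })
            if (!is.null(U) && !identical(dimnames(M), dimnames(U)))
              note(u_path, "M and U dimnames differ")
          }
        }
      }
    }
  }
  if (!is.null(tf_path) && !is.null(expr_genes)) {
    tfs <- tryCatch(read_id_list(tf_path), error = function(e) {
      note(tf_path, conditionMessage(e)); NULL })
    if (!is.null(tfs)) {
      absent <- setdiff(tfs, expr_genes)
      if (length(absent))
        note(tf_path, paste("TF(s) absent from expression matrix:",
                            paste(utils::head(absent, 5), collapse = ", ")))
    }
  }
  if (length(problems) == 0)
    return(data.frame(file = character(), problem = character()))
  out <- do.call(rbind, problems)
  rownames(out) <- NULL
  out
}

#' Parse an INI-style run configuration
#'
#' Flat `key = value` lines grouped under `[section]` headers; blank lines
#' and `#` comments ignored. Unknown sections are rejected by
#' [run_pipeline]. Values are auto-converted to numeric when possible.
#'
#' @param path config file.
#' @return nested named list: `config$section$key`.
#' @export
parse_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  config <- list()
  section <- "global"
  for (line in lines) {
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      next
    }
    if (!grepl("=", line, fixed = TRUE))
      stop(path, ": malformed line '", line, "'")
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); value <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(value))
    config[[section]][[key]] <- if (!is.na(num)) num else value
  }
  config
}
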