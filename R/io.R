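#' Read a tab-delimited expression matrix
#'
#' Expression files may carry probes in rows (the usual genes-by-samples
#' layout) or samples in rows (bead-chip style exports); the orientation is
#' declared explicitly and never guessed.
#'
#' @param path Path to a tab-delimited text file. The first row and first
#'   column hold identifiers; the body must be numeric. Scientific notation
#'   is accepted; the decimal separator is always the point.
#' @param orientation Either `"probes"` (rows are probes, default) or
#'   `"samples"` (rows are samples; the matrix is transposed on load).
#' @param impute_missing If `TRUE`, missing cells are filled with the
#'   per-probe median; by default any missing value is an error, since the
#'   downstream procedures assume complete matrices.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("probes", "samples"),
                                   impute_missing = FALSE) {
  orientation <- match.arg(orientation)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", row.names = NULL,
                           na.strings = c("NA", ""))
  if (ncol(raw) < 2 || nrow(raw) < 1)
    stop("expression file must have at least one id column, one data column ",
         "and one data row: ", path, call. = FALSE)
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 body[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(body)[bad[1, 2]], path), call. = FALSE)
  dimnames(vals) <- list(ids, colnames(body))
  if (orientation == "samples") vals <- t(vals)
  if (anyNA(vals)) {
    if (!impute_missing) {
      miss <- which(is.na(vals), arr.ind = TRUE)
      stop(sprintf(paste0("missing value at probe '%s', sample '%s' in %s ",
                          "(use impute_missing = TRUE to fill with the ",
                          "per-probe median)"),
                   rownames(vals)[miss[1, 1]], colnames(vals)[miss[1, 2]],
                   path), call. = FALSE)
    }
    for (i in which(rowSums(is.na(vals)) > 0)) {
      med <- stats::median(vals[i, ], na.rm = TRUE)
      if (is.na(med))
        stop("probe '", rownames(vals)[i], "' has no observed values; ",
             "cannot impute", call. = FALSE)
      vals[i, is.na(vals[i, ])] <- med
    }
  }
  expression_matrix(vals)
}

#' Write an expression matrix as tab-delimited text
#'
#' Values are written with enough digits (17 significant) that reading the
#' file back reproduces the stored doubles exactly.
#'
#' @param matrix An [expression_matrix()].
#' @param path Output path.
#' @param orientation Row layout to write, as in [read_expression_matrix()].
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(matrix, path,
                                    orientation = c("probes", "samples")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  vals <- matrix$exprs
  if (ncol(vals) == 0 || nrow(vals) == 0)
    stop("refusing to write a degenerate expression matrix (",
         nrow(vals), " probes x ", ncol(vals), " samples)", call. = FALSE)
  if (orientation == "samples") vals <- t(vals)
  id_col <- if (orientation == "probes") "probe_id" else "sample_id"
  header <- paste(c(id_col, colnames(vals)), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write a signature model
#'
#' Three-column TSV with header: `probe_id`, `direction` (`up`/`down`,
#' case-insensitive) and `performance` in `[0, 1]`.
#'
#' @param path File path.
#' @return For `read_signature`, a [signature_model()].
#' @export
read_signature <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  for (col in c("probe_id", "direction", "performance"))
    if (!col %in% names(df))
      stop("signature file is missing column '", col, "': ", path,
           call. = FALSE)
  perf <- suppressWarnings(as.numeric(df$performance))
  if (anyNA(perf))
    stop("non-numeric performance at row ",
         which(is.na(perf))[1], " of ", path, call. = FALSE)
  dir <- tolower(df$direction)
  bad <- which(!dir %in% c("up", "down"))
  if (length(bad))
    stop("unknown direction '", df$direction[bad[1]], "' at row ", bad[1],
         " of ", path, call. = FALSE)
  signature_model(df$probe_id, dir, perf,
                  training_note = paste("read from", basename(path)))
}

#' @rdname read_signature
#' @param signature A [signature_model()].
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "SignatureModel"))
  utils::write.table(as.data.frame(signature)[c("probe_id", "direction",
                                                "performance")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Each line is `term<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' members within a term are de-duplicated; lines with fewer than three
#' fields are rejected.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("GMT line ", short[1], " has fewer than 3 fields: ", path,
         call. = FALSE)
  ids <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(stats::setNames(sets, ids),
                      descriptions = stats::setNames(desc, ids))
}

#' @rdname read_gmt
#' @param gmt A [gene_set_collection()].
#' @export
write_gmt <- function(gmt, path) {
  stopifnot(inherits(gmt, "GeneSetCollection"))
  desc <- attr(gmt, "descriptions")
  lines <- vapply(names(gmt), function(id) {
    paste(c(id, desc[[id]], gmt[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata / probe annotation tables
#'
#' Tab-delimited with header. `read_sample_table` requires `sample_id` and
#' `group` columns; `read_probe_annotation` requires `probe_id`,
#' `gene_symbol` and `multi_locus` (TRUE/FALSE/1/0 accepted).
#'
#' @param path TSV file path.
#' @param levels Optional declared group label set (see [sample_table()]).
#' @return A [sample_table()] or [probe_annotation()].
#' @export
read_sample_table <- function(path, levels = NULL) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  sample_table(df, levels = levels)
}

#' @rdname read_sample_table
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  probe_annotation(df)
}

#' @rdname read_sample_table
#' @param table A `SampleTable` or `ProbeAnnotation`.
#' @export
write_tsv_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
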