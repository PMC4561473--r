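#' Expression matrix container
#'
#' A light wrapper around a numeric matrix of log-scale expression values,
#' probes in rows and samples in columns, together with a record of the
#' transforms that have been applied to it.
#'
#' @param values Numeric matrix with unique, non-empty rownames (probe ids)
#'   and colnames (sample ids). All values must be finite.
#' @param transform_log Character vector of transforms already applied
#'   (e.g. `"log2"`, `"quantile_normalize"`).
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `exprs` (the matrix) and `transform_log`.
#' @export
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' em <- expression_matrix(m)
#' probe_ids(em)
expression_matrix <- function(values, transform_log = character()) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  pid <- rownames(values)
  sid <- colnames(values)
  if (is.null(pid) && nrow(values) == 0) pid <- character(0)
  if (is.null(sid) && ncol(values) == 0) sid <- character(0)
  dimnames(values) <- list(pid, sid)
  if ((is.null(pid) && nrow(values) > 0) ||
      (is.null(sid) && ncol(values) > 0))
    stop("expression matrix must have probe rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(pid))
    stop("duplicate probe id(s): ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample id(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (!all(is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  structure(list(exprs = values, transform_log = as.character(transform_log)),
            class = "ExpressionMatrix")
}

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
probe_ids <- function(x) rownames(x$exprs)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$exprs)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$exprs), ncol(x$exprs)))
  if (length(x$transform_log))
    cat("transforms:", paste(x$transform_log, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$exprs)

#' Sample metadata table
#'
#' Validates a data frame of per-sample metadata: a unique `sample_id`
#' column and a `group` label drawn from a declared label set. Optional
#' columns (`age`, covariates) are carried through untouched.
#'
#' @param df Data frame with at least `sample_id` and `group` columns.
#' @param levels Optional character vector declaring the admissible group
#'   labels (and their order). Defaults to the labels present.
#' @return The validated data frame, `group` converted to a factor, with
#'   class `SampleTable` prepended.
#' @export
sample_table <- function(df, levels = NULL) {
  for (col in c("sample_id", "group"))
    if (!col %in% names(df))
      stop("sample table is missing mandatory column '", col, "'",
           call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  grp <- as.character(df$group)
  if (is.null(levels)) levels <- unique(grp)
  if (!all(grp %in% levels))
    stop("group label(s) outside declared set: ",
         paste(setdiff(grp, levels), collapse = ", "), call. = FALSE)
  df$group <- factor(grp, levels = levels)
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' Probe annotation table
#'
#' @param df Data frame with mandatory columns `probe_id`, `gene_symbol`
#'   and `multi_locus` (logical, or any of "TRUE"/"FALSE"/"1"/"0",
#'   case-insensitive). An optional `platform` column is retained.
#' @return Validated data frame with class `ProbeAnnotation`.
#' @export
probe_annotation <- function(df) {
  for (col in c("probe_id", "gene_symbol", "multi_locus"))
    if (!col %in% names(df))
      stop("probe annotation is missing mandatory column '", col, "'",
           call. = FALSE)
  df$probe_id <- as.character(df$probe_id)
  df$gene_symbol <- as.character(df$gene_symbol)
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id(s): ",
         paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "),
         call. = FALSE)
  df$multi_locus <- parse_logical(df$multi_locus, "multi_locus")
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  key <- toupper(trimws(as.character(x)))
  out <- c("TRUE" = TRUE, "T" = TRUE, "1" = TRUE,
           "FALSE" = FALSE, "F" = FALSE, "0" = FALSE)[key]
  if (anyNA(out))
    stop("column '", what, "' has unparseable logical value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  unname(out)
}

#' Signature model
#'
#' The ordered feature set emitted by signature selection: probe ids, the
#' direction of regulation with age (`down` = lower expression in the
#' older/case group) and each probe's hold-out classification performance.
#'
#' @param probe_id Character vector of unique probe ids.
#' @param direction Character vector, `"up"` or `"down"` per probe
#'   (case-insensitive on input).
#' @param performance Numeric in `[0, 1]` per probe.
#' @param training_note Free-text provenance string.
#' @return A data frame of class `SignatureModel` with columns
#'   `probe_id`, `direction`, `performance` and attribute `training_note`.
#' @export
signature_model <- function(probe_id, direction, performance,
                            training_note = "") {
  probe_id <- as.character(probe_id)
  direction <- tolower(as.character(direction))
  performance <- as.numeric(performance)
  # scalar direction/performance recycle across probes
  if (length(direction) == 1 && length(probe_id) != 1)
    direction <- rep(direction, length(probe_id))
  if (length(performance) == 1 && length(probe_id) != 1)
    performance <- rep(performance, length(probe_id))
  stopifnot(length(probe_id) == length(direction),
            length(probe_id) == length(performance))
  if (anyDuplicated(probe_id))
    stop("duplicate probe id(s) in signature: ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "),
         call. = FALSE)
  bad <- !direction %in% c("up", "down")
  if (any(bad))
    stop("unknown direction token(s): ",
         paste(unique(direction[bad]), collapse = ", "),
         " (row ", paste(which(bad), collapse = ", "), ")", call. = FALSE)
  if (any(!is.finite(performance) | performance < 0 | performance > 1))
    stop("performance values must lie in [0, 1]", call. = FALSE)
  out <- data.frame(probe_id = probe_id, direction = direction,
                    performance = performance, stringsAsFactors = FALSE)
  attr(out, "training_note") <- training_note
  class(out) <- c("SignatureModel", "data.frame")
  out
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat(sprintf("SignatureModel: %d probes (%d down, %d up)\n",
              nrow(x), sum(x$direction == "down"), sum(x$direction == "up")))
  note <- attr(x, "training_note")
  if (!is.null(note) && nzchar(note)) cat("note:", note, "\n")
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("... and", nrow(x) - 6, "more probes\n")
  invisible(x)
}

#' Gene set collection
#'
#' @param sets Named list of character vectors (term id -> member gene
#'   symbols). Members are de-duplicated; empty sets are rejected.
#' @param descriptions Optional named character vector of term descriptions.
#' @return Named list of class `GeneSetCollection` with a `descriptions`
#'   attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets))))
    stop("gene sets must have unique non-empty term ids", call. = FALSE)
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "),
         call. = FALSE)
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d terms, set sizes %d-%d\n",
              length(x), min(lengths(x)), max(lengths(x))))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
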