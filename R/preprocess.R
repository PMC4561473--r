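#' Element-wise log2 transform
#'
#' @param matrix An [expression_matrix()] of strictly positive linear-scale
#'   intensities.
#' @return The transformed matrix, `"log2"` appended to its transform log.
#'   Applying the transform twice is an error.
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if ("log2" %in% matrix$transform_log)
    stop("matrix is already log2-transformed", call. = FALSE)
  bad <- which(matrix$exprs <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-positive value %g at probe '%s', sample '%s'",
                 matrix$exprs[bad[1, 1], bad[1, 2]],
                 rownames(matrix$exprs)[bad[1, 1]],
                 colnames(matrix$exprs)[bad[1, 2]]), call. = FALSE)
  expression_matrix(log2(matrix$exprs),
                    transform_log = c(matrix$transform_log, "log2"))
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' per-rank mean across samples. Tied values within a column receive the
#' mean of the reference values at the ranks they jointly occupy, so that
#' within-column rank order (modulo ties) is preserved exactly.
#'
#' @param matrix An [expression_matrix()] with at least two samples.
#' @return Normalized [expression_matrix()].
#' @export
quantile_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  x <- matrix$exprs
  if (ncol(x) < 2)
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    o <- order(col)
    s <- col[o]
    grp <- cumsum(!duplicated(s))
    norm_sorted <- stats::ave(ref, grp, FUN = mean)
    res <- numeric(length(col))
    res[o] <- norm_sorted
    res
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, transform_log = c(matrix$transform_log,
                                           "quantile_normalize"))
}

#' Per-probe scaling and centering
#'
#' Each probe row is centered to mean 0 and scaled to unit standard
#' deviation (n - 1 denominator). Zero-variance probes cannot be scaled and
#' are dropped with a warning. A per-sample variant is available for
#' sensitivity analysis.
#'
#' @param matrix An [expression_matrix()].
#' @param axis `"probe"` (default) or `"sample"`.
#' @return Scaled [expression_matrix()].
#' @export
scale_center <- function(matrix, axis = c("probe", "sample")) {
  axis <- match.arg(axis)
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  x <- matrix$exprs
  if (axis == "sample") x <- t(x)
  sds <- apply(x, 1, stats::sd)
  degenerate <- sds == 0 | !is.finite(sds)
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance ",
            if (axis == "probe") "probe(s)" else "sample(s)",
            " dropped during scaling: ",
            paste(utils::head(rownames(x)[degenerate], 5), collapse = ", "),
            if (sum(degenerate) > 5) ", ..." else "", call. = FALSE)
    x <- x[!degenerate, , drop = FALSE]
    sds <- sds[!degenerate]
  }
  if (nrow(x) == 0)
    stop("all rows were zero-variance; nothing left to scale", call. = FALSE)
  out <- (x - rowMeans(x)) / sds
  if (axis == "sample") out <- t(out)
  expression_matrix(out, transform_log = c(matrix$transform_log,
                                           paste0("scale_center_", axis)))
}

#' Map a signature across platforms via gene symbols
#'
#' Signature probes are translated from a source platform to a destination
#' platform through shared gene symbols; this mirrors how an
#' Affymetrix-trained probe-set list is carried onto Illumina bead chips.
#' Direction and performance are conserved. When one gene maps to several
#' destination probes, all of them are retained with the gene's direction.
#' Entries whose gene symbol is absent from the destination annotation are
#' dropped, with a message giving the count.
#'
#' @param signature A [signature_model()] on the source platform.
#' @param src,dst [probe_annotation()] tables for the source and
#'   destination platforms.
#' @return A [signature_model()] on destination probe ids.
#' @export
map_signature <- function(signature, src, dst) {
  stopifnot(inherits(signature, "SignatureModel"),
            inherits(src, "ProbeAnnotation"),
            inherits(dst, "ProbeAnnotation"))
  missing_src <- setdiff(signature$probe_id, src$probe_id)
  if (length(missing_src))
    stop("signature probe(s) absent from source annotation: ",
         paste(utils::head(missing_src, 5), collapse = ", "), call. = FALSE)
  genes <- src$gene_symbol[match(signature$probe_id, src$probe_id)]
  entries <- lapply(seq_len(nrow(signature)), function(i) {
    hits <- dst$probe_id[dst$gene_symbol == genes[i]]
    if (length(hits) == 0) return(NULL)
    data.frame(probe_id = hits, direction = signature$direction[i],
               performance = signature$performance[i],
               stringsAsFactors = FALSE)
  })
  n_unmapped <- sum(vapply(entries, is.null, logical(1)))
  if (n_unmapped > 0)
    message(n_unmapped, " signature entr",
            if (n_unmapped == 1) "y" else "ies",
            " had no destination probe and were dropped")
  out <- do.call(rbind, entries)
  if (is.null(out) || nrow(out) == 0)
    stop("no signature probes mappable to the destination platform",
         call. = FALSE)
  # same destination probe reachable from two source probes: keep first
  out <- out[!duplicated(out$probe_id), , drop = FALSE]
  signature_model(out$probe_id, out$direction, out$performance,
                  training_note = sprintf(
                    "mapped via gene symbols (%d of %d entries survived)",
                    nrow(signature) - n_unmapped, nrow(signature)))
}

#' Collapse probe-level rows to gene level
#'
#' Rows sharing a gene symbol are averaged (arithmetic mean on the log
#' scale); unannotated probes are dropped. Collapsing an already-collapsed
#' matrix is a no-op.
#'
#' @param matrix An [expression_matrix()].
#' @param annotation A [probe_annotation()] covering (a subset of) the rows.
#' @return An [expression_matrix()] with one row per gene symbol.
#' @export
collapse_to_genes <- function(matrix, annotation) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(annotation, "ProbeAnnotation"))
  ids <- probe_ids(matrix)
  genes <- annotation$gene_symbol[match(ids, annotation$probe_id)]
  # rows already named by gene symbol (an earlier collapse) pass through
  already <- is.na(genes) & ids %in% annotation$gene_symbol
  genes[already] <- ids[already]
  keep <- !is.na(genes) & nzchar(genes)
  if (!any(keep))
    stop("no probes in the matrix are annotated with a gene symbol",
         call. = FALSE)
  x <- matrix$exprs[keep, , drop = FALSE]
  g <- genes[keep]
  out <- rowsum(x, g, reorder = FALSE) / as.vector(table(g)[unique(g)])
  expression_matrix(out, transform_log = c(matrix$transform_log,
                                           "collapse_to_genes"))
}
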