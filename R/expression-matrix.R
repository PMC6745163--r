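#' @keywords internal
"_PACKAGE"

#' Sample-level expression matrix with biotype and tissue labels
#'
#' The raw input container of the pipeline: a nonnegative expression matrix
#' (rows = RNAs, columns = samples, unit-agnostic, e.g. RPKM/TPM) together
#' with a per-RNA biotype (`miRNA`, `lncRNA` or `mRNA`), a per-RNA pseudogene
#' flag and a per-sample tissue label.
#'
#' @param values numeric matrix, RNAs in rows (rownames = RNA ids), samples
#'   in columns (colnames = sample ids). All entries must be finite and >= 0.
#' @param biotype character vector of length `nrow(values)`; each element one
#'   of `"miRNA"`, `"lncRNA"`, `"mRNA"`. Names, if present, must match the
#'   rownames of `values`.
#' @param tissue character vector of length `ncol(values)` mapping each
#'   sample to a tissue. Names, if present, must match the colnames.
#' @param is_pseudogene logical vector of length `nrow(values)`; defaults to
#'   all `FALSE`.
#' @return An object of class `SampleExpressionMatrix`: a list with elements
#'   `values`, `biotype`, `is_pseudogene`, `tissue`.
#' @seealso [tissue_registry()], [tissue_medians()], [filter_pseudogenes()]
#' @export
sample_expression_matrix <- function(values, biotype, tissue,
                                     is_pseudogene = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry RNA ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate RNA ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "expression values must be finite and >= 0; first offender: RNA '%s', sample '%s' (value %s)",
      rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      format(values[bad[1, , drop = FALSE]])), call. = FALSE)

  biotype <- .match_row_labels(biotype, rownames(values), "biotype")
  if (!all(biotype %in% BIOTYPES))
    stop("unknown biotype(s): ",
         paste(setdiff(unique(biotype), BIOTYPES), collapse = ", "),
         "; expected one of ", paste(BIOTYPES, collapse = ", "),
         call. = FALSE)
  if (is.null(is_pseudogene))
    is_pseudogene <- rep(FALSE, nrow(values))
  is_pseudogene <- .match_row_labels(is_pseudogene, rownames(values),
                                     "is_pseudogene")
  if (!is.logical(is_pseudogene) || anyNA(is_pseudogene))
    stop("`is_pseudogene` must be logical with no NAs", call. = FALSE)

  tissue <- .match_row_labels(tissue, colnames(values), "tissue")
  if (anyNA(tissue) || any(!nzchar(tissue)))
    stop("every sample must map to exactly one tissue; sample(s) without a tissue: ",
         paste(colnames(values)[is.na(tissue) | !nzchar(tissue)],
               collapse = ", "), call. = FALSE)

  structure(
    list(values = values,
         biotype = stats::setNames(as.character(biotype), rownames(values)),
         is_pseudogene = stats::setNames(as.logical(is_pseudogene),
                                         rownames(values)),
         tissue = stats::setNames(as.character(tissue), colnames(values))),
    class = "SampleExpressionMatrix")
}

# align a per-row annotation vector to the matrix labels, by name if named
.match_row_labels <- function(x, labels, what) {
  if (!is.null(names(x))) {
    if (!setequal(names(x), labels))
      stop(sprintf("names of `%s` do not match the matrix ids", what),
           call. = FALSE)
    x <- x[labels]
  } else if (length(x) != length(labels)) {
    stop(sprintf("`%s` must have length %d (one entry per id)", what,
                 length(labels)), call. = FALSE)
  }
  x
}

#' @export
print.SampleExpressionMatrix <- function(x, ...) {
  reg <- tissue_registry(x)
  cat(sprintf("SampleExpressionMatrix: %d RNAs x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values), nrow(reg)))
  tab <- table(factor(x$biotype, levels = BIOTYPES))
  cat("  biotypes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("(pseudogene-flagged: %d)\n", sum(x$is_pseudogene)))
  invisible(x)
}

#' @export
dim.SampleExpressionMatrix <- function(x) dim(x$values)

#' Tissue registry: ordered tissue names with sample counts
#'
#' @param x a `SampleExpressionMatrix` (counts are tallied from its sample ->
#'   tissue map) or a character vector of tissue names accompanied by
#'   `n_samples`.
#' @param n_samples integer vector of per-tissue sample counts (only when `x`
#'   is a character vector).
#' @return A data.frame of class `TissueRegistry` with columns `tissue` and
#'   `n_samples`, tissues in first-appearance order.
#' @export
tissue_registry <- function(x, n_samples = NULL) {
  if (inherits(x, "SampleExpressionMatrix")) {
    tis <- unique(x$tissue)
    cnt <- as.integer(table(factor(x$tissue, levels = tis)))
  } else {
    tis <- as.character(x)
    cnt <- as.integer(n_samples)
    if (length(cnt) != length(tis))
      stop("`n_samples` must match the number of tissues", call. = FALSE)
  }
  if (anyDuplicated(tis)) stop("tissue names must be unique", call. = FALSE)
  if (length(tis) < 2)
    stop("a tissue registry needs at least 2 tissues", call. = FALSE)
  if (any(cnt < 1))
    stop("every tissue must have at least 1 sample", call. = FALSE)
  structure(data.frame(tissue = tis, n_samples = cnt,
                       stringsAsFactors = FALSE),
            class = c("TissueRegistry", "data.frame"))
}

#' Subset a SampleExpressionMatrix by RNA and/or sample
#' @param x a `SampleExpressionMatrix`
#' @param rnas,samples character or logical selectors; `NULL` keeps all
#' @return the subset `SampleExpressionMatrix`
#' @keywords internal
subset_sem <- function(x, rnas = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(rnas)) v <- v[rnas, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  structure(list(values = v,
                 biotype = x$biotype[rownames(v)],
                 is_pseudogene = x$is_pseudogene[rownames(v)],
                 tissue = x$tissue[colnames(v)]),
            class = "SampleExpressionMatrix")
}

#' Remove pseudogene-flagged RNAs
#'
#' Pseudogenes are dropped before tissue-specificity scoring. By default any
#' RNA carrying the flag is removed regardless of biotype; pass
#' `biotypes = "mRNA"` to restrict the filter to mRNAs only.
#'
#' @param x a `SampleExpressionMatrix`
#' @param biotypes biotypes the filter applies to (default: all)
#' @param quiet suppress the removed-count message
#' @return the filtered `SampleExpressionMatrix` (may have zero rows; a
#'   warning is raised if everything was removed)
#' @export
filter_pseudogenes <- function(x, biotypes = BIOTYPES, quiet = FALSE) {
  stopifnot(inherits(x, "SampleExpressionMatrix"))
  drop <- x$is_pseudogene & x$biotype %in% biotypes
  if (!quiet)
    message(sprintf("filter_pseudogenes: removed %d of %d RNAs",
                    sum(drop), length(drop)))
  if (all(drop)) warning("all RNAs were pseudogene-flagged; empty matrix")
  subset_sem(x, rnas = !drop)
}
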