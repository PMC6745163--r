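#' Aggregate a sample-level matrix to per-tissue medians
#'
#' Builds the m x N tissue-median matrix: entry (i, j) is the median of RNA
#' i's expression over the samples of tissue j. Even sample counts use the
#' midpoint of the two central values (the usual convention).
#'
#' @param x a `SampleExpressionMatrix`
#' @param registry optional `TissueRegistry` fixing the tissue order and the
#'   expected per-tissue sample counts; defaults to the registry derived from
#'   `x`
#' @return an object of class `TissueMedianMatrix`: a list with `x` (numeric
#'   matrix, RNAs x tissues), `biotype` (named character) and `registry`
#' @export
tissue_medians <- function(x, registry = NULL) {
  stopifnot(inherits(x, "SampleExpressionMatrix"))
  if (is.null(registry)) registry <- tissue_registry(x)
  found <- table(factor(x$tissue, levels = registry$tissue))
  if (any(found == 0))
    stop("tissue(s) with zero samples: ",
         paste(registry$tissue[found == 0], collapse = ", "), call. = FALSE)
  if (!all(as.integer(found) == registry$n_samples))
    stop("registry sample counts do not match the matrix", call. = FALSE)
  med <- vapply(registry$tissue, function(tis) {
    apply(x$values[, x$tissue == tis, drop = FALSE], 1, stats::median)
  }, numeric(nrow(x$values)))
  if (is.null(dim(med)))  # single-RNA matrix: vapply returns a vector
    med <- matrix(med, nrow = 1, dimnames = list(rownames(x$values),
                                                 registry$tissue))
  structure(list(x = med, biotype = x$biotype, registry = registry),
            class = "TissueMedianMatrix")
}

#' @export
print.TissueMedianMatrix <- function(x, ...) {
  cat(sprintf("TissueMedianMatrix: %d RNAs x %d tissues\n",
              nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Drop RNAs failing the zero-median filter
#'
#' The default rule removes every RNA whose tissue-median vector is all
#' zeros: such an RNA has no tissue where it is typically expressed, and the
#' Gini index is undefined on the zero vector. The stricter alternative
#' `"pooled_median"` removes RNAs whose median over all samples pooled across
#' tissues is zero (this deletes RNAs expressed in only a few small tissues,
#' so single-tissue RNAs may not survive it).
#'
#' @param tm a `TissueMedianMatrix`
#' @param rule `"all_zero"` (default) or `"pooled_median"`
#' @param sem the `SampleExpressionMatrix` the medians came from; required for
#'   `rule = "pooled_median"`
#' @param quiet suppress the per-biotype removed-count message
#' @return the filtered `TissueMedianMatrix`
#' @export
drop_zero_median <- function(tm, rule = c("all_zero", "pooled_median"),
                             sem = NULL, quiet = FALSE) {
  stopifnot(inherits(tm, "TissueMedianMatrix"))
  rule <- match.arg(rule)
  if (rule == "all_zero") {
    drop <- rowSums(tm$x > 0) == 0
  } else {
    if (is.null(sem))
      stop("rule = \"pooled_median\" needs the sample-level matrix (`sem`)",
           call. = FALSE)
    pooled <- apply(sem$values[rownames(tm$x), , drop = FALSE], 1,
                    stats::median)
    drop <- pooled == 0
  }
  if (!quiet && any(drop)) {
    per <- table(factor(tm$biotype[rownames(tm$x)][drop], levels = BIOTYPES))
    message("drop_zero_median: removed ",
            paste(sprintf("%d %s", per, names(per)), collapse = ", "))
  }
  keep <- rownames(tm$x)[!drop]
  if (length(keep) == 0)
    stop("zero-median filter removed every RNA", call. = FALSE)
  structure(list(x = tm$x[keep, , drop = FALSE],
                 biotype = tm$biotype[keep],
                 registry = tm$registry),
            class = "TissueMedianMatrix")
}

#' Gini index of a nonnegative expression vector
#'
#' The tissue-specificity score: 0 for a perfectly uniform vector
#' (housekeeping-like), (N-1)/N for expression confined to a single tissue.
#' Computed by the sorted-weights form: with x' the vector sorted ascending,
#'
#'   GI = (1/N) * (N + 1 - 2 * sum((N + 1 - i) * x'_i) / sum(x'_i))
#'
#' @param x numeric vector, length >= 2, all entries finite and >= 0, not all
#'   zero
#' @return the Gini index, in `[0, (N-1)/N]`
#' @seealso [gini_pairwise_oracle()] for the independent mean-absolute-
#'   difference formulation used by the test-suite.
#' @export
gini_index <- function(x) {
  .check_gini_input(x)
  n <- length(x)
  xs <- sort(x)
  (n + 1 - 2 * sum((n + 1 - seq_len(n)) * xs) / sum(xs)) / n
}

#' Gini index via the pairwise mean-absolute-difference identity
#'
#' Independent O(N^2) formulation, `sum_ij |x_i - x_j| / (2 N^2 mean(x))`,
#' kept solely as a cross-check of [gini_index()]; the two agree to numerical
#' precision on any valid input.
#'
#' @inheritParams gini_index
#' @return the Gini index
#' @export
gini_pairwise_oracle <- function(x) {
  .check_gini_input(x)
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

.check_gini_input <- function(x) {
  if (length(x) < 2) stop("need at least 2 tissues", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression vector must be finite", call. = FALSE)
  if (any(x < 0)) stop("negative expression value", call. = FALSE)
  if (all(x == 0))
    stop("Gini index undefined for the all-zero vector (apply drop_zero_median first)",
         call. = FALSE)
  invisible(TRUE)
}

#' Specificity thresholds and comparison policy
#'
#' @param ts_threshold Gini score at or above which an RNA is called
#'   tissue-specific (default 0.85)
#' @param nonspecific_threshold Gini score at or below which an RNA is called
#'   nonspecific / housekeeping-like (default 0.15)
#' @param ts_comparison `">="` (default) or `">"`: whether a score exactly at
#'   `ts_threshold` counts as tissue-specific
#' @return a list of class `SpecificityConfig`
#' @export
specificity_config <- function(ts_threshold = 0.85,
                               nonspecific_threshold = 0.15,
                               ts_comparison = c(">=", ">")) {
  ts_comparison <- match.arg(ts_comparison)
  if (!(nonspecific_threshold >= 0 && nonspecific_threshold < ts_threshold &&
        ts_threshold <= 1))
    stop("need 0 <= nonspecific_threshold < ts_threshold <= 1", call. = FALSE)
  structure(list(ts_threshold = ts_threshold,
                 nonspecific_threshold = nonspecific_threshold,
                 ts_comparison = ts_comparison),
            class = "SpecificityConfig")
}

#' Classify a Gini score
#'
#' @param gini numeric vector of Gini scores in `[0, 1]`
#' @param cfg a [specificity_config()]
#' @return character vector: `"tissue_specific"`, `"nonspecific"` or
#'   `"intermediate"`
#' @export
classify_gini <- function(gini, cfg = specificity_config()) {
  if (any(gini < 0 | gini > 1, na.rm = TRUE) || anyNA(gini))
    stop("Gini scores must lie in [0, 1]", call. = FALSE)
  ts <- if (cfg$ts_comparison == ">=") gini >= cfg$ts_threshold
        else gini > cfg$ts_threshold
  ifelse(ts, "tissue_specific",
         ifelse(gini <= cfg$nonspecific_threshold, "nonspecific",
                "intermediate"))
}

#' Assign a tissue-specific RNA to its maximal-expression tissue
#'
#' @param row numeric vector of per-tissue medians (not all zero)
#' @param tissues tissue names, in registry order
#' @return the name of the tissue with the maximal median; ties go to the
#'   first tissue in registry order, with a warning
#' @export
assign_tissue <- function(row, tissues) {
  stopifnot(length(row) == length(tissues))
  if (all(row == 0)) stop("cannot assign an all-zero RNA", call. = FALSE)
  hits <- which(row == max(row))
  if (length(hits) > 1)
    warning("maximal median tied across tissues (",
            paste(tissues[hits], collapse = ", "),
            "); assigning the first in registry order")
  tissues[hits[1]]
}

#' Score, classify and assign every RNA in a tissue-median matrix
#'
#' The core specificity pass: per RNA, the Gini index of its tissue-median
#' vector, the class under `cfg`, and — for tissue-specific RNAs only — the
#' tissue of maximal median expression. An RNA is tissue-specific for at most
#' one tissue; a tissue can own many tissue-specific RNAs.
#'
#' @param tm a filtered `TissueMedianMatrix` (see [drop_zero_median()])
#' @param cfg a [specificity_config()]
#' @return a data.frame of class `specificity_calls` with columns `rna_id`,
#'   `biotype`, `gini`, `class`, `assigned_tissue` (`NA` unless
#'   tissue-specific); attribute `registry` carries the tissue registry.
#' @export
run_specificity <- function(tm, cfg = specificity_config()) {
  stopifnot(inherits(tm, "TissueMedianMatrix"))
  gini <- apply(tm$x, 1, gini_index)
  cls <- classify_gini(gini, cfg)
  assigned <- rep(NA_character_, nrow(tm$x))
  ts <- which(cls == "tissue_specific")
  tissues <- tm$registry$tissue
  for (i in ts) assigned[i] <- assign_tissue(tm$x[i, ], tissues)
  out <- data.frame(rna_id = rownames(tm$x),
                    biotype = unname(tm$biotype[rownames(tm$x)]),
                    gini = unname(gini),
                    class = cls,
                    assigned_tissue = assigned,
                    stringsAsFactors = FALSE)
  structure(out, class = c("specificity_calls", "data.frame"),
            registry = tm$registry, config = cfg)
}

#' Per-biotype class tallies and per-tissue tissue-specific counts
#'
#' @param calls a `specificity_calls` data.frame
#' @return list with `class_counts` (biotype x class contingency, plus
#'   one-decimal percentages) and `ts_by_tissue` (tissue x biotype counts of
#'   tissue-specific RNAs, all registry tissues present)
#' @export
summarize_specificity <- function(calls) {
  stopifnot(inherits(calls, "specificity_calls"))
  reg <- attr(calls, "registry")
  bio <- factor(calls$biotype, levels = BIOTYPES)
  cls <- factor(calls$class, levels = CLASS_LABELS)
  counts <- table(biotype = bio, class = cls)
  pct <- round_half_up(100 * prop.table(counts, margin = 1), 1)
  ts <- calls[calls$class == "tissue_specific", ]
  ts_by_tissue <- table(
    tissue = factor(ts$assigned_tissue, levels = reg$tissue),
    biotype = factor(ts$biotype, levels = BIOTYPES))
  list(class_counts = counts, class_pct = pct, ts_by_tissue = ts_by_tissue)
}

#' Round half away from zero (presentation rounding)
#' @param x numeric
#' @param digits decimal places
#' @return rounded numeric
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
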