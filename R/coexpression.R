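#' Co-expression network construction policy
#'
#' @param corr_threshold absolute Pearson correlation an edge must strictly
#'   exceed (default 0.7; `r = 0.7` exactly is not an edge)
#' @param min_samples minimum samples a tissue needs before correlations are
#'   attempted (default 3; Pearson r at n = 2 is always +/-1)
#' @param allowed_pairs character vector of unordered biotype pairs written
#'   `"a-b"`; the default is the three cross-class pairings
#'   (`miRNA-lncRNA`, `miRNA-mRNA`, `lncRNA-mRNA`) — no within-class edges
#' @param log_transform apply `log2(x + 1)` to expression before correlating
#'   (default `FALSE`: raw values)
#' @return a list of class `NetworkConfig`
#' @export
network_config <- function(corr_threshold = 0.7, min_samples = 3,
                           allowed_pairs = c("miRNA-lncRNA", "miRNA-mRNA",
                                             "lncRNA-mRNA"),
                           log_transform = FALSE) {
  if (!(corr_threshold > 0 && corr_threshold < 1))
    stop("corr_threshold must lie in (0, 1)", call. = FALSE)
  if (min_samples < 2) stop("min_samples must be >= 2", call. = FALSE)
  allowed_pairs <- vapply(strsplit(allowed_pairs, "-", fixed = TRUE),
                          function(p) {
    if (length(p) != 2 || !all(p %in% BIOTYPES))
      stop("allowed_pairs entries must be 'biotype-biotype'", call. = FALSE)
    paste(p[order(BIOTYPE_RANK[p])], collapse = "-")
  }, "")
  structure(list(corr_threshold = corr_threshold,
                 min_samples = as.integer(min_samples),
                 allowed_pairs = unique(allowed_pairs),
                 log_transform = isTRUE(log_transform)),
            class = "NetworkConfig")
}

#' Pearson correlation with the network module's degeneracy policy
#'
#' @param a,b numeric vectors of equal length
#' @param min_samples vectors shorter than this yield `NA` with a warning
#' @return the Pearson product-moment correlation, or `NA_real_` when it is
#'   undefined (zero variance in either vector, or too few samples)
#' @export
pearson <- function(a, b, min_samples = 3) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < min_samples) {
    warning("fewer than ", min_samples, " samples; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b, method = "pearson")
}

#' Build the co-expression network of one tissue
#'
#' Restricts to the samples of `tissue` and to the RNAs called
#' tissue-specific for `tissue`, computes sample-level Pearson correlations
#' for every unordered RNA pair whose biotype pair is allowed, and keeps the
#' pairs with `|r|` strictly above the threshold. Within an edge, the
#' endpoint with lower biotype precedence (miRNA < lncRNA < mRNA), then lower
#' lexicographic id, is `rna_a`; rows are sorted on (rna_a, rna_b), so output
#' is deterministic.
#'
#' A tissue with fewer than `min_samples` samples, or with no
#' tissue-specific RNAs, yields an empty network (with a warning in the first
#' case), never an error.
#'
#' @param sem the sample-level `SampleExpressionMatrix`
#' @param calls a `specificity_calls` data.frame (see [run_specificity()])
#' @param tissue tissue name, present in the registry
#' @param cfg a [network_config()]
#' @return an object of class `TissueNetwork`: list with `tissue`, `edges`
#'   (canonical edge data.frame), `n_edges`, `node_tally` (RNAs incident to
#'   at least one edge, per biotype) and `n_samples`
#' @export
build_network <- function(sem, calls, tissue, cfg = network_config()) {
  stopifnot(inherits(sem, "SampleExpressionMatrix"),
            inherits(calls, "specificity_calls"))
  reg <- attr(calls, "registry")
  if (!tissue %in% reg$tissue)
    stop("unknown tissue: ", tissue, call. = FALSE)
  samp <- names(sem$tissue)[sem$tissue == tissue]
  ts <- calls$rna_id[calls$class == "tissue_specific" &
                     !is.na(calls$assigned_tissue) &
                     calls$assigned_tissue == tissue]
  ts <- intersect(ts, rownames(sem$values))

  empty <- .tissue_network(tissue, .collect_edges(list()), length(samp))
  if (length(samp) < cfg$min_samples) {
    warning(sprintf("tissue '%s' has %d < %d samples; empty network",
                    tissue, length(samp), cfg$min_samples))
    return(empty)
  }
  if (length(ts) < 2) return(empty)

  expr <- t(sem$values[ts, samp, drop = FALSE])  # samples x RNAs
  if (cfg$log_transform) expr <- log2(expr + 1)
  # zero-variance profiles have undefined r: no edge, by policy
  r <- suppressWarnings(stats::cor(expr, method = "pearson"))
  r[!is.finite(r)] <- 0

  bio <- sem$biotype[ts]
  pair_key <- function(b1, b2) {
    sw <- BIOTYPE_RANK[b1] > BIOTYPE_RANK[b2]
    paste(ifelse(sw, b2, b1), ifelse(sw, b1, b2), sep = "-")
  }
  idx <- which(upper.tri(r) & abs(r) > cfg$corr_threshold, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    keep <- pair_key(bio[idx[, 1]], bio[idx[, 2]]) %in% cfg$allowed_pairs
    idx <- idx[keep, , drop = FALSE]
  }
  if (nrow(idx) == 0) return(empty)

  a <- ts[idx[, 1]]; b <- ts[idx[, 2]]
  # canonical endpoint order: biotype precedence, then id
  sw <- BIOTYPE_RANK[bio[idx[, 1]]] > BIOTYPE_RANK[bio[idx[, 2]]] |
    (bio[idx[, 1]] == bio[idx[, 2]] & a > b)
  rna_a <- ifelse(sw, b, a); rna_b <- ifelse(sw, a, b)
  edges <- data.frame(
    tissue = tissue,
    rna_a = rna_a, biotype_a = unname(bio[rna_a]),
    rna_b = rna_b, biotype_b = unname(bio[rna_b]),
    pearson_r = r[idx],
    n_samples = length(samp),
    stringsAsFactors = FALSE)
  edges <- edges[order(BIOTYPE_RANK[edges$biotype_a], edges$rna_a,
                       BIOTYPE_RANK[edges$biotype_b], edges$rna_b), ]
  rownames(edges) <- NULL
  .tissue_network(tissue, edges, length(samp))
}

.tissue_network <- function(tissue, edges, n_samples) {
  nodes <- unique(data.frame(id = c(edges$rna_a, edges$rna_b),
                             biotype = c(edges$biotype_a, edges$biotype_b),
                             stringsAsFactors = FALSE))
  tally <- table(factor(nodes$biotype, levels = BIOTYPES))
  structure(list(tissue = tissue, edges = edges, n_edges = nrow(edges),
                 node_tally = tally, n_samples = n_samples),
            class = "TissueNetwork")
}

#' @export
print.TissueNetwork <- function(x, ...) {
  cat(sprintf("TissueNetwork '%s': %d edges over %s (n = %d samples)\n",
              x$tissue, x$n_edges,
              paste(sprintf("%d %s", x$node_tally, names(x$node_tally)),
                    collapse = ", "),
              x$n_samples))
  invisible(x)
}

#' Build networks for every tissue in the registry
#'
#' @inheritParams build_network
#' @return named list of `TissueNetwork`, one per registry tissue
#' @export
build_networks <- function(sem, calls, cfg = network_config()) {
  reg <- attr(calls, "registry")
  stats::setNames(
    lapply(reg$tissue, function(tis) build_network(sem, calls, tis, cfg)),
    reg$tissue)
}

#' Per-tissue interaction summary with grand totals
#'
#' @param networks list of `TissueNetwork` (one per tissue)
#' @return data.frame of class `interaction_summary` with columns `tissue`,
#'   `n_edges` (`NA` when the tissue has no tissue-specific network at all,
#'   mirroring a printed em-dash), `n_mirna`, `n_lncrna`, `n_mrna`;
#'   attributes `total_edges` (sum over tissues) and `total_ts_rnas`
#'   (distinct RNAs incident to an edge in any tissue network)
#' @export
count_interactions <- function(networks) {
  rows <- lapply(networks, function(nw) {
    data.frame(tissue = nw$tissue,
               n_edges = if (nw$n_edges == 0) NA_integer_ else nw$n_edges,
               n_mirna = unname(nw$node_tally["miRNA"]),
               n_lncrna = unname(nw$node_tally["lncRNA"]),
               n_mrna = unname(nw$node_tally["mRNA"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  all_nodes <- unique(unlist(lapply(networks, function(nw)
    c(nw$edges$rna_a, nw$edges$rna_b))))
  structure(out, class = c("interaction_summary", "data.frame"),
            total_edges = sum(out$n_edges, na.rm = TRUE),
            total_ts_rnas = length(all_nodes))
}
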