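#' Parameters of the synthetic expression generator
#'
#' The generator emulates the structure of a multi-tissue bulk expression
#' resource: a modest number of tissues with unequal sample counts,
#' housekeeping RNAs expressed uniformly everywhere, tissue-specific RNAs
#' enriched (or exclusively expressed) in one home tissue, intermediate RNAs
#' expressed in a subset of tissues, pseudogene-flagged RNAs to exercise the
#' pre-filter, and latent-factor-driven co-expression between chosen pairs of
#' same-tissue, cross-biotype tissue-specific RNAs.
#'
#' The default shape is deliberately scaled down (10 tissues, 20
#' samples/tissue, ~60 RNAs) so a full pipeline run takes well under a
#' second; pass `samples_per_tissue` a vector to mimic strongly unequal
#' designs.
#'
#' @param n_tissues number of tissues (default 10)
#' @param samples_per_tissue integer scalar or vector of per-tissue sample
#'   counts (default 20 each)
#' @param counts named list per biotype giving the number of planted
#'   `housekeeping`, `tissue_specific`, `intermediate` and `pseudogene` RNAs
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   log-normal baseline expression level drawn once per RNA (defaults 3, 1:
#'   median abundance ~ e^3 ~ 20 units, spanning ~2 orders of magnitude)
#' @param ts_mode `"pure"` (tissue-specific RNAs are exactly 0 outside the
#'   home tissue) or `"leaky"` (baseline divided by `ts_enrichment` outside)
#' @param ts_enrichment home-tissue fold-enrichment in leaky mode
#'   (default 50)
#' @param noise_cv multiplicative noise coefficient of variation per sample
#'   (default 0.1); the log-scale noise sd is `sqrt(log(1 + noise_cv^2))`
#' @param planted_edges data.frame with columns `rna_a`, `rna_b`, `target_r`
#'   naming pairs of tissue-specific RNA labels (see Details) to co-express;
#'   `0 < |target_r| < 1`
#' @param seed integer seed; the same seed reproduces the dataset
#'   bit-for-bit
#' @details Planted RNAs are labelled deterministically:
#' `hk_<biotype>_<k>`, `ts_<biotype>_<k>` (home tissue `tissue_((k-1) mod
#' n_tissues)+1`), `mid_<biotype>_<k>`, `pseudo_<biotype>_<k>`. Planted edges
#' must join two tissue-specific RNAs of different biotypes sharing a home
#' tissue. Each edge gets its own standard-normal latent factor, shared by
#' its two endpoints over the home-tissue samples with loading
#' `sqrt(|target_r|)` (sign carried by one endpoint), so the expected
#' log-scale Pearson correlation equals `target_r`; an RNA may sit on several
#' edges as long as its summed squared loadings stay below 1.
#' @return a list of class `GeneratorParams`
#' @export
generator_params <- function(n_tissues = 10,
                             samples_per_tissue = 20,
                             counts = list(
                               miRNA = c(housekeeping = 4, tissue_specific = 10,
                                         intermediate = 4, pseudogene = 0),
                               lncRNA = c(housekeeping = 4, tissue_specific = 10,
                                          intermediate = 4, pseudogene = 1),
                               mRNA = c(housekeeping = 4, tissue_specific = 10,
                                        intermediate = 4, pseudogene = 2)),
                             baseline_log_mean = 3, baseline_log_sd = 1,
                             ts_mode = c("pure", "leaky"),
                             ts_enrichment = 50,
                             noise_cv = 0.1,
                             planted_edges = NULL,
                             seed = 42L) {
  ts_mode <- match.arg(ts_mode)
  if (n_tissues < 2) stop("need n_tissues >= 2", call. = FALSE)
  if (length(samples_per_tissue) == 1)
    samples_per_tissue <- rep(samples_per_tissue, n_tissues)
  if (length(samples_per_tissue) != n_tissues || any(samples_per_tissue < 1))
    stop("samples_per_tissue must give a positive count per tissue",
         call. = FALSE)
  stopifnot(setequal(names(counts), BIOTYPES))
  roles <- c("housekeeping", "tissue_specific", "intermediate", "pseudogene")
  for (b in BIOTYPES) {
    if (!all(roles %in% names(counts[[b]])) || any(counts[[b]] < 0))
      stop("counts$", b, " must name nonnegative ",
           paste(roles, collapse = "/"), call. = FALSE)
  }
  if (noise_cv <= 0) stop("noise_cv must be > 0", call. = FALSE)
  if (ts_mode == "leaky" && ts_enrichment <= 1)
    stop("ts_enrichment must exceed 1 in leaky mode", call. = FALSE)
  if (!is.null(planted_edges)) {
    stopifnot(is.data.frame(planted_edges),
              all(c("rna_a", "rna_b", "target_r") %in% names(planted_edges)))
    if (any(abs(planted_edges$target_r) <= 0 |
            abs(planted_edges$target_r) >= 1))
      stop("target_r must satisfy 0 < |r| < 1", call. = FALSE)
  }
  structure(list(n_tissues = as.integer(n_tissues),
                 samples_per_tissue = as.integer(samples_per_tissue),
                 counts = counts,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 ts_mode = ts_mode, ts_enrichment = ts_enrichment,
                 noise_cv = noise_cv,
                 planted_edges = planted_edges,
                 seed = as.integer(seed)),
            class = "GeneratorParams")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Expression model: each RNA draws a log-normal baseline level; each sample
#' observation multiplies the RNA's tissue-level mean by log-normal noise of
#' coefficient of variation `noise_cv`. Tissue-specific RNAs take their
#' baseline only in the home tissue (pure mode: exactly zero elsewhere;
#' leaky mode: baseline / `ts_enrichment` elsewhere). Intermediate RNAs are
#' expressed in half the tissues. Planted edges add a shared standard-normal
#' latent factor to both endpoints' log-noise over home-tissue samples (see
#' [generator_params()]), so their expected log-scale Pearson correlation is
#' `target_r`.
#'
#' @param params a [generator_params()]
#' @return list with `matrix` (a `SampleExpressionMatrix`) and `truth` (class
#'   `SyntheticTruth`: data.frame `roles` with `rna_id`, `biotype`, `role`,
#'   `home_tissue`; the planted edge data.frame; the params)
#' @export
generate_expression <- function(params = generator_params()) {
  stopifnot(inherits(params, "GeneratorParams"))
  set.seed(params$seed)
  nT <- params$n_tissues
  tissues <- sprintf("tissue_%02d", seq_len(nT))
  tissue_of_sample <- rep(tissues, params$samples_per_tissue)
  sample_ids <- sprintf("s%04d", seq_along(tissue_of_sample))
  names(tissue_of_sample) <- sample_ids

  roles <- do.call(rbind, lapply(BIOTYPES, function(b) {
    cnt <- params$counts[[b]]
    mk <- function(role, tag) {
      k <- cnt[[role]]
      if (k == 0) return(NULL)
      data.frame(rna_id = sprintf("%s_%s_%02d", tag, b, seq_len(k)),
                 biotype = b, role = role,
                 home_tissue = if (role == "tissue_specific")
                   tissues[(seq_len(k) - 1) %% nT + 1] else NA_character_,
                 stringsAsFactors = FALSE)
    }
    rbind(mk("housekeeping", "hk"), mk("tissue_specific", "ts"),
          mk("intermediate", "mid"), mk("pseudogene", "pseudo"))
  }))

  edges <- params$planted_edges
  loadings <- .edge_loadings(edges, roles)

  sd_log <- sqrt(log(1 + params$noise_cv^2))
  n_samp <- length(sample_ids)
  baseline <- stats::rlnorm(nrow(roles), params$baseline_log_mean,
                            params$baseline_log_sd)
  # per-edge latent factor, one draw per sample
  factors <- if (is.null(edges)) NULL else
    matrix(stats::rnorm(nrow(edges) * n_samp), nrow(edges), n_samp)

  values <- matrix(0, nrow(roles), n_samp,
                   dimnames = list(roles$rna_id, sample_ids))
  for (i in seq_len(nrow(roles))) {
    role <- roles$role[i]
    mean_of_tissue <- stats::setNames(rep(baseline[i], nT), tissues)
    if (role == "tissue_specific") {
      off <- if (params$ts_mode == "pure") 0 else
        baseline[i] / params$ts_enrichment
      mean_of_tissue[] <- off
      mean_of_tissue[roles$home_tissue[i]] <- baseline[i]
    } else if (role == "intermediate") {
      # expressed in a deterministic half of the tissues: mid-range Gini
      mean_of_tissue[seq_len(nT) %% 2 == i %% 2] <- 0
    }
    mu <- mean_of_tissue[tissue_of_sample]
    lam <- loadings[[roles$rna_id[i]]]
    if (is.null(lam)) {
      z <- stats::rnorm(n_samp)
    } else {
      shared <- colSums(factors[lam$edge, , drop = FALSE] * lam$loading)
      z <- shared + sqrt(1 - sum(lam$loading^2)) * stats::rnorm(n_samp)
    }
    values[i, ] <- mu * exp(sd_log * z - sd_log^2 / 2)
  }

  sem <- sample_expression_matrix(
    values, biotype = roles$biotype, tissue = tissue_of_sample,
    is_pseudogene = roles$role == "pseudogene")
  truth <- structure(list(roles = roles, planted_edges = edges,
                          params = params),
                     class = "SyntheticTruth")
  list(matrix = sem, truth = truth)
}

# per-RNA latent-factor loadings; validates the planted-edge contract
.edge_loadings <- function(edges, roles) {
  if (is.null(edges) || nrow(edges) == 0) return(list())
  info <- function(id) {
    j <- match(id, roles$rna_id)
    if (is.na(j)) stop("planted edge names unknown RNA '", id, "'",
                       call. = FALSE)
    roles[j, ]
  }
  out <- list()
  for (e in seq_len(nrow(edges))) {
    a <- info(edges$rna_a[e]); b <- info(edges$rna_b[e])
    if (a$role != "tissue_specific" || b$role != "tissue_specific")
      stop("planted edges must join tissue_specific RNAs", call. = FALSE)
    if (a$biotype == b$biotype)
      stop("planted edge joins two RNAs of biotype ", a$biotype,
           "; cross-biotype pairs only", call. = FALSE)
    if (a$home_tissue != b$home_tissue)
      stop("planted edge endpoints have different home tissues",
           call. = FALSE)
    r <- edges$target_r[e]
    lam <- sqrt(abs(r))
    out[[a$rna_id]] <- .add_loading(out[[a$rna_id]], e, lam)
    out[[b$rna_id]] <- .add_loading(out[[b$rna_id]], e, lam * sign(r))
  }
  for (id in names(out))
    if (sum(out[[id]]$loading^2) >= 1)
      stop("RNA '", id, "' carries total squared loading >= 1; ",
           "reduce its planted correlations", call. = FALSE)
  out
}

.add_loading <- function(entry, edge, loading) {
  if (is.null(entry)) entry <- list(edge = integer(), loading = numeric())
  list(edge = c(entry$edge, edge), loading = c(entry$loading, loading))
}

#' Compare pipeline output against the planted truth
#'
#' @param calls a `specificity_calls` data.frame from the pipeline run
#' @param networks list of `TissueNetwork` from the same run (or `NULL` to
#'   skip edge metrics)
#' @param truth the `SyntheticTruth` the data came from
#' @return list of class `recovery_report`: `confusion` (planted role x
#'   called class table over non-pseudogene RNAs), per-role recalls
#'   (`ts_recall`, `hk_nonspecific_recall`), `tissue_accuracy` (share of
#'   planted tissue-specific RNAs called tissue-specific AND assigned their
#'   home tissue), and — when networks are given — `edge_precision` /
#'   `edge_recall` of recovered vs planted edges (unordered pairs)
#' @export
recovery_report <- function(calls, networks, truth) {
  stopifnot(inherits(calls, "specificity_calls"),
            inherits(truth, "SyntheticTruth"))
  roles <- truth$roles[truth$roles$role != "pseudogene", ]
  j <- match(roles$rna_id, calls$rna_id)
  if (anyNA(j))
    stop("truth and calls disagree on RNA ids (",
         paste(utils::head(roles$rna_id[is.na(j)], 3), collapse = ", "),
         " missing from calls)", call. = FALSE)
  called <- calls$class[j]
  confusion <- table(planted = roles$role, called = called)
  rec <- function(role, cls) {
    n <- sum(roles$role == role)
    if (n == 0) NA_real_ else sum(roles$role == role & called == cls) / n
  }
  is_ts <- roles$role == "tissue_specific"
  tissue_ok <- is_ts & called == "tissue_specific" &
    calls$assigned_tissue[j] == roles$home_tissue
  out <- list(confusion = confusion,
              ts_recall = rec("tissue_specific", "tissue_specific"),
              hk_nonspecific_recall = rec("housekeeping", "nonspecific"),
              tissue_accuracy = if (any(is_ts))
                sum(tissue_ok, na.rm = TRUE) / sum(is_ts) else NA_real_)
  if (!is.null(networks) && !is.null(truth$planted_edges)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    found <- unlist(lapply(networks, function(nw)
      key(nw$edges$rna_a, nw$edges$rna_b)))
    planted <- key(truth$planted_edges$rna_a, truth$planted_edges$rna_b)
    out$edge_precision <- if (length(found) == 0) NA_real_ else
      mean(found %in% planted)
    out$edge_recall <- mean(planted %in% found)
  }
  structure(out, class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("recovery_report\n")
  print(x$confusion)
  cat(sprintf("  ts_recall = %.3f, hk_nonspecific_recall = %.3f, tissue_accuracy = %.3f\n",
              x$ts_recall, x$hk_nonspecific_recall, x$tissue_accuracy))
  if (!is.null(x$edge_precision))
    cat(sprintf("  edge_precision = %.3f, edge_recall = %.3f\n",
                x$edge_precision, x$edge_recall))
  invisible(x)
}
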