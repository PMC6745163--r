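# in-code fixture builders shared across test files

# tiny labelled matrix: RNAs x samples with tissue + biotype annotation
make_sem <- function(values, biotype, tissue, is_pseudogene = NULL) {
  sample_expression_matrix(values, biotype = biotype, tissue = tissue,
                           is_pseudogene = is_pseudogene)
}

# 3 RNAs (one per biotype) x 4 samples over 2 tissues, deterministic values
tiny_sem <- function() {
  v <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                0, 0, 9, 10), nrow = 3, byrow = TRUE,
              dimnames = list(c("mir1", "lnc1", "m1"),
                              c("s1", "s2", "s3", "s4")))
  make_sem(v, biotype = c("miRNA", "lncRNA", "mRNA"),
           tissue = c(s1 = "liver", s2 = "liver", s3 = "brain", s4 = "brain"))
}

# N-tissue matrix with one sample per tissue and given per-tissue rows
median_sem <- function(rows, biotype, n_tissues = ncol(rows)) {
  tissues <- sprintf("t%02d", seq_len(n_tissues))
  colnames(rows) <- sprintf("s%02d", seq_len(n_tissues))
  make_sem(rows, biotype = biotype,
           tissue = stats::setNames(tissues, colnames(rows)))
}

# deterministic collinear hub instance: `n_sat` satellite RNAs of biotype
# `sat_bio` plus one hub RNA of biotype `hub_bio`, all proportional within
# the home tissue and zero in 8 one-sample "away" tissues (N = 9 tissues, so
# single-tissue expression gives GI = 8/9 > 0.85)
hub_sem <- function(n_sat = 5, sat_bio = "mRNA", hub_bio = "lncRNA",
                    n_samples = 10) {
  base <- seq_len(n_samples)                      # perfectly collinear
  ids <- c(sprintf("sat%02d", seq_len(n_sat)), "hub")
  home <- t(vapply(seq_len(n_sat + 1), function(i) i * base,
                   numeric(n_samples)))
  away <- matrix(0, n_sat + 1, 8)
  v <- cbind(home, away)
  dimnames(v) <- list(ids, sprintf("s%02d", seq_len(n_samples + 8)))
  tissue <- c(rep("home", n_samples), sprintf("away%d", 1:8))
  make_sem(v, biotype = c(rep(sat_bio, n_sat), hub_bio),
           tissue = stats::setNames(tissue, colnames(v)))
}

# randomized multi-biotype instance: all RNAs expressed only in "home"
# (N = 9 tissues, so everything is tissue-specific there), with a few shared
# multiplicative factors inducing suprathreshold correlations
random_instance <- function(seed, n_rna = 30, n_samples = 12) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n_rna))
  bio <- sample(c("miRNA", "lncRNA", "mRNA"), n_rna, replace = TRUE)
  home <- matrix(stats::rlnorm(n_rna * n_samples), n_rna, n_samples)
  for (k in 1:4) {
    members <- sample(n_rna, 6)
    f <- stats::rnorm(n_samples)
    home[members, ] <- home[members, ] * exp(outer(rep(0.8, 6), f))
  }
  v <- cbind(home, matrix(0, n_rna, 8))
  dimnames(v) <- list(ids, sprintf("s%02d", seq_len(n_samples + 8)))
  sem <- make_sem(v, biotype = bio,
                  tissue = c(rep("home", n_samples), sprintf("away%d", 1:8)))
  calls <- run_specificity(drop_zero_median(tissue_medians(sem),
                                            quiet = TRUE))
  list(sem = sem, calls = calls)
}

# independent O(p^2) brute-force network oracle: double loop over all
# unordered pairs, correlation computed from first principles (no stats::cor)
oracle_network_edges <- function(sem, calls, tissue, cfg) {
  samp <- names(sem$tissue)[sem$tissue == tissue]
  ts <- calls$rna_id[calls$class == "tissue_specific" &
                     !is.na(calls$assigned_tissue) &
                     calls$assigned_tissue == tissue]
  ts <- intersect(ts, rownames(sem$values))
  rank <- c(miRNA = 1, lncRNA = 2, mRNA = 3)
  out <- list()
  if (length(samp) < cfg$min_samples || length(ts) < 2)
    return(data.frame(rna_a = character(), rna_b = character(),
                      pearson_r = numeric()))
  for (i in seq_along(ts)) for (j in seq_along(ts)) {
    if (i >= j) next
    a <- ts[i]; b <- ts[j]
    ba <- sem$biotype[[a]]; bb <- sem$biotype[[b]]
    pr <- sort(rank[c(ba, bb)])
    if (!paste(names(pr)[1], names(pr)[2], sep = "-") %in% cfg$allowed_pairs)
      next
    va <- sem$values[a, samp]; vb <- sem$values[b, samp]
    if (cfg$log_transform) { va <- log2(va + 1); vb <- log2(vb + 1) }
    da <- va - mean(va); db <- vb - mean(vb)
    if (sum(da^2) == 0 || sum(db^2) == 0) next
    r <- sum(da * db) / sqrt(sum(da^2) * sum(db^2))
    if (abs(r) > cfg$corr_threshold) {
      sw <- rank[ba] > rank[bb] || (ba == bb && a > b)
      out[[length(out) + 1]] <- data.frame(
        rna_a = if (sw) b else a, rna_b = if (sw) a else b,
        biotype_a = if (sw) bb else ba, biotype_b = if (sw) ba else bb,
        pearson_r = r, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(rna_a = character(), rna_b = character(),
                      pearson_r = numeric()))
  out <- do.call(rbind, out)
  # same canonical row order the package declares
  out[order(rank[out$biotype_a], out$rna_a, rank[out$biotype_b], out$rna_b), ]
}
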