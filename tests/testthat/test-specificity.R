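test_that("tissue medians use the midpoint convention and registry order", {
  v <- matrix(c(1, 2, 100, 1, 3,
                5, 5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:5)))
  sem <- make_sem(v, biotype = c("mRNA", "mRNA"),
                  tissue = c("t1", "t1", "t1", "t2", "t2"))
  tm <- tissue_medians(sem)
  expect_identical(colnames(tm$x), c("t1", "t2"))
  expect_equal(tm$x["a", ], c(t1 = 2, t2 = 2))   # odd count, then midpoint
  expect_equal(unname(tm$x["b", ]), c(5, 5))     # constant case
  # a registry naming a tissue with no samples errors
  reg <- tissue_registry(c("t1", "t2", "t3"), c(3, 2, 1))
  expect_error(tissue_medians(sem, reg), "zero samples")
})

test_that("zero-median filter drops all-zero rows only (default rule)", {
  rows <- rbind(zero = c(0, 0, 0, 0),
                ts_like = c(0, 0, 0, 5),
                flat = c(2, 2, 2, 2))
  sem <- median_sem(rows, biotype = rep("mRNA", 3))
  tm <- tissue_medians(sem)
  out <- suppressMessages(drop_zero_median(tm))
  expect_identical(rownames(out$x), c("ts_like", "flat"))
  # identity when nothing is all-zero
  expect_identical(rownames(suppressMessages(drop_zero_median(out))$x),
                   c("ts_like", "flat"))
  # stricter pooled rule also drops the RNA seen in one tissue out of four
  pooled <- suppressMessages(drop_zero_median(tm, rule = "pooled_median",
                                              sem = sem))
  expect_identical(rownames(pooled$x), "flat")
  # filtering everything is an error
  allzero <- median_sem(rbind(z = c(0, 0, 0, 0)), biotype = "mRNA")
  expect_error(suppressMessages(drop_zero_median(tissue_medians(allzero))),
               "every RNA")
})

test_that("Gini index matches hand-derived values", {
  expect_equal(gini_index(c(5, 5, 5, 5)), 0)
  expect_equal(gini_index(c(0, 0, 6)), 2 / 3)
  expect_equal(gini_index(c(rep(0, 29), 7)), 29 / 30)
  expect_equal(gini_index(c(1, 2, 3, 4)), 0.25)  # pairwise oracle: 20/80
  expect_equal(gini_pairwise_oracle(c(0, 1)), 0.5)
  expect_error(gini_index(c(0, 0, 0)), "all-zero")
  expect_error(gini_index(c(1, -1, 2)), "negative")
  expect_error(gini_index(5), "at least 2")
})

test_that("sorted-weights form equals the pairwise oracle on random vectors", {
  set.seed(101)
  for (n in c(2, 3, 5, 30)) {
    for (rep in seq_len(250)) {
      x <- stats::rexp(n) * stats::rbinom(n, 1, 0.8)
      if (all(x == 0)) x[1] <- 1
      expect_equal(gini_index(x), gini_pairwise_oracle(x), tolerance = 1e-12)
    }
  }
})

test_that("Gini is scale- and permutation-invariant and bounded", {
  set.seed(102)
  for (rep in seq_len(200)) {
    n <- sample(c(2, 3, 5, 30), 1)
    x <- stats::rlnorm(n)
    g <- gini_index(x)
    expect_equal(gini_index(x * stats::runif(1, 0.01, 100)), g,
                 tolerance = 1e-12)
    expect_equal(gini_index(sample(x)), g, tolerance = 1e-12)
    expect_gte(g, 0)
    expect_lte(g, (n - 1) / n)
  }
  # bounds attained exactly at the uniform and single-nonzero extremes
  expect_equal(gini_index(rep(3, 7)), 0)
  expect_equal(gini_index(c(9, rep(0, 6))), 6 / 7)
})

test_that("moving mass from a larger to a smaller coordinate never raises GI", {
  set.seed(103)
  for (rep in seq_len(200)) {
    x <- stats::rexp(10)
    i <- which.max(x); j <- which.min(x)
    d <- stats::runif(1, 0, (x[i] - x[j]) / 2)
    y <- x; y[i] <- y[i] - d; y[j] <- y[j] + d
    expect_lte(gini_index(y), gini_index(x) + 1e-12)
  }
})

test_that("classification honours thresholds and the comparison switch", {
  cfg <- specificity_config()
  expect_identical(classify_gini(c(0.85, 0.15, 0.5, 0, 1), cfg),
                   c("tissue_specific", "nonspecific", "intermediate",
                     "nonspecific", "tissue_specific"))
  strict <- specificity_config(ts_comparison = ">")
  expect_identical(classify_gini(0.85, strict), "intermediate")
  expect_error(classify_gini(1.2, cfg), "\\[0, 1\\]")
  expect_error(specificity_config(ts_threshold = 0.1,
                                  nonspecific_threshold = 0.2))
})

test_that("tissue assignment takes the maximal median, ties to registry order", {
  tis <- c("t1", "t2", "t3")
  expect_identical(assign_tissue(c(0, 0, 7), tis), "t3")
  expect_warning(hit <- assign_tissue(c(3, 3, 1), tis), "tied")
  expect_identical(hit, "t1")
  expect_error(assign_tissue(c(0, 0, 0), tis), "all-zero")
})

test_that("run_specificity scores, classifies and assigns consistently", {
  # three single-tissue RNAs over N = 30 tissues: GI = 29/30, one call each
  rows <- matrix(0, 3, 30, dimnames = list(c("a", "b", "c"), NULL))
  rows[1, 7] <- 4; rows[2, 7] <- 9; rows[3, 30] <- 1
  sem <- median_sem(rows, biotype = c("miRNA", "lncRNA", "mRNA"))
  calls <- run_specificity(drop_zero_median(tissue_medians(sem), quiet = TRUE))
  expect_identical(calls$class, rep("tissue_specific", 3))
  expect_equal(calls$gini, rep(29 / 30, 3))
  expect_identical(calls$assigned_tissue, c("t07", "t07", "t30"))

  # uniform RNAs are all nonspecific, with no assigned tissue
  flat <- median_sem(matrix(5, 2, 30,
                            dimnames = list(c("u1", "u2"), NULL)),
                     biotype = c("mRNA", "mRNA"))
  calls <- run_specificity(drop_zero_median(tissue_medians(flat),
                                            quiet = TRUE))
  expect_identical(calls$class, rep("nonspecific", 2))
  expect_true(all(is.na(calls$assigned_tissue)))

  # invariant: assigned tissue present iff tissue_specific
  sim <- generate_expression(generator_params(seed = 7L))
  tm <- drop_zero_median(tissue_medians(
    suppressMessages(filter_pseudogenes(sim$matrix))), quiet = TRUE)
  calls <- run_specificity(tm)
  expect_identical(is.na(calls$assigned_tissue),
                   calls$class != "tissue_specific")
})

test_that("summarize_specificity tallies per biotype and per tissue", {
  sim <- generate_expression(generator_params(seed = 11L))
  tm <- drop_zero_median(tissue_medians(
    suppressMessages(filter_pseudogenes(sim$matrix))), quiet = TRUE)
  calls <- run_specificity(tm)
  s <- summarize_specificity(calls)
  expect_identical(sum(s$class_counts), nrow(calls))
  expect_identical(sum(s$ts_by_tissue),
                   sum(calls$class == "tissue_specific"))
  # percentages re-derive from counts at one decimal
  expect_equal(s$class_pct["miRNA", ],
               round_half_up(100 * s$class_counts["miRNA", ] /
                               sum(s$class_counts["miRNA", ]), 1))
})
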