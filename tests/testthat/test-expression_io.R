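write_tsv_trio <- function(sem, dir) {
  write_expression_matrix(sem, file.path(dir, "expr"))
  list(expr = file.path(dir, "expr.tsv"),
       samples = file.path(dir, "expr_samples.tsv"),
       annot = file.path(dir, "expr_annotation.tsv"))
}

test_that("TSV round trip reproduces the matrix and its labels", {
  sem <- tiny_sem()
  p <- write_tsv_trio(sem, withr::local_tempdir())
  back <- read_expression_matrix(p$expr, "tsv", sample_map = p$samples,
                                 annotation = p$annot)
  expect_identical(back$values, sem$values)
  expect_identical(back$biotype, sem$biotype)
  expect_identical(back$tissue, sem$tissue)
  expect_identical(nrow(tissue_registry(back)), 2L)
})

test_that("GCT dialect yields the identical matrix as the TSV form", {
  sem <- tiny_sem()
  dir <- withr::local_tempdir()
  p <- write_tsv_trio(sem, dir)
  gct <- file.path(dir, "expr.gct")
  writeLines(c("#1.2", paste(nrow(sem$values), ncol(sem$values), sep = "\t"),
               paste(c("Name", "Description", colnames(sem$values)),
                     collapse = "\t"),
               apply(cbind(rownames(sem$values), "na", sem$values), 1,
                     paste, collapse = "\t")),
             gct)
  from_gct <- read_expression_matrix(gct, "gct", sample_map = p$samples,
                                     annotation = p$annot)
  from_tsv <- read_expression_matrix(p$expr, "tsv", sample_map = p$samples,
                                     annotation = p$annot)
  expect_identical(from_gct, from_tsv)
  # declared dimensions are enforced
  bad <- sub("3\t4", "5\t4", readLines(gct))
  writeLines(bad, gct)
  expect_error(read_expression_matrix(gct, "gct", sample_map = p$samples,
                                      annotation = p$annot), "declares")
})

test_that("validation errors name the offender", {
  sem <- tiny_sem()
  dir <- withr::local_tempdir()
  p <- write_tsv_trio(sem, dir)
  txt <- readLines(p$expr)
  writeLines(sub("\t9\t", "\t-1\t", txt, fixed = TRUE), p$expr)
  expect_error(read_expression_matrix(p$expr, "tsv", sample_map = p$samples,
                                      annotation = p$annot),
               "RNA 'm1'.*sample 's3'")
  writeLines(txt, p$expr)
  # sample missing from the map
  sm <- utils::read.delim(p$samples)
  utils::write.table(sm[-2, ], p$samples, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression_matrix(p$expr, "tsv", sample_map = p$samples,
                                      annotation = p$annot), "s2")
  # malformed header
  writeLines(c("foo\tbar", "a\t1"), p$expr)
  expect_error(read_expression_matrix(p$expr, "tsv", sample_map = p$samples,
                                      annotation = p$annot), "header")
})

test_that("constructor rejects duplicate ids, negatives and unmapped samples", {
  v <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("s1", "s2")))
  expect_error(make_sem(v, c("mRNA", "mRNA"), c("t1", "t2")), "duplicate RNA")
  v <- matrix(c(1, -1, 1, 1), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(make_sem(v, c("mRNA", "mRNA"), c("t1", "t2")), "finite and >= 0")
  v <- abs(v)
  expect_error(make_sem(v, c("mRNA", "badtype"), c("t1", "t2")),
               "unknown biotype")
  expect_error(make_sem(v, c("mRNA", "mRNA"), c("t1", NA)), "tissue")
})

test_that("filter_pseudogenes handles 2-of-5, none and all flagged", {
  v <- matrix(seq_len(10), 5, 2,
              dimnames = list(paste0("r", 1:5), c("s1", "s2")))
  sem <- make_sem(v, biotype = c("mRNA", "mRNA", "lncRNA", "miRNA", "mRNA"),
                  tissue = c("t1", "t2"),
                  is_pseudogene = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  out <- suppressMessages(filter_pseudogenes(sem))
  expect_identical(rownames(out$values), c("r2", "r4", "r5"))
  # surviving values untouched
  expect_identical(out$values, sem$values[c("r2", "r4", "r5"), ])

  none <- make_sem(v, biotype = rep("mRNA", 5), tissue = c("t1", "t2"))
  expect_identical(suppressMessages(filter_pseudogenes(none))$values, v)

  allf <- make_sem(v, biotype = rep("mRNA", 5), tissue = c("t1", "t2"),
                   is_pseudogene = rep(TRUE, 5))
  expect_warning(out <- suppressMessages(filter_pseudogenes(allf)), "all RNAs")
  expect_identical(nrow(out$values), 0L)

  # restriction to mRNA leaves a flagged lncRNA alone
  out <- suppressMessages(filter_pseudogenes(sem, biotypes = "mRNA"))
  expect_true("r3" %in% rownames(out$values))
  expect_false("r1" %in% rownames(out$values))
})

test_that("paper table fixtures load with printed values and absent cells", {
  t1 <- load_paper_table("T1")
  expect_identical(nrow(t1), 30L)
  expect_identical(t1$value[t1$tissue == "Testis"], 172L)
  expect_identical(attr(t1, "printed_total"), 8553)

  t3 <- load_paper_table("T3")
  expect_identical(t3$value[t3$tissue == "Esophagus"], 1L)

  t5 <- load_paper_table("T5")
  expect_true(all(is.na(
    t5$value[t5$tissue %in% c("Blood vessel", "Esophagus", "Uterus")])))
  expect_false(anyNA(
    t5$value[!t5$tissue %in% c("Blood vessel", "Esophagus", "Uterus")]))

  t2 <- load_paper_table("T2")
  expect_null(t2$ids[[which(t2$tissue == "Adipose tissue")]])
  expect_identical(t2$value[t2$tissue == "Kidney"], 1L)
  expect_identical(attr(t2, "cell_sum"), 95L)

  expect_error(load_paper_table("T9"), "unknown table id")
})

test_that("edge list round trip preserves every field; empty list is header-only", {
  sem <- hub_sem()
  calls <- run_specificity(drop_zero_median(tissue_medians(sem), quiet = TRUE))
  nw <- build_network(sem, calls, "home")
  expect_gt(nw$n_edges, 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(nw, path)
  back <- read_edge_list(path)
  expect_equal(back, nw$edges)

  expect_warning(empty <- build_network(sem, calls, "away1"),
                 "samples; empty network")
  write_edge_list(empty, path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(nrow(read_edge_list(path)), 0L)
})

test_that("edge endpoints and rows follow the canonical order", {
  sem <- hub_sem(n_sat = 3, sat_bio = "mRNA", hub_bio = "miRNA")
  calls <- run_specificity(drop_zero_median(tissue_medians(sem), quiet = TRUE))
  nw <- build_network(sem, calls, "home")
  # miRNA precedes mRNA in every edge regardless of id
  expect_true(all(nw$edges$biotype_a == "miRNA"))
  expect_identical(nw$edges$rna_b, sort(nw$edges$rna_b))
})

test_that("GraphML export carries nodes, biotypes and edge weights", {
  sem <- hub_sem()
  calls <- run_specificity(drop_zero_median(tissue_medians(sem), quiet = TRUE))
  nw <- build_network(sem, calls, "home")
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(nw, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(g), 6)
  expect_equal(igraph::gsize(g), nw$n_edges, ignore_attr = TRUE)
  expect_setequal(igraph::V(g)$biotype, c("mRNA", "lncRNA"))
})
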