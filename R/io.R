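#' Read a sample-level expression matrix from TSV or GCT
#'
#' The TSV dialect has a header row of sample ids and an `rna_id` first
#' column. The GCT v1.2 dialect has the `#1.2` version line, a dimensions
#' line (`n_rnas<TAB>n_samples`) and `Name`/`Description` columns before the
#' samples; the `Description` column is ignored. Both dialects produce the
#' same object given the same values.
#'
#' @param path path to the expression file
#' @param format `"tsv"` or `"gct"`
#' @param sample_map data.frame with columns `sample_id`, `tissue`, or a path
#'   to a 2-column TSV with that header
#' @param annotation data.frame with columns `rna_id`, `biotype`,
#'   `is_pseudogene`, or a path to a 3-column TSV with that header
#' @param on_missing `"error"` (default: NA cells abort) or `"zero"` (NA cells
#'   become 0 with a warning)
#' @return a validated [sample_expression_matrix()]
#' @export
read_expression_matrix <- function(path, format = c("tsv", "gct"),
                                   sample_map, annotation,
                                   on_missing = c("error", "zero")) {
  format <- match.arg(format)
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)

  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2 || names(tab)[1] != "rna_id")
      stop("malformed header: expected 'rna_id' then one column per sample",
           call. = FALSE)
    ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -1, drop = FALSE])
  } else {
    lines <- readLines(path)
    if (length(lines) < 3 || !startsWith(lines[1], "#1.2"))
      stop("malformed GCT: first line must be '#1.2'", call. = FALSE)
    dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    if (length(dims) < 2 || anyNA(dims[1:2]))
      stop("malformed GCT: second line must give dimensions", call. = FALSE)
    tab <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3 || tolower(names(tab)[1]) != "name")
      stop("malformed GCT header: expected Name, Description, then samples",
           call. = FALSE)
    ids <- as.character(tab[[1]])
    values <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (nrow(values) != dims[1] || ncol(values) != dims[2])
      stop(sprintf("GCT declares %d x %d but file holds %d x %d",
                   dims[1], dims[2], nrow(values), ncol(values)),
           call. = FALSE)
  }
  storage.mode(values) <- "double"
  rownames(values) <- ids
  if (anyNA(values)) {
    if (on_missing == "error")
      stop("missing expression values present; set on_missing = \"zero\" to coerce",
           call. = FALSE)
    warning("coercing ", sum(is.na(values)), " missing values to 0")
    values[is.na(values)] <- 0
  }

  sm <- .as_table(sample_map, c("sample_id", "tissue"))
  an <- .as_table(annotation, c("rna_id", "biotype", "is_pseudogene"))
  missing_samples <- setdiff(colnames(values), sm$sample_id)
  if (length(missing_samples) > 0)
    stop("sample(s) with no tissue in the sample map: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  missing_rnas <- setdiff(ids, an$rna_id)
  if (length(missing_rnas) > 0)
    stop("RNA(s) with no annotation: ",
         paste(utils::head(missing_rnas, 5), collapse = ", "), call. = FALSE)
  an <- an[match(ids, an$rna_id), ]
  tissue <- stats::setNames(sm$tissue, sm$sample_id)[colnames(values)]

  sample_expression_matrix(
    values, biotype = an$biotype, tissue = tissue,
    is_pseudogene = .parse_flag(an$is_pseudogene))
}

.as_table <- function(x, cols) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("no such file: ", x, call. = FALSE)
    x <- utils::read.delim(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || !all(cols %in% names(x)))
    stop("expected a table with columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  x
}

.parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- x %in% c("true", "t", "1", "yes")
  bad <- !(x %in% c("true", "t", "1", "yes", "false", "f", "0", "no"))
  if (any(bad))
    stop("unparseable is_pseudogene value(s): ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  out
}

#' Write an expression matrix (plus sidecar tables) as TSV
#'
#' Emits `<stem>.tsv` (rna_id + samples), `<stem>_samples.tsv`
#' (sample_id, tissue) and `<stem>_annotation.tsv`
#' (rna_id, biotype, is_pseudogene) — the formats [read_expression_matrix()]
#' accepts.
#'
#' @param x a `SampleExpressionMatrix`
#' @param stem output path stem (no extension)
#' @return invisibly, the three paths written
#' @export
write_expression_matrix <- function(x, stem) {
  stopifnot(inherits(x, "SampleExpressionMatrix"))
  paths <- paste0(stem, c(".tsv", "_samples.tsv", "_annotation.tsv"))
  utils::write.table(
    data.frame(rna_id = rownames(x$values), x$values, check.names = FALSE),
    paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(x$tissue), tissue = unname(x$tissue)),
    paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(rna_id = names(x$biotype), biotype = unname(x$biotype),
               is_pseudogene = unname(x$is_pseudogene)),
    paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# ---- paper table fixtures ---------------------------------------------------

PAPER_TABLE_FILES <- c(
  T1 = "table1_sample_counts.tsv",
  T2 = "table2_ts_mirnas.tsv",
  T3 = "table3_ts_lncrna_counts.tsv",
  T4 = "table4_ts_mrna_counts.tsv",
  T5 = "table5_interaction_counts.tsv")

#' Load a packaged printed-table fixture
#'
#' Five per-tissue tables over the same 30 tissues ship with the package:
#' `T1` sample counts, `T2` tissue-specific miRNA identifier lists, `T3`/`T4`
#' tissue-specific lncRNA/mRNA counts, `T5` co-expression interaction counts.
#' Cells printed as an em-dash are stored as absent and come back as `NA`
#' (counts) or `NULL` (identifier lists), never silently as zero.
#'
#' @param table_id one of `"T1"`, `"T2"`, `"T3"`, `"T4"`, `"T5"`
#' @return a data.frame of class `PaperTableFixture` with columns `tissue` and
#'   `value` (integer, `NA` for absent cells) — for `T2`, `ids` (a list column
#'   of identifier vectors) and `value` (their lengths). Attributes:
#'   `table_id`, `printed_total` (the total as printed), `cell_sum` (the sum
#'   of present cells, recomputed on load).
#' @export
load_paper_table <- function(table_id) {
  if (!table_id %in% names(PAPER_TABLE_FILES))
    stop("unknown table id '", table_id, "'; expected one of ",
         paste(names(PAPER_TABLE_FILES), collapse = ", "), call. = FALSE)
  path <- system.file("extdata", PAPER_TABLE_FILES[[table_id]],
                      package = "tsnets", mustWork = TRUE)
  first <- readLines(path, n = 1)
  printed_total <- as.numeric(strsplit(sub("^#\\s*", "", first), "\t")[[1]][2])
  lines <- readLines(path)[-(1:2)]  # drop metadata + header
  parts <- strsplit(lines, "\t")
  tissue <- vapply(parts, `[`, "", 1)
  raw <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_,
                "")
  if (table_id == "T2") {
    ids <- lapply(raw, function(s) {
      if (is.na(s) || !nzchar(s)) NULL else strsplit(s, ",")[[1]]
    })
    out <- data.frame(tissue = tissue, stringsAsFactors = FALSE)
    out$ids <- ids
    out$value <- ifelse(vapply(ids, is.null, TRUE), NA_integer_,
                        lengths(ids))
  } else {
    out <- data.frame(tissue = tissue,
                      value = suppressWarnings(as.integer(raw)),
                      stringsAsFactors = FALSE)
  }
  structure(out,
            class = c("PaperTableFixture", "data.frame"),
            table_id = table_id,
            printed_total = printed_total,
            cell_sum = sum(out$value, na.rm = TRUE))
}

# ---- edge lists and GraphML -------------------------------------------------

EDGE_COLS <- c("tissue", "rna_a", "biotype_a", "rna_b", "biotype_b",
               "pearson_r", "n_samples")

#' Write per-tissue co-expression edges as a TSV edge list
#'
#' Columns: tissue, rna_a, biotype_a, rna_b, biotype_b, pearson_r, n_samples.
#' Endpoint order within an edge and row order are canonical (biotype
#' precedence miRNA < lncRNA < mRNA, then lexicographic RNA id), so repeated
#' runs diff cleanly. An empty network yields a header-only file.
#'
#' @param network a `TissueNetwork` or a list of them
#' @param path output TSV path
#' @return invisibly, `path`
#' @seealso [read_edge_list()], [write_graphml()]
#' @export
write_edge_list <- function(network, path) {
  edges <- .collect_edges(network)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an edge list written by [write_edge_list()]
#' @param path TSV path
#' @return data.frame with the canonical edge columns
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(pearson_r = "numeric",
                                          n_samples = "integer"))
  if (!identical(names(tab), EDGE_COLS))
    stop("not an edge list (columns must be: ",
         paste(EDGE_COLS, collapse = ", "), ")", call. = FALSE)
  tab
}

.collect_edges <- function(network) {
  if (inherits(network, "TissueNetwork")) network <- list(network)
  edges <- do.call(rbind, lapply(network, function(nw) nw$edges))
  if (is.null(edges))
    edges <- stats::setNames(
      data.frame(character(), character(), character(), character(),
                 character(), numeric(), integer(),
                 stringsAsFactors = FALSE), EDGE_COLS)
  edges
}

#' Export a tissue network as GraphML
#'
#' Nodes carry a `biotype` attribute; edges carry `pearson_r` and
#' `n_samples`. Delegated to igraph's GraphML writer.
#'
#' @param network a `TissueNetwork`
#' @param path output `.graphml` path
#' @return invisibly, `path`
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "TissueNetwork"))
  e <- network$edges
  nodes <- unique(data.frame(
    name = c(e$rna_a, e$rna_b),
    biotype = c(e$biotype_a, e$biotype_b),
    stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(
    e[, c("rna_a", "rna_b", "pearson_r", "n_samples")],
    directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
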