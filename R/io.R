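#' @name hbnet-io
#' @title File formats used by the workflow
#' @description
#' All readers and writers use UTF-8, `.` as decimal separator and
#' mandatory header rows. Expression matrices are TSV with a `gene` first
#' column and `<patient>_T1` / `<patient>_T2` sample columns; cohort and
#' Ct tables are CSV; gene panels are plain text, one symbol per line
#' (whitespace-stripped, matched case-sensitively); graphs are written
#' both as a TSV edge list (`gene_a`, `gene_b`, `r`, `p`, plus a `#`
#' node-list header line preserving isolated nodes) and as GraphML.
#' Numbers are formatted with up to 15 significant digits so that
#' write-read-write round trips are byte-identical.
NULL

fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 15, trim = TRUE,
                                   scientific = FALSE)
  }, character(1))
}

check_numeric_cells <- function(cells, rows, cols, file) {
  suppressWarnings(num <- as.numeric(cells))
  bad <- which(is.na(num) & !cells %in% c("NA", ""))
  if (length(bad))
    stop("non-numeric cell(s) in ", file, " at (row, column): ",
         paste(sprintf("(%d, %s)", rows[bad], cols[bad]), collapse = ", "),
         call. = FALSE)
  num
}

#' Write / read an expression matrix as TSV
#'
#' @param em An [expression_matrix()].
#' @param path File path.
#' @return `read_expression_tsv()` returns an [expression_matrix()];
#'   `write_expression_tsv()` returns `path` invisibly.
#' @rdname expression-tsv
#' @export
write_expression_tsv <- function(em, path) {
  stopifnot(inherits(em, "expr_matrix"))
  header <- paste(c("gene", colnames(em$values)), collapse = "\t")
  body <- vapply(seq_len(nrow(em$values)), function(i)
    paste(c(rownames(em$values)[i], fmt_num(em$values[i, ])),
          collapse = "\t"), character(1))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname expression-tsv
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  if (header[1] != "gene")
    stop("expression TSV must start with a 'gene' column", call. = FALSE)
  nf <- length(header)
  bad <- which(vapply(fields[-1], length, integer(1)) != nf)
  if (length(bad))
    stop("malformed row(s) in ", path, " at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  genes <- vapply(fields[-1], `[`, character(1), 1L)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "),
         call. = FALSE)
  cells <- unlist(lapply(fields[-1], `[`, -1L))
  rows <- rep(seq_along(genes) + 1L, each = nf - 1L)
  cols <- rep(header[-1], length(genes))
  vals <- matrix(check_numeric_cells(cells, rows, cols, path),
                 nrow = length(genes), byrow = TRUE,
                 dimnames = list(genes, header[-1]))
  expression_matrix(vals)
}

#' Write / read a cohort table as CSV
#'
#' @param cohort Cohort data.frame (see [simulate_cohort()]).
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort data.frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @rdname cohort-csv
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cohort
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname cohort-csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "group", "sex", "hb_count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cohort CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (v in setdiff(names(df), c("id", "group", "sex"))) {
    if (all(df[[v]] %in% c("TRUE", "FALSE"))) {
      df[[v]] <- df[[v]] == "TRUE"
    } else {
      df[[v]] <- check_numeric_cells(df[[v]], seq_len(nrow(df)) + 1L,
                                     rep(v, nrow(df)), path)
    }
  }
  df
}

#' Write / read a gene panel as plain text
#'
#' One symbol per line; surrounding whitespace is stripped, blank lines
#' dropped, symbols matched case-sensitively.
#'
#' @param panel Character vector of gene symbols.
#' @param path File path.
#' @return `read_panel()` returns a character vector; `write_panel()`
#'   returns `path` invisibly.
#' @rdname panel-io
#' @export
write_panel <- function(panel, path) {
  writeLines(panel, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname panel-io
#' @export
read_panel <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8"))
  x[nzchar(x)]
}

#' Write / read a gene co-expression graph
#'
#' The TSV form is an edge list (`gene_a`, `gene_b`, `r`, `p`) preceded by
#' a `#nodes` comment line carrying the full node set, so isolated nodes
#' survive the round trip. `write_graph_graphml()` delegates to igraph's
#' GraphML writer.
#'
#' @param graph An igraph graph with `r` and `p` edge attributes.
#' @param path File path.
#' @return Readers return an igraph graph; writers return `path`
#'   invisibly.
#' @rdname graph-io
#' @export
write_graph_tsv <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  lines <- c(paste0("#nodes\t", paste(igraph::V(graph)$name,
                                      collapse = "\t")),
             paste(c("gene_a", "gene_b", "r", "p"), collapse = "\t"))
  if (nrow(el))
    lines <- c(lines, paste(el$from, el$to, fmt_num(el$r), fmt_num(el$p),
                            sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname graph-io
#' @export
read_graph_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2 || !startsWith(lines[1], "#nodes"))
    stop("not a graph TSV (missing #nodes header): ", path, call. = FALSE)
  nodes <- strsplit(lines[1], "\t", fixed = TRUE)[[1]][-1]
  el <- if (length(lines) > 2) {
    f <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
    bad <- which(vapply(f, length, integer(1)) != 4L)
    if (length(bad))
      stop("malformed edge row(s) at line(s): ",
           paste(bad + 2L, collapse = ", "), call. = FALSE)
    data.frame(from = vapply(f, `[`, character(1), 1),
               to = vapply(f, `[`, character(1), 2),
               r = as.numeric(vapply(f, `[`, character(1), 3)),
               p = as.numeric(vapply(f, `[`, character(1), 4)),
               stringsAsFactors = FALSE)
  } else data.frame(from = character(0), to = character(0),
                    r = numeric(0), p = numeric(0))
  igraph::graph_from_data_frame(el, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

#' @rdname graph-io
#' @export
write_graph_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname graph-io
#' @export
read_graph_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' Write / read a qPCR Ct table as CSV
#'
#' @param table Ct table `data.frame(sample, group, gene, ct,
#'   is_reference)`.
#' @param path File path.
#' @return `read_ct_csv()` returns the Ct table; `write_ct_csv()` returns
#'   `path` invisibly.
#' @rdname ct-csv
#' @export
write_ct_csv <- function(table, path) {
  df <- table
  df$ct <- fmt_num(df$ct)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ct-csv
#' @export
read_ct_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("sample", "group", "gene", "ct", "is_reference")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("Ct CSV missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$ct <- check_numeric_cells(df$ct, seq_len(nrow(df)) + 1L,
                               rep("ct", nrow(df)), path)
  df$is_reference <- df$is_reference == "TRUE"
  df
}
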