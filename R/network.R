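#' Panel genes expressed in at least one sample
#'
#' Applies the study's expression filter to a gene panel: a panel gene is
#' kept when it is present in the matrix and has at least one value over 0
#' across all samples. Order follows the panel.
#'
#' @param matrix An [expression_matrix()].
#' @param panel Character vector of gene symbols (non-empty).
#' @return Character vector of expressed panel genes (possibly empty, with
#'   a warning).
#' @export
filter_expressed <- function(matrix, panel) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (!length(panel)) stop("panel is empty", call. = FALSE)
  present <- panel[panel %in% rownames(matrix$values)]
  keep <- present[apply(matrix$values[present, , drop = FALSE], 1,
                        function(r) max(r) > 0)]
  if (!length(keep)) warning("no panel gene passes the expression filter")
  keep
}

#' Pearson correlation edge test
#'
#' Sample Pearson correlation between two expression profiles with the
#' analytic two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2
#' degrees of freedom (via [stats::cor.test()]). A constant vector makes
#' the correlation undefined: the pair is skipped with `r = p = NA` and a
#' warning.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return List with `r`, `p.value`, `n`.
#' @export
pearson_edge <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors with n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined, pair skipped")
    return(list(r = NA_real_, p.value = NA_real_, n = length(x)))
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p.value = ht$p.value, n = length(x))
}

#' Build the hemoglobin-panel co-expression network
#'
#' Computes the Pearson correlation for every unordered pair of expressed
#' panel genes over all samples (patients and timepoints pooled) and keeps
#' the pairs with p-value not over `alpha` as edges. No multiple-testing
#' correction is applied by default, matching the raw p <= 0.05 edge rule
#' of the workflow; set `adjust = "BH"` to filter on adjusted p instead.
#' Genes whose profile is constant are kept as isolated nodes (they pass
#' the expression filter) with all their pairs skipped.
#'
#' @param matrix An [expression_matrix()] with at least 3 samples.
#' @param panel Character vector of panel gene symbols.
#' @param alpha Edge p-value threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An [igraph][igraph::igraph-package] undirected graph whose
#'   vertices are the expressed panel genes and whose edges carry `r` and
#'   `p` attributes; graph attributes `alpha` and `n_tests` record the
#'   threshold and the number of correlation tests performed.
#' @export
build_hb_network <- function(matrix, panel, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (ncol(matrix$values) < 3)
    stop("need at least 3 samples to build the network", call. = FALSE)
  adjust <- match.arg(adjust, c("none", "BH"))
  genes <- filter_expressed(matrix, panel)
  k <- length(genes)
  vals <- matrix$values[genes, , drop = FALSE]
  constant <- apply(vals, 1, function(r) stats::sd(r) == 0)
  ea <- eb <- character(0); er <- ep <- numeric(0)
  n_tests <- 0L
  if (k >= 2) {
    pr <- pp <- matrix(NA_real_, k, k)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        n_tests <- n_tests + 1L
        if (constant[i] || constant[j]) next
        ht <- stats::cor.test(vals[i, ], vals[j, ], method = "pearson")
        pr[i, j] <- unname(ht$estimate)
        pp[i, j] <- ht$p.value
      }
    }
    idx <- which(!is.na(pp), arr.ind = TRUE)
    pv <- pp[idx]
    pv_f <- if (adjust == "BH") stats::p.adjust(pv, "BH") else pv
    keep <- pv_f <= alpha
    ea <- genes[idx[keep, 1]]; eb <- genes[idx[keep, 2]]
    er <- pr[idx][keep]; ep <- pv[keep]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb, r = er, p = ep,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g <- igraph::set_graph_attr(g, "n_tests", n_tests)
  g
}

new_network_layer <- function(layer, graph, seeds, nodes) {
  structure(list(layer = layer,
                 graph = igraph::induced_subgraph(graph, nodes),
                 seeds = seeds, nodes = nodes),
            class = "network_layer")
}

#' @export
print.network_layer <- function(x, ...) {
  cat(x$layer, "layer:", length(x$nodes), "nodes,",
      igraph::ecount(x$graph), "edges,", length(x$seeds), "seeds\n")
  invisible(x)
}

#' Extract the candidate (CHB) seed-neighborhood subnetwork
#'
#' Keeps the seed genes (the common DEGs) and every gene directly
#' connected to a seed in the co-expression network, with the induced
#' edges. Seeds absent from the network are retained as isolated nodes
#' with a warning.
#'
#' @param graph Co-expression graph from [build_hb_network()].
#' @param seeds Non-empty character vector of seed gene symbols.
#' @return A `network_layer` object (`layer = "CHB"`) holding the induced
#'   subgraph, its node set and the seed set.
#' @export
extract_chb <- function(graph, seeds) {
  if (!length(seeds)) stop("empty seed set", call. = FALSE)
  missing <- setdiff(seeds, igraph::V(graph)$name)
  if (length(missing)) {
    warning("seed(s) not in the network, kept as isolated nodes: ",
            paste(missing, collapse = ", "))
    graph <- igraph::add_vertices(graph, length(missing), name = missing)
  }
  nbr <- unlist(lapply(seeds, function(s)
    igraph::V(graph)$name[as.integer(igraph::neighbors(graph, s))]))
  nodes <- igraph::V(graph)$name[igraph::V(graph)$name %in%
                                   union(seeds, nbr)]
  new_network_layer("CHB", graph, seeds, nodes)
}

#' Extend the CHB layer by one further neighborhood step (ECHB)
#'
#' Maps the CHB nodes back into the full co-expression network and adds
#' every gene connected to any of them, with induced edges; the result is
#' the extended candidate (ECHB) subnetwork whose genes are scored as
#' candidate biomarkers.
#'
#' @param graph The same co-expression graph the CHB layer was built from.
#' @param chb A `network_layer` from [extract_chb()].
#' @return A `network_layer` object (`layer = "ECHB"`).
#' @export
extend_echb <- function(graph, chb) {
  stopifnot(inherits(chb, "network_layer"))
  known <- union(igraph::V(graph)$name, chb$seeds)
  if (!all(chb$nodes %in% known))
    stop("CHB layer does not match this graph", call. = FALSE)
  missing <- setdiff(chb$nodes, igraph::V(graph)$name)
  if (length(missing))
    graph <- igraph::add_vertices(graph, length(missing), name = missing)
  inb <- chb$nodes[chb$nodes %in% igraph::V(graph)$name]
  nbr <- unlist(lapply(inb, function(s)
    igraph::V(graph)$name[as.integer(igraph::neighbors(graph, s))]))
  nodes <- igraph::V(graph)$name[igraph::V(graph)$name %in%
                                   union(chb$nodes, nbr)]
  new_network_layer("ECHB", graph, chb$seeds, nodes)
}

#' Topological summary of a gene graph
#'
#' Minimal topology report: per-node degree, node and edge counts, and
#' connected-component sizes.
#'
#' @param graph An igraph graph (non-empty).
#' @return List with `n_nodes`, `n_edges`, `degree` (named vector) and
#'   `component_sizes`.
#' @export
topology_summary <- function(graph) {
  if (igraph::vcount(graph) == 0) stop("empty graph", call. = FALSE)
  comp <- igraph::components(graph)
  list(n_nodes = igraph::vcount(graph),
       n_edges = igraph::ecount(graph),
       degree = igraph::degree(graph),
       component_sizes = unname(comp$csize))
}
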