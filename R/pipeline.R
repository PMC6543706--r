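#' Run the full anemia / stroke-recovery analysis pipeline
#'
#' Executes the workflow end to end on a simulated study (or on
#' caller-supplied tables): cohort baseline statistics, per-patient
#' two-timepoint DEG calling, common-DEG intersection, hemoglobin
#' co-expression network construction, CHB and ECHB seed-neighborhood
#' extraction, ECS scoring with outcome-concordance classification and,
#' optionally, delta-delta-Ct qPCR validation. If the common-DEG
#' intersection is empty the pipeline stops cleanly after that stage with
#' an explanatory report rather than an error.
#'
#' @param config A [sim_config()]; drives the synthetic inputs and the
#'   seed.
#' @param alpha Edge p-value threshold for the co-expression network.
#' @param q_threshold FDR threshold for DEG calling.
#' @param min_concordant Concordance threshold for [classify_correlation()]
#'   (`NULL` = 3/4 rule).
#' @param run_qpcr Include the qPCR validation stage.
#' @param out_dir Optional directory: stage outputs are written there
#'   (TSV/CSV/GraphML) with MD5 checksums and a JSON run report; on a
#'   stage failure a `FAILED` marker naming the stage is left behind.
#' @param cohort,matrix,ct Optional pre-built inputs overriding the
#'   simulated ones.
#' @return A run report: list with per-stage results and row counts, the
#'   config, and `completed` (stage names in execution order).
#' @export
run_pipeline <- function(config = sim_config(), alpha = 0.05,
                         q_threshold = 0.05, min_concordant = NULL,
                         run_qpcr = TRUE, out_dir = NULL,
                         cohort = NULL, matrix = NULL, ct = NULL) {
  report <- list(config = config, completed = character(0), stages = list())
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    report$completed <<- c(report$completed, name)
    res
  }
  emit <- function(fname, writer, obj) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, fname)
    writer(obj, path)
    invisible(path)
  }

  cohort <- stage("simulate_cohort",
                  if (is.null(cohort)) simulate_cohort(config) else cohort)
  emit("cohort.csv", write_cohort_csv, cohort)
  baseline <- stage("cohort_stats", baseline_table(cohort))
  report$stages$baseline <- baseline

  em <- stage("simulate_expression",
              if (is.null(matrix)) simulate_expression(config) else matrix)
  emit("expression.tsv", write_expression_tsv, em)

  patients <- unique(em$samples$patient)
  degs <- stage("deg_calling", lapply(patients, function(p)
    call_degs(em, p, q_threshold = q_threshold)))
  names(degs) <- patients
  deg_sets <- lapply(degs, function(d) d$gene[d$called])
  report$stages$deg_counts <- vapply(deg_sets, length, integer(1))

  nonempty <- deg_sets[vapply(deg_sets, length, integer(1)) > 0]
  seeds <- stage("common_degs",
                 if (length(nonempty) >= 2) common_degs(nonempty)
                 else character(0))
  report$stages$common_degs <- seeds
  if (!length(seeds)) {
    report$stages$stopped <- paste(
      "no common DEGs across patients; candidate-biomarker stages skipped")
    finalize_report(report, out_dir)
    return(report)
  }

  panel <- hb_panel(config)
  graph <- stage("hb_network", build_hb_network(em, panel, alpha = alpha))
  emit("hb_network.tsv", write_graph_tsv, graph)
  emit("hb_network.graphml", write_graph_graphml, graph)
  report$stages$hb_network <- list(n_nodes = igraph::vcount(graph),
                                   n_edges = igraph::ecount(graph))

  chb <- stage("chb", suppressWarnings(extract_chb(graph, seeds)))
  echb <- stage("echb", extend_echb(graph, chb))
  report$stages$layers <- data.frame(
    layer = c("HB", "CHB", "ECHB"),
    n_nodes = c(igraph::vcount(graph), length(chb$nodes),
                length(echb$nodes)),
    stringsAsFactors = FALSE)
  report$stages$topology <- topology_summary(echb$graph)

  etab <- stage("ecs", ecs_table(em, echb$nodes))
  outcomes <- sim_outcomes(config)
  cls <- stage("classification",
               classify_correlation(etab, outcomes,
                                    min_concordant = min_concordant))
  report$stages$ecs <- etab
  report$stages$classification <- cls

  if (run_qpcr) {
    ctab <- stage("simulate_qpcr",
                  if (is.null(ct)) simulate_qpcr(config) else ct)
    emit("qpcr_ct.csv", write_ct_csv, ctab)
    rel <- stage("qpcr", relative_expression(ctab))
    genes <- unique(rel$gene)
    report$stages$qpcr <- list(
      tests = do.call(rbind, lapply(genes, function(g) {
        w <- wilcoxon_group_test(rel, "ISA", "control", g)
        data.frame(gene = g, W = w$statistic, p = w$p.value,
                   stringsAsFactors = FALSE)
      })),
      ranks = lapply(stats::setNames(genes, genes), function(g)
        group_rank_profile(rel, g)$ranking))
  }
  finalize_report(report, out_dir)
  report
}

finalize_report <- function(report, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  files <- setdiff(list.files(out_dir), c("run_report.json", "FAILED"))
  sums <- tools::md5sum(file.path(out_dir, files))
  payload <- list(
    r_version = as.character(getRversion()),
    seed = report$config$seed,
    completed = report$completed,
    deg_counts = as.list(report$stages$deg_counts),
    common_degs = report$stages$common_degs,
    checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(payload, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
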