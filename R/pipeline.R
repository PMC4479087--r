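#' Assemble a validated pipeline configuration
#'
#' Collects file paths and stage thresholds for [run_pipeline()]. The
#' defaults are the standard analysis cutoffs: 3'UTR >= 1250 bp, junction
#' > 50 nt, q <= 0.05, fold change > 1.5 or < 0.67, Bayes factor > 10,
#' delta-psi > 0.2, read floor 20, enrichment alpha 0.05.
#'
#' @param gtf path to the GTF annotation.
#' @param expression path to the expression TSV (see
#'   [read_expression_table()]).
#' @param gmt optional path to a GMT gene-set collection; enrichment is
#'   skipped when `NULL`.
#' @param events optional path to a splicing-event TSV; the splicing stage
#'   is skipped when `NULL`.
#' @param out_dir directory for intermediate TSVs and the JSON report.
#' @param utr3_min_bp,junction_min_nt NMD rule thresholds.
#' @param q_max,up_min,down_max,pseudocount DE filter thresholds.
#' @param bf_min,dpsi_min,min_reads splicing filter thresholds.
#' @param alpha enrichment significance level.
#' @param universe_policy `"detected"` (genes with nonzero FPKM in either
#'   condition; default) or `"annotated"` (every gene in the GTF).
#' @param cds_includes_stop GTF dialect flag for stop-codon resolution.
#' @param gene_aggregation transcript-to-gene NMD policy, `"any"` or
#'   `"all"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(gtf, expression, gmt = NULL, events = NULL,
                            out_dir = tempfile("nmdscope_"),
                            utr3_min_bp = 1250, junction_min_nt = 50,
                            q_max = 0.05, up_min = 1.5, down_max = 0.67,
                            pseudocount = 0,
                            bf_min = 10, dpsi_min = 0.2, min_reads = 20,
                            alpha = 0.05,
                            universe_policy = c("detected", "annotated"),
                            cds_includes_stop = TRUE,
                            gene_aggregation = c("any", "all")) {
  cfg <- list(gtf = gtf, expression = expression, gmt = gmt, events = events,
              out_dir = out_dir,
              utr3_min_bp = utr3_min_bp, junction_min_nt = junction_min_nt,
              q_max = q_max, up_min = up_min, down_max = down_max,
              pseudocount = pseudocount,
              bf_min = bf_min, dpsi_min = dpsi_min, min_reads = min_reads,
              alpha = alpha,
              universe_policy = match.arg(universe_policy),
              cds_includes_stop = isTRUE(cds_includes_stop),
              gene_aggregation = match.arg(gene_aggregation))
  for (f in c("gtf", "expression", "gmt", "events"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stopf("configured %s file does not exist: %s", f, cfg[[f]])
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys are an
#' error. Values given in the YAML override the defaults.
#'
#' @param path YAML file path.
#' @param ... overrides applied on top of the file (CLI precedence).
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full interpretation pipeline
#'
#' Executes the stages in dependency order: parse the annotation, classify
#' NMD susceptibility per transcript and aggregate to genes, filter the
#' expression table for differential expression, partition DE genes by
#' biotype, intersect DE genes with NMD-prone genes, cross-reference DE
#' genes with the gene-set collection (when given), and filter/summarize
#' splicing events (when given). Every intermediate is written to
#' `out_dir` as TSV and the report as `report.json`. Outputs carry no
#' timestamps, so identical inputs and configuration give byte-identical
#' files. Any stage error is re-raised with the stage name prepended.
#'
#' @param config a [pipeline_config()].
#' @return the report, a nested list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  models <- stage("annotation", parse_gtf(config$gtf))
  calls <- stage("nmd_classification", {
    tab <- nmd_call_table(models, utr3_min_bp = config$utr3_min_bp,
                          junction_min_nt = config$junction_min_nt,
                          cds_includes_stop = config$cds_includes_stop)
    write_tsv(tab, out("nmd_transcripts.tsv"))
    tab
  })
  gene_nmd <- stage("nmd_gene_aggregation", {
    g <- gene_level_nmd(calls, policy = config$gene_aggregation)
    write_tsv(g, out("nmd_genes.tsv"))
    g
  })
  expr <- stage("expression_input", read_expression_table(config$expression))
  de <- stage("de_filter", {
    d <- filter_de(expr, q_max = config$q_max, up_min = config$up_min,
                   down_max = config$down_max,
                   pseudocount = config$pseudocount)
    write_tsv(d, out("de_genes.tsv"))
    d
  })
  breakdown <- stage("biotype_breakdown", {
    b <- biotype_breakdown(de, gene_biotypes(models))
    write_tsv(b, out("biotype_breakdown.tsv"))
    b
  })
  nmd_de <- stage("de_nmd_intersection",
                  intersect_de_nmd(de, gene_nmd))

  annotated_genes <- unique(vapply(models, `[[`, character(1L), "gene_id"))
  detected_genes <- expr$gene_id[expr$fpkm_control > 0 | expr$fpkm_case > 0]

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    enrichment <- stage("enrichment", {
      if (nrow(de) == 0L) stopf("empty query: no DE genes to cross-reference")
      universe <- if (config$universe_policy == "detected")
        detected_genes else annotated_genes
      res <- cross_reference(de$gene_id, read_gmt(config$gmt), universe,
                             alpha = config$alpha)
      write_tsv(res, out("enrichment.tsv"))
      res
    })
  }

  splicing <- NULL
  if (!is.null(config$events)) {
    splicing <- stage("splicing_summary", {
      ev <- read_splicing_events(config$events)
      sig <- filter_events(ev, bf_min = config$bf_min,
                           dpsi_min = config$dpsi_min,
                           min_reads = config$min_reads)
      write_tsv(sig, out("splicing_events_significant.tsv"))
      s <- summarize_events(sig)
      write_tsv(s$proportions, out("splicing_summary.tsv"))
      s
    })
  }

  report <- list(
    tool = list(name = "nmdscope",
                version = as.character(utils::packageVersion("nmdscope"))),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(unlist(
      config[c("gtf", "expression", "gmt", "events")], use.names = FALSE))),
    n_annotated_genes = length(annotated_genes),
    n_detected_genes = length(unique(detected_genes)),
    de = list(n_de_genes = nrow(de),
              n_up = sum(de$direction == "up"),
              n_down = sum(de$direction == "down"),
              fraction_of_annotated = list(
                numerator = nrow(de), denominator = length(annotated_genes),
                value = nrow(de) / length(annotated_genes)),
              fraction_of_detected = list(
                numerator = nrow(de),
                denominator = length(unique(detected_genes)),
                value = nrow(de) / length(unique(detected_genes)))),
    biotype_breakdown = breakdown,
    nmd = list(n_de_nmd_prone = nmd_de$n_prone,
               n_de = nmd_de$n_de,
               fraction_de_nmd_prone = nmd_de$fraction),
    enrichment = enrichment,
    splicing = if (!is.null(splicing))
      list(n_events_significant = splicing$n_events,
           n_genes = splicing$n_genes,
           proportions = splicing$proportions))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(report)
}

#' Intersect DE genes with gene-level NMD calls
#'
#' Counts how many differentially expressed genes carry NMD-susceptibility
#' features (the "m of n DE genes are NMD-prone" computation).
#'
#' @param de DE data frame from [filter_de()] (or a character vector of DE
#'   gene ids).
#' @param gene_nmd data frame from [gene_level_nmd()].
#' @return list with `n_prone`, `n_de` and `fraction = n_prone / n_de`.
#' @export
intersect_de_nmd <- function(de, gene_nmd) {
  ids <- unique(if (is.character(de)) de else de$gene_id)
  if (length(ids) == 0L) stopf("empty DE set: nothing to intersect")
  prone_genes <- gene_nmd$gene_id[gene_nmd$prone]
  n_prone <- length(intersect(ids, prone_genes))
  list(n_prone = n_prone, n_de = length(ids),
       fraction = n_prone / length(ids))
}
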