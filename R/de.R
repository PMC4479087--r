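#' Read a two-condition gene expression table
#'
#' Accepts either a Cuffdiff `gene_exp.diff`-style table (columns `gene` or
#' `gene_id` or `test_id`, `value_1` = control FPKM, `value_2` = case FPKM,
#' optional `p_value`, `q_value`) or a minimal schema (`gene_id`,
#' `fpkm_control`, `fpkm_case`, optional `p_value`, `q_value`). The schema is
#' auto-detected from the header.
#'
#' @param path TSV file path.
#' @return a data frame with columns `gene_id`, `fpkm_control`, `fpkm_case`,
#'   `p_value` (NA when absent) and `q_value`.
#' @export
read_expression_table <- function(path) {
  d <- read_tsv(path)
  nm <- names(d)
  if ("value_1" %in% nm && "value_2" %in% nm) {
    idcol <- intersect(c("gene_id", "gene", "test_id"), nm)[1]
    if (is.na(idcol)) stopf("cuffdiff-style table lacks a gene id column")
    out <- data.frame(gene_id = as.character(d[[idcol]]),
                      fpkm_control = as.numeric(d$value_1),
                      fpkm_case = as.numeric(d$value_2),
                      p_value = if ("p_value" %in% nm) as.numeric(d$p_value) else NA_real_,
                      q_value = as.numeric(d$q_value),
                      stringsAsFactors = FALSE)
  } else if (all(c("gene_id", "fpkm_control", "fpkm_case", "q_value") %in% nm)) {
    out <- data.frame(gene_id = as.character(d$gene_id),
                      fpkm_control = as.numeric(d$fpkm_control),
                      fpkm_case = as.numeric(d$fpkm_case),
                      p_value = if ("p_value" %in% nm) as.numeric(d$p_value) else NA_real_,
                      q_value = as.numeric(d$q_value),
                      stringsAsFactors = FALSE)
  } else {
    stopf("unrecognized expression table schema: columns %s",
          paste(nm, collapse = ", "))
  }
  validate_expression(out)
  out
}

validate_expression <- function(x) {
  if (any(x$fpkm_control < 0 | x$fpkm_case < 0, na.rm = TRUE))
    stopf("negative FPKM values in expression table")
  if (any(x$q_value < 0 | x$q_value > 1, na.rm = TRUE))
    stopf("q-values outside [0, 1] in expression table")
  invisible(x)
}

#' Case/control fold change
#'
#' Fold change is the case FPKM divided by the control FPKM, optionally with
#' a pseudocount added to both. With pseudocount 0 a gene expressed only in
#' the case condition gets `Inf` (counts as upregulated); a gene with zero
#' FPKM in both conditions gets `NaN` (undefined; such records are excluded
#' from differential-expression calls).
#'
#' @param fpkm_case,fpkm_control non-negative FPKM vectors.
#' @param pseudocount non-negative value added to numerator and denominator.
#' @return numeric vector of fold changes.
#' @export
fold_change <- function(fpkm_case, fpkm_control, pseudocount = 0) {
  if (!is_number(pseudocount) || pseudocount < 0)
    stopf("pseudocount must be a non-negative number")
  (fpkm_case + pseudocount) / (fpkm_control + pseudocount)
}

#' Filter a gene expression table for differential expression
#'
#' Retains genes with `q_value <= q_max` and a fold change either strictly
#' above `up_min` (direction `up`) or strictly below `down_max` (direction
#' `down`). The defaults transcribe the standard two-condition cutoff:
#' q-value of 0.05 or less and greater than 1.5-fold up or less than
#' 0.67-fold down — the q boundary is inclusive, the fold-change boundaries
#' strict. Records with undefined fold change (0/0 at pseudocount 0) are
#' excluded; their count is attached as attribute `n_undefined_fc`.
#'
#' @param records expression data frame as from [read_expression_table()].
#' @param q_max maximum q-value (inclusive).
#' @param up_min fold change that upregulated genes must exceed.
#' @param down_max fold change that downregulated genes must be below.
#' @param pseudocount passed to [fold_change()].
#' @return data frame with `gene_id`, `fold_change`, `direction`
#'   (`"up"`/`"down"`), `q_value`.
#' @export
filter_de <- function(records, q_max = 0.05, up_min = 1.5, down_max = 0.67,
                      pseudocount = 0) {
  if (!is_number(q_max) || !is_number(up_min) || !is_number(down_max))
    stopf("thresholds must be finite numbers")
  if (up_min <= down_max)
    stopf("up_min (%.3g) must exceed down_max (%.3g)", up_min, down_max)
  validate_expression(records)
  fc <- fold_change(records$fpkm_case, records$fpkm_control, pseudocount)
  undefined <- is.nan(fc)
  keep <- !undefined & !is.na(records$q_value) & records$q_value <= q_max &
    (fc > up_min | fc < down_max)
  out <- data.frame(gene_id = records$gene_id[keep],
                    fold_change = fc[keep],
                    direction = ifelse(fc[keep] > up_min, "up", "down"),
                    q_value = records$q_value[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_undefined_fc") <- sum(undefined)
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment of a p-value vector, for input
#' tables that carry raw p-values but no q-values.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Gene biotypes from an annotation
#'
#' Gene-level biotype lookup built from transcript models. When transcripts
#' of one gene disagree (should not happen in a consistent annotation), the
#' first transcript's biotype wins and a warning is raised.
#'
#' @param models list of [transcript_model()] objects.
#' @return named character vector, gene id -> biotype.
#' @export
gene_biotypes <- function(models) {
  gid <- vapply(models, `[[`, character(1L), "gene_id")
  bt <- vapply(models, `[[`, character(1L), "gene_biotype")
  first <- !duplicated(gid)
  res <- stats::setNames(bt[first], gid[first])
  conflict <- tapply(bt, gid, function(v) length(unique(v)) > 1L)
  if (any(conflict))
    warnf("gene(s) with conflicting transcript biotypes: %s",
          paste(utils::head(names(conflict)[conflict], 3L), collapse = ", "))
  res
}

#' Partition differentially expressed genes by RNA biotype
#'
#' Counts DE genes per gene biotype and reports percentages of the DE set.
#' Pseudogene sub-biotypes (`processed_pseudogene`, `unitary_pseudogene`,
#' ...) are collapsed into a single `pseudogene` category by default; an
#' explicit `collapse_map` (named vector, raw biotype -> group) overrides
#' this. DE genes absent from the annotation are counted under `"unknown"`
#' with a warning.
#'
#' @param de DE data frame from [filter_de()] (or any data frame with a
#'   `gene_id` column, or a character vector of gene ids).
#' @param biotypes named biotype vector from [gene_biotypes()], or a list of
#'   transcript models.
#' @param collapse_map optional named character vector mapping raw biotypes
#'   to collapsed categories.
#' @return data frame with `biotype`, `n`, `percent` (summing to 100),
#'   ordered by decreasing count.
#' @export
biotype_breakdown <- function(de, biotypes, collapse_map = NULL) {
  ids <- if (is.character(de)) de else de$gene_id
  if (length(ids) == 0L)
    stopf("empty DE set: no genes to break down by biotype")
  if (is.list(biotypes)) biotypes <- gene_biotypes(biotypes)
  bt <- unname(biotypes[ids])
  if (anyNA(bt)) {
    warnf("%d DE gene(s) not found in the annotation; counted as 'unknown'",
          sum(is.na(bt)))
    bt[is.na(bt)] <- "unknown"
  }
  if (is.null(collapse_map)) {
    bt <- ifelse(grepl("pseudogene", bt), "pseudogene", bt)
  } else {
    hit <- bt %in% names(collapse_map)
    bt[hit] <- unname(collapse_map[bt[hit]])
  }
  counts <- sort(table(bt), decreasing = TRUE)
  data.frame(biotype = names(counts),
             n = as.integer(counts),
             percent = 100 * as.integer(counts) / length(ids),
             stringsAsFactors = FALSE, row.names = NULL)
}
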