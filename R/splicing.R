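EVENT_TYPES <- c("SE", "A3SS", "A5SS", "ALE", "AFE")

#' Read an alternative-splicing event table
#'
#' TSV with one row per event. Canonical columns are `event_id`, `gene_id`,
#' `event_type`, `psi_control`, `psi_case`, `bayes_factor`,
#' `informative_reads`; the MISO-summary aliases `event_name`, `psi_1`/
#' `psi_2` (or `sample1_posterior_mean`/`sample2_posterior_mean`), `bf` and
#' `counts` are accepted. `bayes_factor` may be `Inf`.
#'
#' @param path TSV file path.
#' @return validated data frame in canonical columns.
#' @export
read_splicing_events <- function(path) {
  d <- read_tsv(path)
  alias <- function(...) {
    for (nm in c(...)) if (nm %in% names(d)) return(d[[nm]])
    stopf("event table lacks a '%s' column (or an accepted alias)", ..1)
  }
  out <- data.frame(
    event_id = as.character(alias("event_id", "event_name")),
    gene_id = as.character(alias("gene_id", "gene")),
    event_type = as.character(alias("event_type", "type")),
    psi_control = as.numeric(alias("psi_control", "psi_1",
                                   "sample1_posterior_mean")),
    psi_case = as.numeric(alias("psi_case", "psi_2",
                                "sample2_posterior_mean")),
    bayes_factor = as.numeric(alias("bayes_factor", "bf")),
    informative_reads = as.integer(alias("informative_reads", "counts")),
    stringsAsFactors = FALSE)
  validate_events(out)
  out
}

validate_events <- function(e) {
  if (any(e$psi_control < 0 | e$psi_control > 1 |
          e$psi_case < 0 | e$psi_case > 1, na.rm = TRUE))
    stopf("psi values outside [0, 1]")
  bad <- setdiff(unique(e$event_type), EVENT_TYPES)
  if (length(bad))
    stopf("unknown event type(s): %s (expected %s)",
          paste(bad, collapse = ", "), paste(EVENT_TYPES, collapse = "/"))
  if (any(e$bayes_factor < 0, na.rm = TRUE))
    stopf("negative Bayes factors")
  if (any(e$informative_reads < 0, na.rm = TRUE))
    stopf("negative read counts")
  invisible(e)
}

#' Between-condition change in inclusion level
#'
#' `|psi_case - psi_control|` by default (the usual direction-free
#' delta-psi); `signed = TRUE` keeps the sign.
#'
#' @param psi_case,psi_control inclusion levels in `[0, 1]`.
#' @param signed return the signed difference?
#' @return numeric vector.
#' @export
delta_psi <- function(psi_case, psi_control, signed = FALSE) {
  d <- psi_case - psi_control
  if (signed) d else abs(d)
}

#' Filter splicing events for significance
#'
#' Keeps events with Bayes factor strictly greater than `bf_min`, delta-psi
#' strictly greater than `dpsi_min`, and at least `min_reads` informative
#' reads (the read floor stands in for the event-level read-coverage
#' thresholds of the upstream quantifier). Events with an infinite Bayes
#' factor pass the Bayes-factor criterion.
#'
#' @param events event data frame (see [read_splicing_events()]).
#' @param bf_min Bayes-factor threshold, exclusive (default 10).
#' @param dpsi_min delta-psi threshold, exclusive (default 0.2).
#' @param min_reads minimum informative reads, inclusive (default 20).
#' @param signed use signed delta-psi (events pass when the signed change
#'   exceeds `dpsi_min`)?
#' @return the retained rows, with a `delta_psi` column appended.
#' @export
filter_events <- function(events, bf_min = 10, dpsi_min = 0.2,
                          min_reads = 20, signed = FALSE) {
  if (!is_number(bf_min) || bf_min < 0 || !is_number(dpsi_min) ||
      dpsi_min < 0 || !is_count(min_reads))
    stopf("event-filter thresholds must be non-negative")
  validate_events(events)
  d <- delta_psi(events$psi_case, events$psi_control, signed = signed)
  keep <- events$bayes_factor > bf_min & d > dpsi_min &
    events$informative_reads >= min_reads
  keep[is.na(keep)] <- FALSE
  out <- events[keep, , drop = FALSE]
  out$delta_psi <- d[keep]
  rownames(out) <- NULL
  out
}

#' Summarize significant splicing events
#'
#' Event counts and percentages per event type (skipped exon, alternative
#' 3'/5' splice site, alternative last/first exon) plus the number of
#' distinct genes involved.
#'
#' @param events a non-empty (filtered) event data frame.
#' @return list with `n_events`, `n_genes` and `proportions`, a data frame
#'   of `event_type`, `n`, `percent` over all five event types (percentages
#'   sum to 100).
#' @export
summarize_events <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    stopf("empty event set: nothing to summarize")
  counts <- table(factor(events$event_type, levels = EVENT_TYPES))
  list(n_events = nrow(events),
       n_genes = length(unique(events$gene_id)),
       proportions = data.frame(
         event_type = EVENT_TYPES,
         n = as.integer(counts),
         percent = 100 * as.integer(counts) / nrow(events),
         stringsAsFactors = FALSE, row.names = NULL))
}
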