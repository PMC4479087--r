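#' Extract NMD-susceptibility features of a transcript
#'
#' Measures, in spliced (mature mRNA) coordinates, the three quantities that
#' the NMD-susceptibility rule reads:
#'
#' * `utr3_length` — number of exonic bases strictly 3' of the stop codon;
#' * `utr3_intron_count` — introns lying entirely within the 3'UTR, i.e.
#'   introns whose upstream flanking exon is itself entirely untranslated.
#'   The boundary intron directly following the stop-bearing exon is *not*
#'   counted here: it is assessed by the junction-distance rule, so the two
#'   rules stay independent;
#' * `max_junction_distance` — the largest spliced distance from the stop
#'   codon's 3'-most base to a downstream exon-exon junction (`NA` when no
#'   junction lies downstream). A junction's position is the spliced offset
#'   of the last exonic base 5' of it; its distance is that offset minus the
#'   stop's 3'-most offset.
#'
#' The stop codon is resolved from `stop_codon` features when present;
#' otherwise from the CDS, whose 3' end either includes the stop codon
#' (`cds_includes_stop = TRUE`, the Ensembl-style default) or is followed by
#' it (`FALSE`). Transcripts with neither CDS nor stop codon (non-coding
#' biotypes) are reported with `evaluable = FALSE` and zeroed features.
#'
#' @param t a [transcript_model()].
#' @param cds_includes_stop does the annotated CDS include the stop codon?
#'   Only consulted when no `stop_codon` features are annotated.
#' @return a list with elements `transcript_id`, `gene_id`, `evaluable`,
#'   `utr3_length`, `utr3_intron_count`, `max_junction_distance` (NA when
#'   absent) and `stop_offset` (spliced offset of the stop's 3'-most base;
#'   NA when not evaluable).
#' @export
extract_nmd_features <- function(t, cds_includes_stop = TRUE) {
  stopifnot(inherits(t, "transcript_model"))
  L <- spliced_length(t)
  blank <- list(transcript_id = t$transcript_id, gene_id = t$gene_id,
                evaluable = FALSE, utr3_length = 0L, utr3_intron_count = 0L,
                max_junction_distance = NA_integer_,
                stop_offset = NA_integer_)

  stop_off <- stop_codon_offset(t, cds_includes_stop)
  if (is.na(stop_off) || stop_off >= L) return(blank)

  juncs <- junction_spliced_offsets(t)
  downstream <- juncs[juncs > stop_off]
  mjd <- if (length(downstream)) max(downstream) - stop_off else NA_integer_

  # intron i separates transcript-order exons i and i+1; it lies entirely in
  # the 3'UTR when exon i starts after the stop codon's last base
  firsts <- exon_first_offsets_tx(t)
  n_ex <- length(firsts)
  utr_introns <- if (n_ex < 2L) 0L else
    sum(firsts[seq_len(n_ex - 1L)] > stop_off)

  list(transcript_id = t$transcript_id, gene_id = t$gene_id,
       evaluable = TRUE,
       utr3_length = L - stop_off - 1L,
       utr3_intron_count = as.integer(utr_introns),
       max_junction_distance = as.integer(mjd),
       stop_offset = as.integer(stop_off))
}

# spliced offset of the stop codon's 3'-most base, or NA when unresolvable
stop_codon_offset <- function(t, cds_includes_stop) {
  if (nrow(t$stop_codon) > 0L) {
    g <- if (t$strand == "+") max(t$stop_codon[, 2L]) - 1L
         else min(t$stop_codon[, 1L])
    return(genomic_to_spliced(t, g))
  }
  if (nrow(t$cds) > 0L) {
    g <- if (t$strand == "+") max(t$cds[, 2L]) - 1L else min(t$cds[, 1L])
    cds_end <- genomic_to_spliced(t, g)
    return(if (cds_includes_stop) cds_end else cds_end + 3L)
  }
  NA_integer_
}

#' Classify a transcript as NMD-prone from its features
#'
#' Applies the three-part susceptibility rule: a transcript is prone to
#' nonsense-mediated decay when its 3'UTR is at least `utr3_min_bp` bases
#' long (`LONG_UTR3`), or its 3'UTR contains an intron (`UTR3_INTRON`), or
#' an exon-exon junction lies strictly more than `junction_min_nt` nt
#' downstream of the stop codon (`DOWNSTREAM_JUNCTION`). Note the boundary
#' asymmetry: the UTR-length threshold is inclusive, the junction-distance
#' threshold exclusive. Non-evaluable transcripts are never prone.
#'
#' @param f feature list from [extract_nmd_features()].
#' @param utr3_min_bp minimum 3'UTR length (bp, inclusive). Default 1250.
#' @param junction_min_nt junction distance (nt) that must be exceeded.
#'   Default 50.
#' @return a list with `transcript_id`, `prone` (logical),
#'   `triggered_rules` (character vector, empty when not prone) and the
#'   thresholds used.
#' @export
classify_nmd <- function(f, utr3_min_bp = 1250, junction_min_nt = 50) {
  if (!is_number(utr3_min_bp) || utr3_min_bp <= 0 ||
      !is_number(junction_min_nt) || junction_min_nt <= 0)
    stopf("classification thresholds must be positive numbers")
  rules <- character(0)
  if (isTRUE(f$evaluable)) {
    if (f$utr3_length >= utr3_min_bp) rules <- c(rules, "LONG_UTR3")
    if (f$utr3_intron_count >= 1L) rules <- c(rules, "UTR3_INTRON")
    if (!is.na(f$max_junction_distance) &&
        f$max_junction_distance > junction_min_nt)
      rules <- c(rules, "DOWNSTREAM_JUNCTION")
  }
  list(transcript_id = f$transcript_id, prone = length(rules) > 0L,
       triggered_rules = rules,
       utr3_min_bp = utr3_min_bp, junction_min_nt = junction_min_nt)
}

#' Per-transcript NMD feature and call table
#'
#' Runs [extract_nmd_features()] and [classify_nmd()] over a collection of
#' transcript models and returns one row per transcript.
#'
#' @param models list of [transcript_model()] objects (e.g. from
#'   [parse_gtf()]).
#' @inheritParams extract_nmd_features
#' @inheritParams classify_nmd
#' @return a data frame with columns `transcript_id`, `gene_id`,
#'   `gene_biotype`, `evaluable`, `utr3_length`, `utr3_intron_count`,
#'   `max_junction_distance`, `prone`, `triggered_rules` (comma-joined).
#' @export
nmd_call_table <- function(models, utr3_min_bp = 1250, junction_min_nt = 50,
                           cds_includes_stop = TRUE) {
  rows <- lapply(models, function(t) {
    f <- extract_nmd_features(t, cds_includes_stop = cds_includes_stop)
    call <- classify_nmd(f, utr3_min_bp, junction_min_nt)
    data.frame(transcript_id = f$transcript_id, gene_id = f$gene_id,
               gene_biotype = t$gene_biotype,
               evaluable = f$evaluable, utr3_length = f$utr3_length,
               utr3_intron_count = f$utr3_intron_count,
               max_junction_distance = f$max_junction_distance,
               prone = call$prone,
               triggered_rules = paste(call$triggered_rules, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate transcript-level NMD calls to gene level
#'
#' Under the default any-transcript policy a gene is NMD-prone as soon as
#' one of its transcripts is; under `"all"` every transcript must be prone.
#'
#' @param calls data frame from [nmd_call_table()] (needs `transcript_id`,
#'   `gene_id`, `prone`).
#' @param policy `"any"` (default) or `"all"`.
#' @return data frame with `gene_id`, `n_transcripts`, `n_prone`, `prone`.
#' @export
gene_level_nmd <- function(calls, policy = c("any", "all")) {
  policy <- match.arg(policy)
  if (!all(c("transcript_id", "gene_id", "prone") %in% names(calls)))
    stopf("calls must have transcript_id, gene_id and prone columns")
  if (any(is.na(calls$gene_id) | !nzchar(calls$gene_id)))
    stopf("transcript without a gene mapping: %s",
          paste(utils::head(calls$transcript_id[
            is.na(calls$gene_id) | !nzchar(calls$gene_id)], 3L),
            collapse = ", "))
  n_tx <- tapply(calls$prone, calls$gene_id, length)
  n_prone <- tapply(calls$prone, calls$gene_id, sum)
  prone <- if (policy == "any") n_prone >= 1L else n_prone == n_tx
  data.frame(gene_id = names(n_tx),
             n_transcripts = as.integer(n_tx),
             n_prone = as.integer(n_prone),
             prone = as.logical(prone),
             stringsAsFactors = FALSE, row.names = NULL)
}
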