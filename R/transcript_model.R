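#' Strand-aware transcript model
#'
#' Builds the validated transcript structure on which all NMD geometry is
#' computed. Coordinates are 0-based half-open (`[start, end)`) on the
#' genome; GTF input/output converts from/to the 1-based inclusive GTF
#' convention. Exons are stored in genomic (ascending-start) order regardless
#' of strand; transcript 5'->3' orientation is applied at projection time.
#'
#' @param transcript_id transcript identifier.
#' @param gene_id gene identifier the transcript belongs to.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix (or data frame) of 0-based
#'   half-open `(start, end)` exon intervals. Must be non-overlapping.
#' @param cds optional matrix of CDS intervals, same convention; every CDS
#'   interval must lie within an exon.
#' @param stop_codon optional matrix of stop-codon intervals (1-3 pieces,
#'   possibly split across exons).
#' @param gene_biotype annotation class of the gene (e.g. `protein_coding`,
#'   `lincRNA`, `antisense`, a pseudogene sub-biotype); `"unknown"` when the
#'   annotation does not say.
#' @return an object of class `transcript_model`.
#' @examples
#' t <- transcript_model("t1", "g1", "chr1", "+",
#'                       exons = rbind(c(100, 200), c(300, 400)))
#' spliced_length(t)  # 200
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             cds = NULL, stop_codon = NULL,
                             gene_biotype = "unknown") {
  exons <- as_interval_matrix(exons, transcript_id, "exon")
  cds <- as_interval_matrix(cds, transcript_id, "CDS", allow_null = TRUE)
  stop_codon <- as_interval_matrix(stop_codon, transcript_id, "stop_codon",
                                   allow_null = TRUE)
  if (!is.character(strand) || length(strand) != 1L || !strand %in% c("+", "-"))
    stopf("transcript '%s': strand must be \"+\" or \"-\"", transcript_id)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) == 0L)
    stopf("transcript '%s': at least one exon is required", transcript_id)
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stopf("transcript '%s': exons overlap", transcript_id)
  for (nm in list(cds, stop_codon)) {
    if (!is.null(nm) && nrow(nm) > 0L && !all(contained_in_exons(nm, exons)))
      stopf("transcript '%s': CDS/stop_codon interval outside any exon",
            transcript_id)
  }
  structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         gene_biotype = as.character(gene_biotype),
         chrom = as.character(chrom),
         strand = strand,
         exons = exons,
         cds = cds %||% empty_intervals(),
         stop_codon = stop_codon %||% empty_intervals()),
    class = "transcript_model")
}

empty_intervals <- function() {
  matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

as_interval_matrix <- function(x, id, what, allow_null = FALSE) {
  if (is.null(x) || (length(x) == 0L)) {
    if (allow_null) return(NULL)
    stopf("transcript '%s': %s intervals missing", id, what)
  }
  x <- as.matrix(x)
  if (ncol(x) != 2L)
    stopf("transcript '%s': %s intervals must have two columns", id, what)
  storage.mode(x) <- "integer"
  if (anyNA(x)) stopf("transcript '%s': %s coordinates not integral", id, what)
  if (any(x[, 1L] < 0L)) stopf("transcript '%s': negative %s start", id, what)
  if (any(x[, 2L] <= x[, 1L]))
    stopf("transcript '%s': %s interval with end <= start", id, what)
  dimnames(x) <- list(NULL, c("start", "end"))
  x[order(x[, 1L]), , drop = FALSE]
}

# is every interval of m contained in some single exon interval?
contained_in_exons <- function(m, exons) {
  vapply(seq_len(nrow(m)), function(i) {
    any(m[i, 1L] >= exons[, 1L] & m[i, 2L] <= exons[, 2L])
  }, logical(1L))
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (gene %s, %s, %s strand)\n",
              x$transcript_id, x$gene_id, x$gene_biotype, x$strand))
  cat(sprintf("  %d exon(s), spliced length %d; %d CDS segment(s)\n",
              nrow(x$exons), spliced_length(x), nrow(x$cds)))
  invisible(x)
}

#' Spliced (mature mRNA) length of a transcript
#'
#' @param t a [transcript_model()].
#' @return total exonic length in bases.
#' @export
spliced_length <- function(t) {
  sum(t$exons[, 2L] - t$exons[, 1L])
}

exon_widths <- function(t) t$exons[, 2L] - t$exons[, 1L]

# exon widths in transcript (5'->3') order
exon_widths_tx <- function(t) {
  w <- exon_widths(t)
  if (t$strand == "-") rev(w) else w
}

#' Introns of a transcript
#'
#' Gaps between consecutive exons in genomic order.
#'
#' @param t a [transcript_model()].
#' @return integer matrix of 0-based half-open `(start, end)` intron
#'   intervals; zero rows for a single-exon transcript.
#' @export
introns <- function(t) {
  n <- nrow(t$exons)
  if (n < 2L) return(empty_intervals())
  m <- cbind(start = t$exons[-n, 2L], end = t$exons[-1L, 1L])
  m
}

#' Project genomic positions onto spliced transcript coordinates
#'
#' Maps 0-based genomic positions lying inside exons to 0-based offsets along
#' the mature mRNA, counted 5'->3' in transcript orientation. On the `-`
#' strand the traversal starts from the genomically rightmost exon and runs
#' leftward, so the genomically last base is offset 0.
#'
#' @param t a [transcript_model()].
#' @param pos integer vector of 0-based genomic positions; every position
#'   must fall inside an exon of `t`.
#' @return integer vector of spliced offsets in `[0, spliced_length(t))`.
#' @export
genomic_to_spliced <- function(t, pos) {
  pos <- as.integer(pos)
  starts <- t$exons[, 1L]; ends <- t$exons[, 2L]
  w <- ends - starts
  before <- c(0L, cumsum(w))[-(length(w) + 1L)]  # exonic bases left of exon i
  idx <- vapply(pos, function(p) {
    j <- which(p >= starts & p < ends)
    if (length(j) != 1L)
      stopf("position %d is not inside an exon of transcript '%s'",
            p, t$transcript_id)
    j
  }, integer(1L))
  plus_off <- before[idx] + (pos - starts[idx])
  unname(if (t$strand == "-") spliced_length(t) - 1L - plus_off else plus_off)
}

#' Project spliced offsets back to genomic positions
#'
#' Inverse of [genomic_to_spliced()]: maps 0-based offsets along the mature
#' mRNA to 0-based genomic positions.
#'
#' @param t a [transcript_model()].
#' @param offset integer vector of spliced offsets in
#'   `[0, spliced_length(t))`.
#' @return integer vector of genomic positions.
#' @export
spliced_to_genomic <- function(t, offset) {
  offset <- as.integer(offset)
  L <- spliced_length(t)
  if (any(offset < 0L | offset >= L))
    stopf("spliced offset out of range for transcript '%s'", t$transcript_id)
  plus_off <- if (t$strand == "-") L - 1L - offset else offset
  starts <- t$exons[, 1L]
  w <- exon_widths(t)
  before <- c(0L, cumsum(w))[-(length(w) + 1L)]
  idx <- findInterval(plus_off, before)
  unname(starts[idx] + (plus_off - before[idx]))
}

#' Spliced offsets of exon-exon junctions
#'
#' For each intron, the spliced offset of the last exonic base 5' of the
#' junction, in transcript orientation. Offsets are strictly increasing and
#' there is one per intron (exon count - 1).
#'
#' @param t a [transcript_model()].
#' @return integer vector, possibly empty.
#' @export
junction_spliced_offsets <- function(t) {
  w <- exon_widths_tx(t)
  n <- length(w)
  if (n < 2L) return(integer(0))
  cumsum(w)[-n] - 1L
}

# spliced offset of the first base of each exon, in transcript order
exon_first_offsets_tx <- function(t) {
  w <- exon_widths_tx(t)
  c(0L, cumsum(w)[-length(w)])
}
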