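#' Parse a GTF annotation into transcript models
#'
#' Reads GTF text (tab-separated, 9 columns, attributes as `key "value";`;
#' Ensembl GRCh37.75 is the reference dialect) and builds one validated
#' [transcript_model()] per distinct `transcript_id`. Only `exon`, `CDS` and
#' `stop_codon` feature lines are used; other feature types (`gene`, `UTR`,
#' `start_codon`, ...) are ignored without error. GTF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' The gene biotype is read from the `gene_biotype` attribute, falling back
#' to `gene_type` (GENCODE dialect) and then to `"unknown"`.
#'
#' @param x path to a GTF file, or a character vector of GTF lines when
#'   `text = TRUE`.
#' @param text if `TRUE`, `x` is GTF content rather than a path. A single
#'   string containing newlines is split automatically.
#' @return a named list of [transcript_model()] objects (names are
#'   transcript ids, in order of first appearance).
#' @seealso [write_gtf()] for the inverse operation.
#' @export
parse_gtf <- function(x, text = FALSE) {
  lines <- if (text) {
    if (length(x) == 1L && grepl("\n", x, fixed = TRUE))
      strsplit(x, "\n", fixed = TRUE)[[1]]
    else as.character(x)
  } else {
    readLines(x)
  }
  keep_types <- c("exon", "CDS", "stop_codon")
  recs <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L)
      stopf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
            i, length(f))
    if (!f[3L] %in% keep_types) next
    if (!grepl("^[0-9]+$", f[4L]) || !grepl("^[0-9]+$", f[5L]))
      stopf("GTF parse error at line %d: unparseable coordinates '%s'..'%s'",
            i, f[4L], f[5L])
    if (!f[7L] %in% c("+", "-"))
      stopf("GTF parse error at line %d: strand must be '+' or '-'", i)
    attrs <- parse_gtf_attributes(f[9L], i)
    if (is.na(attrs[["transcript_id"]] %||% NA_character_) ||
        is.null(attrs[["transcript_id"]]))
      stopf("GTF parse error at line %d: missing transcript_id attribute", i)
    if (is.null(attrs[["gene_id"]]))
      stopf("GTF parse error at line %d: missing gene_id attribute", i)
    recs[[length(recs) + 1L]] <- list(
      chrom = f[1L], type = f[3L],
      start = as.integer(f[4L]) - 1L,  # to 0-based half-open
      end = as.integer(f[5L]),
      strand = f[7L],
      transcript_id = attrs[["transcript_id"]],
      gene_id = attrs[["gene_id"]],
      gene_biotype = attrs[["gene_biotype"]] %||% attrs[["gene_type"]] %||%
        "unknown")
  }
  if (length(recs) == 0L) return(structure(list(), names = character(0)))
  tx_ids <- vapply(recs, `[[`, character(1L), "transcript_id")
  out <- list()
  for (tid in unique(tx_ids)) {
    rr <- recs[tx_ids == tid]
    chroms <- unique(vapply(rr, `[[`, character(1L), "chrom"))
    strands <- unique(vapply(rr, `[[`, character(1L), "strand"))
    if (length(chroms) > 1L || length(strands) > 1L)
      stopf("transcript '%s' has features on multiple chromosomes or strands",
            tid)
    pick <- function(type) {
      m <- do.call(rbind, lapply(rr[vapply(rr, `[[`, character(1L), "type") == type],
                                 function(r) c(r$start, r$end)))
      if (is.null(m)) NULL else m
    }
    exons <- pick("exon")
    if (is.null(exons))
      stopf("transcript '%s' has no exon features", tid)
    out[[tid]] <- transcript_model(
      transcript_id = tid,
      gene_id = rr[[1L]]$gene_id,
      chrom = chroms, strand = strands,
      exons = exons, cds = pick("CDS"), stop_codon = pick("stop_codon"),
      gene_biotype = rr[[1L]]$gene_biotype)
  }
  out
}

parse_gtf_attributes <- function(s, line_no) {
  m <- gregexpr('([A-Za-z_]+)\\s+"([^"]*)"', s)[[1]]
  if (m[1L] == -1L)
    stopf("GTF parse error at line %d: unparseable attribute field", line_no)
  pieces <- regmatches(s, gregexpr('([A-Za-z_]+)\\s+"([^"]*)"', s))[[1]]
  keys <- sub('^([A-Za-z_]+)\\s+".*$', "\\1", pieces)
  vals <- sub('^[A-Za-z_]+\\s+"([^"]*)".*$', "\\1", pieces)
  as.list(stats::setNames(vals, keys))
}

#' Write transcript models as GTF text
#'
#' Emits `exon`, `CDS` and `stop_codon` lines in the Ensembl GTF dialect
#' (1-based inclusive coordinates, `gene_id`/`transcript_id`/`gene_biotype`
#' attributes). Parsing the output with [parse_gtf()] reconstructs the input
#' models field-by-field.
#'
#' @param models a list of [transcript_model()] objects.
#' @param file optional path; when `NULL` the GTF text is returned.
#' @return the GTF lines as a character vector (invisibly when `file` is
#'   given).
#' @export
write_gtf <- function(models, file = NULL) {
  fmt <- function(t, type, m) {
    if (is.null(m) || nrow(m) == 0L) return(character(0))
    sprintf("%s\tnmdscope\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_biotype \"%s\";",
            t$chrom, type, m[, 1L] + 1L, m[, 2L], t$strand,
            t$gene_id, t$transcript_id, t$gene_biotype)
  }
  lines <- unlist(lapply(models, function(t) {
    c(fmt(t, "exon", t$exons), fmt(t, "CDS", t$cds),
      fmt(t, "stop_codon", t$stop_codon))
  }), use.names = FALSE) %||% character(0)
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
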