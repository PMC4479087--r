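# Seeded generators for every input the pipeline consumes, each with planted
# ground truth. One integer seed drives a single RNG stream per generator
# call; entities are generated in a fixed order, so outputs are byte-stable.

#' Generate a synthetic GTF annotation with planted NMD labels
#'
#' Builds transcripts by explicit geometric construction so that every NMD
#' label is known by design:
#'
#' * `prone` transcripts carry exactly one planted trigger, chosen uniformly:
#'   a 3'UTR of 1250-5000 bp (`LONG_UTR3`), one intron entirely inside a
#'   short 3'UTR with both junctions within 50 nt of the stop
#'   (`UTR3_INTRON`), or a single junction 51-500 nt downstream of the stop
#'   (`DOWNSTREAM_JUNCTION`);
#' * `not_prone` transcripts have a 3'UTR under 1250 bp and either no
#'   junction downstream of the stop or one boundary junction at most 50 nt
#'   downstream (which triggers no rule);
#' * `not_evaluable` transcripts have no CDS and a non-coding biotype drawn
#'   from lincRNA/antisense/pseudogene.
#'
#' Evaluable transcripts are `protein_coding`; half of them annotate an
#' explicit `stop_codon` feature, the other half rely on a CDS that includes
#' the stop codon, exercising both GTF dialects.
#'
#' @param n_genes number of genes.
#' @param transcripts_per_gene transcripts per gene (labels are planted per
#'   transcript).
#' @param prone_fraction fraction of all transcripts planted NMD-prone.
#' @param noneval_fraction fraction of all transcripts with no CDS.
#' @param seed integer seed; same seed and parameters give identical bytes.
#' @param chrom chromosome name used for all transcripts.
#' @return list with `gtf` (character vector of GTF lines), `models`
#'   (the constructed [transcript_model()]s) and `truth` (list with
#'   `nmd_labels`: transcript id -> `prone`/`not_prone`/`not_evaluable`;
#'   `planted_rule`: transcript id -> trigger, for prone transcripts;
#'   `gene_of`: transcript id -> gene id; `seed`).
#' @export
generate_annotation <- function(n_genes = 50, transcripts_per_gene = 1,
                                prone_fraction = 0.4, noneval_fraction = 0.1,
                                seed = 1, chrom = "chr1") {
  if (!is_number(prone_fraction) || prone_fraction < 0 || prone_fraction > 1)
    stopf("prone_fraction must be in [0, 1]")
  if (!is_number(noneval_fraction) || noneval_fraction < 0 ||
      noneval_fraction > 1)
    stopf("noneval_fraction must be in [0, 1]")
  set.seed(as.integer(seed))
  n_tx <- n_genes * transcripts_per_gene
  n_noneval <- round(noneval_fraction * n_tx)
  n_prone <- round(prone_fraction * n_tx)
  if (n_prone + n_noneval > n_tx)
    stopf("prone_fraction + noneval_fraction exceed 1 after rounding")
  status <- sample(rep(c("prone", "not_prone", "not_evaluable"),
                       c(n_prone, n_tx - n_prone - n_noneval, n_noneval)))
  rule_pool <- c("LONG_UTR3", "UTR3_INTRON", "DOWNSTREAM_JUNCTION")

  models <- vector("list", n_tx)
  labels <- character(n_tx); planted_rule <- character(0)
  gene_of <- character(n_tx)
  tx_ids <- sprintf("t%04d", seq_len(n_tx))
  gene_ids <- sprintf("g%04d", rep(seq_len(n_genes), each = transcripts_per_gene))

  for (i in seq_len(n_tx)) {
    base <- (i - 1L) * 100000L + 1000L
    strand <- sample(c("+", "-"), 1L)
    st <- status[i]
    if (st == "not_evaluable") {
      bp <- blueprint_noncoding()
      biotype <- sample(c("lincRNA", "antisense", "pseudogene"), 1L)
    } else if (st == "prone") {
      rule <- sample(rule_pool, 1L)
      planted_rule[tx_ids[i]] <- rule
      bp <- blueprint_coding(rule)
      biotype <- "protein_coding"
    } else {
      bp <- blueprint_coding("NONE")
      biotype <- "protein_coding"
    }
    models[[i]] <- blueprint_to_model(
      bp, transcript_id = tx_ids[i], gene_id = gene_ids[i], chrom = chrom,
      strand = strand, base = base,
      emit_stop_codon = st != "not_evaluable" && (i %% 2L == 0L),
      gene_biotype = biotype)
    labels[i] <- st
    gene_of[i] <- gene_ids[i]
  }
  names(models) <- tx_ids
  truth <- list(seed = as.integer(seed),
                nmd_labels = stats::setNames(labels, tx_ids),
                planted_rule = planted_rule,
                gene_of = stats::setNames(gene_of, tx_ids))
  list(gtf = write_gtf(models), models = models, truth = truth)
}

# spliced-space blueprint of a coding transcript: exon cut points plus the
# stop codon's 3'-most spliced offset. "rule" picks the planted geometry.
blueprint_coding <- function(rule) {
  u5 <- sample(100:300, 1L)
  cds_len <- 3L * sample(100:300, 1L)           # includes the stop codon
  stop_off <- u5 + cds_len - 1L
  region_a <- u5 + cds_len
  # 0-2 junctions upstream of the stop (inside 5'UTR/CDS)
  k_up <- sample(0:2, 1L)
  cuts <- if (k_up > 0L) sort(sample(2:(region_a - 2L), k_up)) else integer(0)
  if (rule == "LONG_UTR3") {
    u3 <- sample(1250:5000, 1L)
  } else if (rule == "UTR3_INTRON") {
    d1 <- sample(1:25, 1L)                      # stop-bearing exon runs d1 past stop
    w <- sample(1:(50L - d1), 1L)               # pure-UTR exon, junction2 <= 50 nt
    rest <- sample(100:1000, 1L)
    cuts <- c(cuts, stop_off + d1 + 1L, stop_off + d1 + w + 1L)
    u3 <- d1 + w + rest
  } else if (rule == "DOWNSTREAM_JUNCTION") {
    d <- sample(51:500, 1L)
    rest <- sample(100:700, 1L)                 # keeps u3 < 1250
    cuts <- c(cuts, stop_off + d + 1L)
    u3 <- d + rest
  } else {                                      # NONE: not prone
    if (stats::runif(1) < 0.3) {
      d <- sample(1:50, 1L)                     # boundary junction, <= 50 nt
      rest <- sample(100:1000, 1L)
      cuts <- c(cuts, stop_off + d + 1L)
      u3 <- d + rest
    } else {
      u3 <- sample(100:1200, 1L)                # stop in the last exon
    }
  }
  list(L = region_a + u3, cuts = sort(cuts), u5 = u5, stop_off = stop_off,
       coding = TRUE)
}

blueprint_noncoding <- function() {
  L <- sample(500:3000, 1L)
  k <- sample(0:2, 1L)
  cuts <- if (k > 0L) sort(sample(2:(L - 2L), k)) else integer(0)
  list(L = L, cuts = cuts, u5 = NA_integer_, stop_off = NA_integer_,
       coding = FALSE)
}

# lay a spliced-space blueprint onto the genome and build the model
blueprint_to_model <- function(bp, transcript_id, gene_id, chrom, strand,
                               base, emit_stop_codon, gene_biotype) {
  starts_sp <- c(0L, bp$cuts)                       # transcript order
  ends_sp <- c(bp$cuts, bp$L)
  widths_tx <- ends_sp - starts_sp
  n <- length(widths_tx)
  intron_w <- if (n > 1L) sample(60:500, n - 1L, replace = TRUE) else integer(0)
  widths_gen <- if (strand == "-") rev(widths_tx) else widths_tx
  introns_gen <- if (strand == "-") rev(intron_w) else intron_w
  gstarts <- base + c(0L, cumsum(widths_gen[-n] + introns_gen))
  exons <- cbind(gstarts, gstarts + widths_gen)

  # map a spliced range [a, b] (transcript order, inclusive) to genomic rows
  sp_to_gen <- function(a, b) {
    f <- c(0L, cumsum(widths_tx)[-n])
    pieces <- list()
    for (j in seq_len(n)) {
      lo <- max(a, f[j]); hi <- min(b, f[j] + widths_tx[j] - 1L)
      if (lo > hi) next
      jj <- if (strand == "-") n - j + 1L else j
      if (strand == "+") {
        gs <- exons[jj, 1L] + (lo - f[j]); ge <- exons[jj, 1L] + (hi - f[j]) + 1L
      } else {
        ge <- exons[jj, 2L] - (lo - f[j]); gs <- exons[jj, 2L] - (hi - f[j]) - 1L
      }
      pieces[[length(pieces) + 1L]] <- c(gs, ge)
    }
    do.call(rbind, pieces)
  }

  cds <- NULL; stop_codon <- NULL
  if (bp$coding) {
    cds <- sp_to_gen(bp$u5, bp$stop_off)            # CDS includes the stop
    if (emit_stop_codon) stop_codon <- sp_to_gen(bp$stop_off - 2L, bp$stop_off)
  }
  transcript_model(transcript_id, gene_id, chrom, strand, exons,
                   cds = cds, stop_codon = stop_codon,
                   gene_biotype = gene_biotype)
}

#' Generate a synthetic two-condition expression table with planted DE genes
#'
#' A planted fraction of genes is differentially expressed at exactly the
#' stated fold changes with q-values in `(0, 0.05]`; the remaining null
#' genes have fold changes near 1 (within `[0.9, 1.1]`) and q-values in
#' `(0.05, 1]`, so the standard cutoff (q <= 0.05 and fold change > 1.5 or
#' < 0.67) recovers the planted set exactly. Control FPKM is log-uniform on
#' `[1, 100]`.
#'
#' @param gene_ids character vector of gene ids (e.g. from a generated
#'   annotation).
#' @param de_fraction fraction of genes planted differentially expressed.
#' @param up_down_ratio ratio of up- to down-regulated among planted DE.
#' @param fc_up planted upregulation fold change (must exceed 1.5).
#' @param fc_down planted downregulation fold change (must be below 0.67).
#' @param seed integer seed.
#' @return list with `table` (data frame: `gene_id`, `fpkm_control`,
#'   `fpkm_case`, `p_value`, `q_value`) and `truth` (list with `de_genes`:
#'   gene id -> `up`/`down`/`null`; `seed`).
#' @export
generate_expression <- function(gene_ids, de_fraction = 0.1,
                                up_down_ratio = 1, fc_up = 2, fc_down = 0.5,
                                seed = 1) {
  if (!is_number(de_fraction) || de_fraction < 0 || de_fraction > 1)
    stopf("de_fraction must be in [0, 1]")
  if (!is_number(fc_up) || fc_up <= 1.5)
    stopf("fc_up must exceed 1.5 or the planted genes are undetectable")
  if (!is_number(fc_down) || fc_down >= 0.67 || fc_down < 0)
    stopf("fc_down must be below 0.67 or the planted genes are undetectable")
  set.seed(as.integer(seed))
  n <- length(gene_ids)
  n_de <- round(n * de_fraction)
  n_up <- round(n_de * up_down_ratio / (1 + up_down_ratio))
  status <- sample(rep(c("up", "down", "null"), c(n_up, n_de - n_up, n - n_de)))
  fpkm_control <- exp(stats::runif(n, log(1), log(100)))
  fc <- ifelse(status == "up", fc_up,
        ifelse(status == "down", fc_down, stats::runif(n, 0.9, 1.1)))
  q <- ifelse(status == "null", stats::runif(n, 0.05, 1),
              stats::runif(n, 0, 0.05))
  tab <- data.frame(gene_id = gene_ids,
                    fpkm_control = fpkm_control,
                    fpkm_case = fpkm_control * fc,
                    p_value = q * stats::runif(n, 0.1, 1),
                    q_value = q,
                    stringsAsFactors = FALSE)
  list(table = tab,
       truth = list(seed = as.integer(seed),
                    de_genes = stats::setNames(status, gene_ids)))
}

#' Generate synthetic gene-set collections with one planted enriched set
#'
#' The first set (`planted_set`) shares exactly `planted_overlap` members
#' with the designated query; the remaining sets are sampled uniformly from
#' the universe independently of the query (null sets).
#'
#' @param universe character vector of background gene ids.
#' @param query character vector (subset of the universe) against which the
#'   enrichment is planted.
#' @param n_sets total number of sets (>= 1).
#' @param set_size members per set.
#' @param planted_overlap exact overlap of `planted_set` with `query`.
#' @param seed integer seed.
#' @return list with `sets` (named list of member vectors), `gmt` (GMT
#'   lines) and `truth` (list with `enriched_sets`: set name -> planted
#'   overlap; `seed`).
#' @export
generate_genesets <- function(universe, query, n_sets = 5, set_size = 50,
                              planted_overlap = 20, seed = 1) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (set_size > length(universe))
    stopf("set_size exceeds the universe size")
  if (planted_overlap > min(set_size, length(query)))
    stopf("planted_overlap %d is infeasible for set_size %d and query size %d",
          planted_overlap, set_size, length(query))
  if (set_size - planted_overlap > length(setdiff(universe, query)))
    stopf("universe too small outside the query for the requested set")
  set.seed(as.integer(seed))
  sets <- list()
  sets[["planted_set"]] <- sample(c(
    sample(query, planted_overlap),
    sample(setdiff(universe, query), set_size - planted_overlap)))
  if (n_sets > 1L) for (j in seq_len(n_sets - 1L))
    sets[[sprintf("null_set_%d", j)]] <- sample(universe, set_size)
  gmt <- vapply(names(sets), function(nm)
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t"), character(1L))
  list(sets = sets, gmt = unname(gmt),
       truth = list(seed = as.integer(seed),
                    enriched_sets = c(planted_set = planted_overlap)))
}

#' Generate a synthetic splicing-event table with planted significant events
#'
#' Planted significant events draw a Bayes factor log-uniformly in
#' `(10, 1e6]` (a few get `Inf`, the overwhelming-evidence convention),
#' a delta-psi in `(0.2, 0.8]` with random sign, and at least `min_reads`
#' informative reads. Null events violate one criterion chosen at random
#' (Bayes factor <= 10, delta-psi <= 0.2, or too few reads) while the other
#' fields range freely. Event types follow `composition` mapped to exact
#' integer counts (largest-remainder rounding).
#'
#' @param n_events number of events.
#' @param sig_fraction fraction planted significant.
#' @param seed integer seed.
#' @param composition named non-negative weights over SE/A3SS/A5SS/ALE/AFE;
#'   the default mirrors a typical event-type mix dominated by exon
#'   skipping.
#' @param min_reads read floor used when planting significant events.
#' @param n_genes number of distinct genes events are spread over.
#' @return list with `table` (canonical event columns) and `truth` (list
#'   with `significant_events`: character vector of planted event ids;
#'   `seed`).
#' @export
generate_events <- function(n_events = 500, sig_fraction = 0.2, seed = 1,
                            composition = c(SE = 0.614, ALE = 0.185,
                                            A3SS = 0.1115, A5SS = 0.0924),
                            min_reads = 20, n_genes = max(1L, n_events %/% 4L)) {
  if (!is_number(sig_fraction) || sig_fraction < 0 || sig_fraction > 1)
    stopf("sig_fraction must be in [0, 1]")
  if (any(composition < 0) || sum(composition) <= 0)
    stopf("composition must be non-negative with positive sum")
  if (!all(names(composition) %in% EVENT_TYPES))
    stopf("composition names must be among %s",
          paste(EVENT_TYPES, collapse = "/"))
  set.seed(as.integer(seed))
  types <- sample(rep(names(composition),
                      largest_remainder_counts(composition, n_events)))
  n_sig <- round(n_events * sig_fraction)
  sig <- sample(rep(c(TRUE, FALSE), c(n_sig, n_events - n_sig)))

  bf <- numeric(n_events); dpsi <- numeric(n_events)
  reads <- integer(n_events)
  bf[sig] <- exp(stats::runif(n_sig, log(10.5), log(1e6)))
  bf[sig][stats::runif(n_sig) < 0.05] <- Inf
  dpsi[sig] <- stats::runif(n_sig, 0.21, 0.8)
  reads[sig] <- sample(min_reads:500, n_sig, replace = TRUE)
  n_null <- n_events - n_sig
  if (n_null > 0L) {
    mode <- sample(c("bf", "dpsi", "reads"), n_null, replace = TRUE)
    bf[!sig] <- ifelse(mode == "bf", stats::runif(n_null, 0, 9.9),
                       exp(stats::runif(n_null, log(0.1), log(1e4))))
    dpsi[!sig] <- ifelse(mode == "dpsi", stats::runif(n_null, 0, 0.19),
                         stats::runif(n_null, 0, 0.8))
    reads[!sig] <- ifelse(mode == "reads",
                          sample(0:(min_reads - 1L), n_null, replace = TRUE),
                          sample(min_reads:500, n_null, replace = TRUE))
    # a null event must fail at least one criterion whatever the free fields
    redo <- !sig & bf > 10 & dpsi > 0.2 & reads >= min_reads
    bf[redo] <- stats::runif(sum(redo), 0, 9.9)
  }
  psi_control <- stats::runif(n_events) * (1 - dpsi)
  flip <- sample(c(TRUE, FALSE), n_events, replace = TRUE)
  psi_case <- psi_control + dpsi
  tmp <- psi_control
  psi_control[flip] <- psi_case[flip]
  psi_case[flip] <- tmp[flip]

  ids <- sprintf("ev%05d", seq_len(n_events))
  tab <- data.frame(
    event_id = ids,
    gene_id = sprintf("sg%04d", sample.int(n_genes, n_events, replace = TRUE)),
    event_type = types,
    psi_control = psi_control, psi_case = psi_case,
    bayes_factor = bf, informative_reads = reads,
    stringsAsFactors = FALSE)
  list(table = tab,
       truth = list(seed = as.integer(seed),
                    significant_events = ids[sig]))
}

# map a weight vector to integer counts summing to n (largest remainder)
largest_remainder_counts <- function(w, n) {
  p <- w / sum(w)
  raw <- p * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0L) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  stats::setNames(as.integer(counts), names(w))
}
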