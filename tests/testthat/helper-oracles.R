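# Brute-force oracles, deliberately computed by direct enumeration so they
# share no code path with the implementation they check.

# genomic positions of every exonic base, in transcript 5'->3' order
oracle_spliced_bases <- function(t) {
  pos <- unlist(lapply(seq_len(nrow(t$exons)), function(i) {
    seq.int(t$exons[i, 1L], t$exons[i, 2L] - 1L)
  }))
  if (t$strand == "-") rev(pos) else pos
}

oracle_genomic_to_spliced <- function(t, pos) {
  match(pos, oracle_spliced_bases(t)) - 1L
}

# spliced offsets of the last base of every exon except the transcript-last
oracle_junction_offsets <- function(t) {
  bases <- oracle_spliced_bases(t)
  n <- nrow(t$exons)
  if (n < 2L) return(integer(0))
  ord <- if (t$strand == "-") rev(seq_len(n)) else seq_len(n)
  last_base <- vapply(ord[-n], function(i) {
    if (t$strand == "+") t$exons[i, 2L] - 1L else t$exons[i, 1L]
  }, integer(1L))
  sort(match(last_base, bases) - 1L)
}

# per-spliced-base recomputation of the three NMD feature quantities
oracle_nmd_features <- function(t, cds_includes_stop = TRUE) {
  bases <- oracle_spliced_bases(t)
  L <- length(bases)
  if (nrow(t$stop_codon) > 0L) {
    sc_bases <- unlist(lapply(seq_len(nrow(t$stop_codon)), function(i)
      seq.int(t$stop_codon[i, 1L], t$stop_codon[i, 2L] - 1L)))
    stop_off <- max(match(sc_bases, bases)) - 1L
  } else if (nrow(t$cds) > 0L) {
    cds_bases <- unlist(lapply(seq_len(nrow(t$cds)), function(i)
      seq.int(t$cds[i, 1L], t$cds[i, 2L] - 1L)))
    stop_off <- max(match(cds_bases, bases)) - 1L
    if (!cds_includes_stop) stop_off <- stop_off + 3L
  } else {
    stop_off <- NA_integer_
  }
  if (is.na(stop_off) || stop_off >= L)
    return(list(evaluable = FALSE, utr3_length = 0L, utr3_intron_count = 0L,
                max_junction_distance = NA_integer_))
  utr3 <- sum(seq_len(L) - 1L > stop_off)  # count bases past the stop
  n <- nrow(t$exons)
  ord <- if (t$strand == "-") rev(seq_len(n)) else seq_len(n)
  exon_offsets <- lapply(ord, function(i) {
    ex_bases <- seq.int(t$exons[i, 1L], t$exons[i, 2L] - 1L)
    sort(match(ex_bases, bases) - 1L)
  })
  juncs <- oracle_junction_offsets(t)
  downstream <- juncs[juncs > stop_off]
  mjd <- if (length(downstream)) max(downstream) - stop_off else NA_integer_
  # intron i is in the 3'UTR iff every base of transcript-order exon i is
  # past the stop codon
  utr_introns <- 0L
  if (n >= 2L) for (i in seq_len(n - 1L))
    if (all(exon_offsets[[i]] > stop_off)) utr_introns <- utr_introns + 1L
  list(evaluable = TRUE, utr3_length = as.integer(utr3),
       utr3_intron_count = utr_introns,
       max_junction_distance = as.integer(mjd))
}

oracle_classify <- function(f, utr3_min_bp = 1250, junction_min_nt = 50) {
  isTRUE(f$evaluable) &&
    (f$utr3_length >= utr3_min_bp || f$utr3_intron_count >= 1L ||
       (!is.na(f$max_junction_distance) &&
          f$max_junction_distance > junction_min_nt))
}

# runs of consecutive integers -> 0-based half-open interval matrix
runs_to_intervals <- function(pos) {
  pos <- sort(unique(pos))
  brk <- c(0L, which(diff(pos) != 1L), length(pos))
  do.call(rbind, lapply(seq_len(length(brk) - 1L), function(i) {
    seg <- pos[(brk[i] + 1L):brk[i + 1L]]
    c(seg[1L], seg[length(seg)] + 1L)
  }))
}

# a random transcript with random exon count, strand and CDS placement;
# uses the ambient RNG stream (call set.seed before batches)
random_transcript <- function(id = "tx", coding = TRUE) {
  n_exons <- sample(1:8, 1L)
  widths <- sample(30:400, n_exons, replace = TRUE)
  gaps <- if (n_exons > 1L) sample(60:500, n_exons - 1L, replace = TRUE)
          else integer(0)
  starts <- 1000L + c(0L, cumsum(widths[-n_exons] + gaps))
  exons <- cbind(starts, starts + widths)
  strand <- sample(c("+", "-"), 1L)
  skeleton <- transcript_model(id, paste0("g_", id), "chrT", strand, exons,
                               gene_biotype = "protein_coding")
  if (!coding) return(skeleton)
  bases <- oracle_spliced_bases(skeleton)
  L <- length(bases)
  cds_start <- sample.int(L - 6L, 1L) - 1L
  stop_off <- sample(seq.int(cds_start + 5L, L - 1L), 1L)
  if (stats::runif(1) < 0.5) {
    sc <- runs_to_intervals(bases[(stop_off - 1L):(stop_off + 1L)])
    transcript_model(id, paste0("g_", id), "chrT", strand, exons,
                     stop_codon = sc, gene_biotype = "protein_coding")
  } else {
    cds <- runs_to_intervals(bases[(cds_start + 1L):(stop_off + 1L)])
    transcript_model(id, paste0("g_", id), "chrT", strand, exons,
                     cds = cds, gene_biotype = "protein_coding")
  }
}

# exact hypergeometric upper tail by binomial-coefficient sums (exact in
# double precision for N <= 20)
oracle_hyper_tail_choose <- function(k, K, n, N) {
  j <- seq.int(k, min(K, n))
  if (length(j) == 0L) return(if (k == 0L) 1 else 0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# full draw-by-draw enumeration: every size-n subset of 1..N, set = 1..K
oracle_hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0L) return(if (k == 0L) 1 else 0)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# hand step-up BH adjustment (independent of stats::p.adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# tiny GTF used across parser tests: one 2-exon transcript plus CDS
toy_gtf <- function(strand = "+") {
  c(sprintf("chr1\ttest\texon\t101\t200\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"tx1\"; gene_biotype \"protein_coding\";", strand),
    sprintf("chr1\ttest\texon\t301\t400\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"tx1\"; gene_biotype \"protein_coding\";", strand),
    sprintf("chr1\ttest\tCDS\t101\t200\t.\t%s\t.\tgene_id \"g1\"; transcript_id \"tx1\"; gene_biotype \"protein_coding\";", strand))
}
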