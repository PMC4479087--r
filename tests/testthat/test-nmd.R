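# helper: single-exon coding transcript with the stop's last base at a
# chosen spliced offset
single_exon_coding <- function(L, stop_off, strand = "+") {
  exons <- rbind(c(1000L, 1000L + L))
  t0 <- transcript_model("t", "g", "c", strand, exons)
  bases <- oracle_spliced_bases(t0)
  transcript_model("t", "g", "c", strand, exons,
                   stop_codon = runs_to_intervals(bases[(stop_off - 1L):(stop_off + 1L)]),
                   gene_biotype = "protein_coding")
}

test_that("feature extraction matches the stated examples", {
  t <- single_exon_coding(500L, 399L)
  f <- extract_nmd_features(t)
  expect_true(f$evaluable)
  expect_identical(f$utr3_length, 100L)
  expect_identical(f$utr3_intron_count, 0L)
  expect_true(is.na(f$max_junction_distance))

  # two exons, junction 30 nt past the stop's 3'-most base
  exons <- rbind(c(1000L, 1500L), c(1600L, 1900L))
  t2 <- transcript_model("t", "g", "c", "+", exons,
                         stop_codon = rbind(c(1467L, 1470L)))
  f2 <- extract_nmd_features(t2)  # stop last base offset 469, junction at 499
  expect_identical(f2$max_junction_distance, 30L)
  expect_identical(f2$utr3_intron_count, 0L)  # boundary intron, not UTR-internal
  expect_identical(f2$utr3_length, 800L - 469L - 1L)

  # no CDS/stop -> not evaluable, never prone
  linc <- transcript_model("t", "g", "c", "+", exons, gene_biotype = "lincRNA")
  fl <- extract_nmd_features(linc)
  expect_false(fl$evaluable)
  expect_false(classify_nmd(fl)$prone)
  expect_length(classify_nmd(fl)$triggered_rules, 0L)
})

test_that("stop-codon dialects resolve to the same geometry", {
  set.seed(404)
  exons <- rbind(c(1000L, 1500L), c(1600L, 1900L))
  t0 <- transcript_model("t", "g", "c", "+", exons)
  bases <- oracle_spliced_bases(t0)
  stop_off <- 299L
  with_sc <- transcript_model("t", "g", "c", "+", exons,
                              stop_codon = runs_to_intervals(bases[298:300]))
  cds_incl <- transcript_model("t", "g", "c", "+", exons,
                               cds = runs_to_intervals(bases[101:300]))
  cds_excl <- transcript_model("t", "g", "c", "+", exons,
                               cds = runs_to_intervals(bases[101:297]))
  f1 <- extract_nmd_features(with_sc)
  f2 <- extract_nmd_features(cds_incl, cds_includes_stop = TRUE)
  f3 <- extract_nmd_features(cds_excl, cds_includes_stop = FALSE)
  for (f in list(f1, f2, f3)) {
    expect_identical(f$stop_offset, stop_off)
    expect_identical(f$utr3_length, 800L - stop_off - 1L)
  }
  # CDS running to the transcript end with an appended stop codon is
  # unresolvable -> not evaluable
  cds_at_end <- transcript_model("t", "g", "c", "+", exons,
                                 cds = runs_to_intervals(bases[101:800]))
  expect_false(extract_nmd_features(cds_at_end, cds_includes_stop = FALSE)$evaluable)
})

test_that("classification thresholds follow the rule boundaries", {
  f <- function(utr3 = 0L, intr = 0L, mjd = NA_integer_)
    list(transcript_id = "t", evaluable = TRUE, utr3_length = utr3,
         utr3_intron_count = intr, max_junction_distance = mjd)
  expect_identical(classify_nmd(f(utr3 = 1250L))$triggered_rules, "LONG_UTR3")
  expect_false(classify_nmd(f(utr3 = 1249L))$prone)
  expect_false(classify_nmd(f(utr3 = 100L, mjd = 50L))$prone)
  expect_identical(classify_nmd(f(utr3 = 100L, mjd = 51L))$triggered_rules,
                   "DOWNSTREAM_JUNCTION")
  expect_identical(classify_nmd(f(utr3 = 100L, intr = 1L))$triggered_rules,
                   "UTR3_INTRON")
  expect_false(classify_nmd(f())$prone)
  expect_error(classify_nmd(f(), utr3_min_bp = 0), "positive")
  expect_error(classify_nmd(f(), junction_min_nt = -1), "positive")
})

test_that("prone status flips exactly at the documented boundaries on real transcripts", {
  # 3'UTR length sweep: single exon, stop placed to give each UTR length
  for (u3 in c(1249L, 1250L, 1251L)) {
    t <- single_exon_coding(2000L, 2000L - u3 - 1L)
    call <- classify_nmd(extract_nmd_features(t))
    expect_identical(call$prone, u3 >= 1250L)
  }
  # junction distance sweep: stop in first exon, one downstream junction
  for (strand in c("+", "-")) for (d in c(49L, 50L, 51L)) {
    exons <- rbind(c(1000L, 2000L), c(2500L, 2800L))
    t0 <- transcript_model("t", "g", "c", strand, exons)
    bases <- oracle_spliced_bases(t0)
    stop_off <- junction_spliced_offsets(t0)[1] - d
    t <- transcript_model("t", "g", "c", strand, exons,
                          stop_codon = runs_to_intervals(
                            bases[(stop_off - 1L):(stop_off + 1L)]))
    f <- extract_nmd_features(t)
    expect_identical(f$max_junction_distance, d)
    expect_identical(classify_nmd(f)$prone, d > 50L)
  }
})

test_that("classifier agrees with the per-base oracle on 250 random transcripts", {
  set.seed(303)
  for (i in 1:250) {
    coding <- stats::runif(1) < 0.8
    t <- random_transcript(sprintf("o%03d", i), coding = coding)
    f <- extract_nmd_features(t)
    o <- oracle_nmd_features(t)
    expect_identical(f$evaluable, o$evaluable)
    expect_identical(f$utr3_length, o$utr3_length)
    expect_identical(f$utr3_intron_count, o$utr3_intron_count)
    expect_identical(f$max_junction_distance, o$max_junction_distance)
    expect_identical(classify_nmd(f)$prone,
                     oracle_classify(o))
  }
})

test_that("extending the terminal exon or adding a UTR intron is monotone", {
  set.seed(505)
  for (i in 1:30) {
    t <- random_transcript(sprintf("mono%02d", i), coding = TRUE)
    f <- extract_nmd_features(t)
    if (!f$evaluable) next
    # extend the 3'-terminal exon by 500 bp
    exons <- t$exons
    if (t$strand == "+") exons[nrow(exons), 2L] <- exons[nrow(exons), 2L] + 500L
    else exons[1L, 1L] <- exons[1L, 1L] - 500L
    t_ext <- transcript_model(t$transcript_id, t$gene_id, t$chrom, t$strand,
                              exons, cds = if (nrow(t$cds)) t$cds,
                              stop_codon = if (nrow(t$stop_codon)) t$stop_codon)
    f_ext <- extract_nmd_features(t_ext)
    expect_gte(f_ext$utr3_length, f$utr3_length)
    if (classify_nmd(f)$prone && "LONG_UTR3" %in% classify_nmd(f)$triggered_rules)
      expect_true(classify_nmd(f_ext)$prone)
  }
})

test_that("gene-level aggregation follows the any-transcript policy", {
  calls <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    gene_id = c("gA", "gA", "gB", "gB"),
    prone = c(TRUE, FALSE, FALSE, FALSE))
  g <- gene_level_nmd(calls)
  expect_identical(g$prone[g$gene_id == "gA"], TRUE)
  expect_identical(g$prone[g$gene_id == "gB"], FALSE)
  g_all <- gene_level_nmd(calls, policy = "all")
  expect_false(any(g_all$prone))
  calls$gene_id[1] <- ""
  expect_error(gene_level_nmd(calls), "gene mapping")
})

test_that("planted NMD labels are recovered exactly from a generated annotation", {
  gen <- generate_annotation(n_genes = 50, prone_fraction = 0.4,
                             noneval_fraction = 0.1, seed = 7)
  models <- parse_gtf(gen$gtf, text = TRUE)
  tab <- nmd_call_table(models)
  expect_identical(nrow(tab), length(gen$truth$nmd_labels))
  for (i in seq_len(nrow(tab))) {
    lab <- gen$truth$nmd_labels[[tab$transcript_id[i]]]
    expect_identical(tab$prone[i], lab == "prone")
    expect_identical(tab$evaluable[i], lab != "not_evaluable")
    if (lab == "prone") {
      planted <- gen$truth$planted_rule[[tab$transcript_id[i]]]
      expect_identical(tab$triggered_rules[i], planted)
    }
  }
  # zero prone fraction -> zero prone calls
  none <- generate_annotation(n_genes = 10, prone_fraction = 0, seed = 2)
  expect_false(any(nmd_call_table(parse_gtf(none$gtf, text = TRUE))$prone))
})
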