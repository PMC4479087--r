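test_that("toy GTF parses to the expected 0-based half-open model", {
  expect_identical(parse_gtf(character(0), text = TRUE),
                   structure(list(), names = character(0)))

  models <- parse_gtf(toy_gtf("+"), text = TRUE)
  expect_length(models, 1L)
  t <- models[["tx1"]]
  expect_s3_class(t, "transcript_model")
  expect_equal(unname(t$exons), rbind(c(100L, 200L), c(300L, 400L)))
  expect_equal(unname(t$cds), rbind(c(100L, 200L)))
  expect_identical(spliced_length(t), 200L)
  expect_identical(t$gene_biotype, "protein_coding")
  expect_identical(t$gene_id, "g1")

  # minus strand: stored genomic order identical, traversal reversed
  tm <- parse_gtf(toy_gtf("-"), text = TRUE)[["tx1"]]
  expect_equal(tm$exons, t$exons)
  expect_identical(genomic_to_spliced(tm, 399L), 0L)
})

test_that("parser errors name the offending line or transcript", {
  bad <- toy_gtf(); bad[2] <- "chr1\ttest\texon\t301\t400\t."
  expect_error(parse_gtf(bad, text = TRUE), "line 2")
  bad2 <- toy_gtf(); bad2[3] <- sub("\t101\t200", "\tabc\t200", bad2[3])
  expect_error(parse_gtf(bad2, text = TRUE), "line 3")
  # CDS outside any exon names the transcript
  bad3 <- c(toy_gtf()[1:2],
            "chr1\ttest\tCDS\t250\t260\t.\t+\t.\tgene_id \"g1\"; transcript_id \"tx1\";")
  expect_error(parse_gtf(bad3, text = TRUE), "tx1")
  # transcript split across strands is rejected, not silently split
  bad4 <- toy_gtf(); bad4[2] <- sub("\t\\+\t", "\t-\t", bad4[2])
  expect_error(parse_gtf(bad4, text = TRUE), "strand")
})

test_that("unrecognized feature lines and gene_type dialect are tolerated", {
  lines <- c("# a comment",
             "chr1\ttest\tgene\t101\t400\t.\t+\t.\tgene_id \"g1\";",
             "chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"tx1\"; gene_type \"lincRNA\";",
             "chr1\ttest\tstart_codon\t101\t103\t.\t+\t.\tgene_id \"g1\"; transcript_id \"tx1\";")
  models <- parse_gtf(lines, text = TRUE)
  expect_identical(models[["tx1"]]$gene_biotype, "lincRNA")
  # gene_biotype preferred over gene_type when both appear
  both <- sub("gene_type \"lincRNA\";",
              "gene_type \"lincRNA\"; gene_biotype \"antisense\";", lines[3])
  expect_identical(parse_gtf(both, text = TRUE)[["tx1"]]$gene_biotype,
                   "antisense")
  # no biotype attribute at all -> unknown
  none <- "chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id \"g1\"; transcript_id \"tx1\";"
  expect_identical(parse_gtf(none, text = TRUE)[["tx1"]]$gene_biotype,
                   "unknown")
})

test_that("introns are the gaps between consecutive exons", {
  one <- transcript_model("t", "g", "c", "+", rbind(c(0L, 10L)))
  expect_identical(nrow(introns(one)), 0L)
  two <- transcript_model("t", "g", "c", "+", rbind(c(100L, 200L), c(300L, 400L)))
  expect_equal(unname(introns(two)), rbind(c(200L, 300L)))
  three <- transcript_model("t", "g", "c", "+",
                            rbind(c(0L, 10L), c(20L, 30L), c(40L, 50L)))
  expect_identical(nrow(introns(three)), 2L)
})

test_that("spliced projection matches the stated examples", {
  tp <- transcript_model("t", "g", "c", "+", rbind(c(100L, 200L), c(300L, 400L)))
  expect_identical(genomic_to_spliced(tp, 100L), 0L)
  expect_identical(genomic_to_spliced(tp, 300L), 100L)
  tm <- transcript_model("t", "g", "c", "-", rbind(c(100L, 200L), c(300L, 400L)))
  expect_identical(genomic_to_spliced(tm, 399L), 0L)
  expect_identical(junction_spliced_offsets(tp), 99L)
  expect_identical(junction_spliced_offsets(tm), 99L)
  expect_identical(junction_spliced_offsets(
    transcript_model("t", "g", "c", "+", rbind(c(0L, 10L)))), integer(0))
  # positions outside exons are rejected
  expect_error(genomic_to_spliced(tp, 250L), "not inside an exon")
  expect_error(genomic_to_spliced(tp, 400L), "not inside an exon")
})

test_that("projection and junctions agree with the per-base oracle on random transcripts", {
  set.seed(101)
  for (i in 1:120) {
    t <- random_transcript(sprintf("r%03d", i), coding = FALSE)
    bases <- oracle_spliced_bases(t)
    expect_identical(spliced_length(t), length(bases))
    # every exonic base projects to its oracle index, and back
    offs <- genomic_to_spliced(t, bases)
    expect_identical(offs, seq_along(bases) - 1L)
    expect_identical(spliced_to_genomic(t, seq_along(bases) - 1L), bases)
    expect_identical(junction_spliced_offsets(t), oracle_junction_offsets(t))
  }
})

test_that("mirroring coordinates and flipping strand preserves spliced geometry", {
  set.seed(202)
  for (i in 1:40) {
    t <- random_transcript(sprintf("m%03d", i), coding = FALSE)
    hi <- max(t$exons) + 1000L
    mirrored <- transcript_model(t$transcript_id, t$gene_id, t$chrom,
                                 if (t$strand == "+") "-" else "+",
                                 cbind(hi - t$exons[, 2L], hi - t$exons[, 1L]))
    expect_identical(spliced_length(mirrored), spliced_length(t))
    expect_identical(junction_spliced_offsets(mirrored),
                     junction_spliced_offsets(t))
    expect_identical(genomic_to_spliced(mirrored, hi - 1L - oracle_spliced_bases(t)),
                     seq_len(spliced_length(t)) - 1L)
  }
})

test_that("write -> parse round-trip is a fixed point on synthetic annotations", {
  gen <- generate_annotation(n_genes = 30, prone_fraction = 0.4,
                             noneval_fraction = 0.15, seed = 7)
  parsed <- parse_gtf(gen$gtf, text = TRUE)
  expect_equal(parsed, gen$models)
  reparsed <- parse_gtf(write_gtf(parsed), text = TRUE)
  expect_equal(reparsed, parsed)
})

test_that("parser agrees with rtracklayer on a synthetic annotation", {
  gen <- generate_annotation(n_genes = 12, seed = 13)
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(gen$gtf, path)
  ref <- as.data.frame(rtracklayer::import(path, format = "gtf"))
  ours <- parse_gtf(path)
  ref_exons <- ref[ref$type == "exon", ]
  for (tid in names(ours)) {
    re <- ref_exons[ref_exons$transcript_id == tid, ]
    re <- re[order(re$start), ]
    expect_equal(unname(ours[[tid]]$exons[, 1L]), re$start - 1L)  # to 0-based
    expect_equal(unname(ours[[tid]]$exons[, 2L]), re$end)
    expect_identical(unique(as.character(re$strand)), ours[[tid]]$strand)
  }
})
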