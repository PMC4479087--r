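# build the four synthetic fixtures on disk and a matching pipeline config
make_fixtures <- function(dir, n_genes = 50, seeds = c(7, 3, 5, 11)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(n_genes = n_genes, prone_fraction = 0.4,
                             noneval_fraction = 0.1, seed = seeds[1])
  writeLines(ann$gtf, file.path(dir, "annotation.gtf"))
  gene_ids <- sort(unique(unname(ann$truth$gene_of)))
  expr <- generate_expression(gene_ids, de_fraction = 0.2, seed = seeds[2])
  write_tsv(expr$table, file.path(dir, "expression.tsv"))
  de_ids <- names(expr$truth$de_genes)[expr$truth$de_genes != "null"]
  gs <- generate_genesets(gene_ids, de_ids, n_sets = 3,
                          set_size = min(20, n_genes %/% 2),
                          planted_overlap = min(8, length(de_ids)),
                          seed = seeds[3])
  writeLines(gs$gmt, file.path(dir, "sets.gmt"))
  ev <- generate_events(n_events = 200, sig_fraction = 0.15, seed = seeds[4])
  write_tsv(ev$table, file.path(dir, "events.tsv"))
  list(ann = ann, expr = expr, gs = gs, ev = ev,
       config = pipeline_config(
         gtf = file.path(dir, "annotation.gtf"),
         expression = file.path(dir, "expression.tsv"),
         gmt = file.path(dir, "sets.gmt"),
         events = file.path(dir, "events.tsv"),
         out_dir = file.path(dir, "out")))
}
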