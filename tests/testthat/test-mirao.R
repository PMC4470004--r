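write_tsv <- function(df) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("miRT table loading keys records by target gene", {
  f <- write_tsv(data.frame(gene_id = "ENSG00000236342",
                            mirna_id = "mir-1238", pubmed = "17964270"))
  t1 <- load_mirt(f)
  expect_named(t1, "ENSG00000236342")
  expect_equal(t1[["ENSG00000236342"]]$mirna_id, "mir-1238")
  expect_equal(t1[["ENSG00000236342"]]$pubmed, "17964270")

  empty <- load_mirt(write_tsv(data.frame(gene_id = character(),
                                          mirna_id = character(),
                                          pubmed = character())))
  expect_length(empty, 0L)

  multi <- load_mirt(write_tsv(data.frame(
    gene_id = "ENSG1", mirna_id = c("mir-a", "mir-b"), pubmed = c("1", "2"))))
  expect_equal(nrow(multi[["ENSG1"]]), 2L)

  expect_error(load_mirt(write_tsv(data.frame(gene = "x", mirna_id = "y",
                                              pubmed = "1"))),
               "must have columns")
  expect_warning(load_mirt(write_tsv(data.frame(
    gene_id = c("g", "g"), mirna_id = c("m", "m"), pubmed = c("1", "1")))),
    "duplicate")
})

test_that("TFmiR table loading keys TF records by miRNA", {
  f <- write_tsv(data.frame(mirna_id = "mir-223",
                            tf_gene_id = "ENSG00000159216",
                            regulation = "repression", pubmed = "17996649"))
  t1 <- load_tfmir(f)
  expect_named(t1, "mir-223")
  expect_equal(t1[["mir-223"]]$tf_gene_id, "ENSG00000159216")
  expect_equal(t1[["mir-223"]]$regulation, "repression")

  expect_error(load_tfmir(write_tsv(data.frame(
    mirna_id = "mir-1", tf_gene_id = "g", regulation = "up", pubmed = "1"))),
    "row 1")

  two <- load_tfmir(write_tsv(data.frame(
    mirna_id = "mir-1", tf_gene_id = c("g1", "g2"),
    regulation = c("activation", "repression"), pubmed = c("1", "2"))))
  expect_equal(nrow(two[["mir-1"]]), 2L)
})

test_that("extension adds the closed-form census delta for a toy model", {
  base <- one_gene_cascade()
  mirt <- mirt_table(data.frame(gene_id = "ENSG00000000777",
                                mirna_id = "mir-x", pubmed = "1"))
  ext <- extend_model(base, mirt)
  ## one new miRNA with one target: 3 + 1 species, 4 + 1 reactions
  expect_equal(length(ext$species) - length(base$species), 4L)
  expect_equal(length(ext$reactions) - length(base$reactions), 5L)
  cs <- census(ext)
  expect_equal(unname(cs$species["miRNA"]), 2L)     # nuclear + cytoplasmic
  expect_equal(unname(cs$species["complex"]), 1L)
  expect_equal(unname(cs$reactions["miRNA-binding"]), 1L)
  expect_equal(unname(cs$reactions["translocation"]), 1L)
  expect_true(all(c("miRgene:mir-x", "miR:mir-x:nuc", "miR:mir-x:cyt",
                    "cx:mir-x:mRNA:g") %in% names(ext$species)))
  d <- expected_deltas(base, mirt)
  expect_equal(length(ext$species) - length(base$species), d$species)
  expect_equal(length(ext$reactions) - length(base$reactions), d$reactions)
})

test_that("extension is idempotent and skips unmatched genes", {
  base <- one_gene_cascade()
  mirt <- mirt_table(data.frame(gene_id = "ENSG00000000777",
                                mirna_id = "mir-x", pubmed = "1"))
  ext1 <- extend_model(base, mirt)
  ext2 <- extend_model(ext1, mirt)
  expect_true(model_equal(ext1, ext2))
  ## miRT keyed on an absent gene leaves the model unchanged
  miss <- mirt_table(data.frame(gene_id = "ENSG99999999999",
                                mirna_id = "mir-z", pubmed = "1"))
  expect_true(model_equal(extend_model(base, miss), base))
})

test_that("a matched gene without an mRNA is skipped with a warning", {
  m <- molecular_model(list(species("ENSG1", "gene")))
  mirt <- mirt_table(data.frame(gene_id = "ENSG1", mirna_id = "mir-a",
                                pubmed = "1"))
  expect_warning(ext <- extend_model(m, mirt), "no mRNA")
  expect_true(model_equal(ext, m))
})

test_that("extension growth is monotone and leaves other genes untouched", {
  for (sd in 1:5) {
    spec <- fixture_spec(sd, n_genes = 4, n_mirnas = 3)
    toy <- gen_toy_model(spec)
    tabs <- gen_mir_tables(spec)
    ext <- extend_model(toy$model, tabs$mirt, tabs$tfmir)
    c0 <- census(toy$model); c1 <- census(ext)
    expect_true(all(c1$species >= c0$species))
    expect_true(all(c1$reactions >= c0$reactions))
    d <- expected_deltas(toy$model, tabs$mirt)
    expect_equal(c1$n_species - c0$n_species, d$species)
    expect_equal(c1$n_reactions - c0$n_reactions, d$reactions)
    ## genes outside the miRT table keep identical incident reactions
    untouched <- setdiff(toy$info$gene_ids, names(tabs$mirt))
    incident <- function(model, g) {
      hit <- vapply(model$reactions, function(r)
        g %in% c(r$reactants, r$products, r$enzymes), logical(1))
      model$reactions[hit]
    }
    for (g in untouched)
      expect_identical(incident(ext, g), incident(toy$model, g))
  }
})

test_that("TF regulation lands on the miRNA transcription reaction", {
  base <- one_gene_cascade()
  base <- molecular_model(
    c(base$species, list(species("ENSGTFA", "gene", compartment = "nucleus",
                                 concentration = 5),
                         species("ENSGTFR", "gene", compartment = "nucleus",
                                 concentration = 5))),
    base$reactions)
  mirt <- mirt_table(data.frame(gene_id = "ENSG00000000777",
                                mirna_id = "mir-x", pubmed = "1"))
  tfmir <- tfmir_table(data.frame(
    mirna_id = "mir-x", tf_gene_id = c("ENSGTFA", "ENSGTFR", "ENSGABSENT"),
    regulation = c("activation", "repression", "activation"),
    pubmed = c("1", "2", "3")))
  ext <- extend_model(base, mirt, tfmir)
  tc <- ext$reactions[["rx:tc:mir-x"]]
  expect_true("ENSGTFA" %in% tc$enzymes)           # activator catalyzes
  expect_false("ENSGABSENT" %in% tc$enzymes)       # absent TF ignored
  expect_equal(tc$inhibitors$ref, "ENSGTFR")       # repressor inhibits
  expect_equal(tc$inhibitors$iKd, 1)
})

test_that("silencing is monotone: more miRNA gene, never more protein", {
  base <- one_gene_cascade()
  mirt <- mirt_table(data.frame(gene_id = "ENSG00000000777",
                                mirna_id = "mir-x", pubmed = "1"))
  ext <- extend_model(base, mirt)
  prot <- vapply(seq(0, 450, by = 50), function(lv) {
    m <- suppressMessages(
      initialize_model(ext, c(ENSG00000000777 = 20), c(`mir-x` = lv)))
    r <- simulate_to_steady(m)
    expect_true(r$reached_steady)
    r$final[["prot:g"]]
  }, numeric(1))
  expect_true(all(diff(prot) <= 1e-9))
  expect_lt(prot[10], prot[1])   # silencing genuinely bites
})
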