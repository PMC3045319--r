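olex <- default_organism_lexicon()
glex <- tiny_gene_lexicon()
labels3 <- c("fly", "mouse", "yeast")

test_that("gene-name features count the per-document top-n genes", {
  doc <- doc_from_tokens(list(c("Adh", "Adh", "Adh", "and", "Copg1")))
  gm <- tag_gene_mentions(doc, glex)
  feats <- gene_name_features(doc, gm)
  expect_equal(feats[["gn:Adh"]], 3)
  expect_equal(feats[["gn:Copg1"]], 1)

  expect_length(gene_name_features(doc, gm[0, ]), 0L)

  # cap at n_top_genes
  many <- data.frame(surface = sprintf("G%03d", 1:150),
                     canonical = sprintf("G%03d", 1:150), kind = "gene",
                     section_index = 0L, sentence_index = 0L,
                     token_index = 0:149)
  expect_length(gene_name_features(doc, many,
                                   feature_config(n_top_genes = 100L)), 100L)
})

test_that("organism frequency counts raw mentions per label", {
  doc <- multi_species_doc()
  om <- tag_organism_mentions(doc, olex)
  feats <- organism_frequency(doc, om, labels3)
  expect_equal(unname(feats[c("of:fly", "of:mouse", "of:yeast")]),
               c(1, 2, 0))

  empty <- document("e", title = "t")
  expect_equal(unname(organism_frequency(empty,
                                         tag_organism_mentions(empty, olex),
                                         labels3)),
               c(0, 0, 0))

  tripled <- doc_from_tokens(list(c("mouse", "mouse", "mouse")))
  expect_equal(organism_frequency(tripled,
                                  tag_organism_mentions(tripled, olex),
                                  labels3)[["of:mouse"]], 3)
})

test_that("MeSH selector picks per-class top headings with tie-break", {
  mk <- function(id, label, mesh) document(id, title = "t", mesh = mesh,
                                           gold_label = label)
  docs <- list(mk("1", "fly", c("Drosophila", "Genes")),
               mk("2", "fly", c("Drosophila", "Wings")),
               mk("3", "mouse", c("Mice", "Genes")),
               mk("4", "mouse", c("Mice", "Tails")))
  sel <- fit_mesh_selector(docs, mesh_per_class = 1L)
  expect_identical(sel$per_class$fly, "Drosophila")
  expect_identical(sel$per_class$mouse, "Mice")

  # exactly mesh_per_class with frequency-then-lexicographic tie-break
  docs5 <- list(mk("1", "fly", c("B", "A", "C", "D", "E")),
                mk("2", "fly", c("B", "A")))
  sel3 <- fit_mesh_selector(docs5, mesh_per_class = 3L)
  expect_identical(sel3$per_class$fly, c("A", "B", "C"))

  feats <- mesh_features(mk("x", "fly", c("Drosophila")), sel)
  expect_equal(feats[["mh:Drosophila"]], 1)
  expect_equal(feats[["mh:Mice"]], 0)
})

test_that("planted MeSH headings are recovered from a synthetic corpus", {
  corpus <- generate_corpus(generator_config(docs_per_class = 30, seed = 8))
  sel <- fit_mesh_selector(corpus$documents, mesh_per_class = 3L)
  for (cl in labels3) {
    expect_setequal(sel$per_class[[cl]], sprintf("MH-%s-%d", cl, 1:3))
  }
})

test_that("title features flag organisms and lexicon genes in the title", {
  doc <- document("a", title = "Drosophila Copg1 study")
  feats <- title_features(doc, glex, olex)
  expect_equal(feats[["dt:org:fly"]], 1)
  expect_equal(feats[["dt:org:mouse"]], 0)
  expect_equal(feats[["dt:gene:Copg1"]], 1)

  plain <- title_features(document("b", title = "Subunit genes"), glex, olex)
  expect_equal(unname(plain[paste0("dt:org:", labels3)]), c(0, 0, 0))

  both <- title_features(document("c", title = "mouse and yeast genes"),
                         glex, olex)
  expect_equal(both[["dt:org:mouse"]], 1)
  expect_equal(both[["dt:org:yeast"]], 1)
})

test_that("term-species weights follow the inverse-distance decay", {
  # gene at token 2, mouse at token 5 (0-based), same sentence: 1/(1+3)
  doc <- doc_from_tokens(list(c("the", "big", "Copg1", "gene", "in", "mouse")))
  gm <- tag_gene_mentions(doc, glex)
  om <- tag_organism_mentions(doc, olex)
  ts <- term_species_weights(doc, gm, om, labels = labels3)
  expect_equal(ts[["ts:mouse"]], 0.25)
  expect_equal(ts[["ts:fly"]], 0)

  # different sentences contribute nothing
  doc2 <- doc_from_tokens(list(c("the", "Copg1", "gene"),
                               c("found", "in", "mouse")))
  ts2 <- term_species_weights(doc2, tag_gene_mentions(doc2, glex),
                              tag_organism_mentions(doc2, olex),
                              labels = labels3)
  expect_equal(unname(ts2), c(0, 0, 0))

  # two fly pairs at d=1 and d=3 sum to 0.75
  doc3 <- doc_from_tokens(list(c("Adh", "drosophila", "x"),
                               c("Adh", "a", "b", "drosophila")))
  ts3 <- term_species_weights(doc3, tag_gene_mentions(doc3, glex),
                              tag_organism_mentions(doc3, olex),
                              labels = labels3)
  expect_equal(ts3[["ts:fly"]], 0.75)
})

test_that("term-species weight never increases with distance", {
  weights <- vapply(1:8, function(d) {
    toks <- rep("w", 10)
    toks[1] <- "Adh"
    toks[1 + d] <- "drosophila"
    doc <- doc_from_tokens(list(toks))
    term_species_weights(doc, tag_gene_mentions(doc, glex),
                         tag_organism_mentions(doc, olex),
                         labels = labels3)[["ts:fly"]]
  }, 0)
  expect_true(all(diff(weights) <= 0))

  # the exponential decay option is monotone too
  cfg <- feature_config(ts_decay = "exponential")
  w2 <- vapply(1:6, function(d) {
    toks <- rep("w", 8)
    toks[1] <- "Adh"; toks[1 + d] <- "drosophila"
    doc <- doc_from_tokens(list(toks))
    term_species_weights(doc, tag_gene_mentions(doc, glex),
                         tag_organism_mentions(doc, olex), cfg,
                         labels = labels3)[["ts:fly"]]
  }, 0)
  expect_true(all(diff(w2) <= 0))
})

test_that("term-species totals are invariant to sentence order", {
  token_lists <- list(c("Adh", "in", "drosophila"),
                      c("Copg1", "x", "y", "mouse"),
                      c("no", "signal", "here"),
                      c("CDC28", "yeast"))
  ts_of <- function(lists) {
    doc <- doc_from_tokens(lists)
    term_species_weights(doc, tag_gene_mentions(doc, glex),
                         tag_organism_mentions(doc, olex),
                         labels = labels3)
  }
  base <- ts_of(token_lists)
  set.seed(3)
  for (i in 1:5) {
    expect_equal(ts_of(sample(token_lists)), base)
  }
})

test_that("journal feature normalizes case and whitespace", {
  expect_identical(journal_feature(document("a", title = "t",
                                            journal = "Genetics"))[["jn"]],
                   "genetics")
  expect_identical(journal_feature(document("b", title = "t",
                                            journal = "  Genetics "))[["jn"]],
                   "genetics")
  expect_length(journal_feature(document("c", title = "t")), 0L)
})

test_that("term-count feature counts distinct corpus-list genes", {
  gl <- structure(list(ranked = data.frame(gene = sprintf("G%03d", 1:100),
                                           freq = 100:1),
                       n_cap = 100L), class = "orgfocus_gene_list")
  mk_m <- function(genes) data.frame(surface = genes, canonical = genes,
                                     kind = "gene", section_index = 0L,
                                     sentence_index = 0L,
                                     token_index = seq_along(genes) - 1L)
  doc <- document("a", title = "t")
  expect_equal(unname(term_count_feature(doc, mk_m(sprintf("G%03d", 1:7)),
                                         gl)), 7)
  expect_equal(unname(term_count_feature(doc, mk_m(c("ZZ1", "ZZ2")), gl)), 0)
  # distinct union over a concatenated document
  joint <- mk_m(c(sprintf("G%03d", 1:3), sprintf("G%03d", 4:7)))
  expect_equal(unname(term_count_feature(doc, joint, gl)), 7)
})

test_that("additional gene names come from co-sentence pairs via the table", {
  tab <- load_synonym_table()
  doc <- doc_from_tokens(list(c("IL2", "signalling", "in", "mouse")))
  gm <- tag_gene_mentions(doc, glex)
  om <- tag_organism_mentions(doc, olex)
  feats <- additional_gene_names(doc, gm, om, tab)
  expect_equal(feats[["agn:Interleukin"]], 1)

  expect_length(additional_gene_names(doc, gm, om, tab[0, ]), 0L)

  # the same pair occurring twice counts twice
  doc2 <- doc_from_tokens(list(c("IL2", "in", "mouse"),
                               c("again", "IL2", "with", "mouse")))
  feats2 <- additional_gene_names(doc2, tag_gene_mentions(doc2, glex),
                                  tag_organism_mentions(doc2, olex), tab)
  expect_equal(feats2[["agn:Interleukin"]], 2)
})

test_that("assembly honours ablation semantics and compositionality", {
  doc <- doc_from_tokens(list(c("Adh", "in", "drosophila", "tissue")),
                         doc_id = "z", journal = "Genetics",
                         gold_label = "fly")
  doc$mesh <- c("MH-fly-1")
  doc$title <- "Adh in drosophila"
  gm <- tag_gene_mentions(doc, glex)
  om <- tag_organism_mentions(doc, olex)
  tab <- load_synonym_table()
  sel <- fit_mesh_selector(list(doc), mesh_per_class = 1L)
  gl <- fit_corpus_gene_list(list(gm))
  bundle <- compute_feature_bundle(doc, gm, om, gene_lexicon = glex,
                                   organism_lexicon = olex,
                                   synonym_table = tab)

  only_of <- assemble_features(bundle, feature_config(enabled = "OF"))
  expect_true(all(startsWith(names(only_of$numeric), "of:")))
  expect_length(only_of$categorical, 0L)

  f1 <- assemble_features(bundle, parse_feature_set("F1"),
                          mesh_selector = sel)
  expect_false(any(startsWith(names(f1$numeric), "ts:")))
  expect_false(any(startsWith(names(f1$numeric), "of:")))
  expect_true(any(startsWith(names(f1$numeric), "gn:")))
  expect_identical(names(f1$categorical), "jn")

  full <- assemble_features(bundle, parse_feature_set("full"),
                            mesh_selector = sel, corpus_gene_list = gl)
  cfg <- feature_config()
  manual <- c(gene_name_features(doc, gm, cfg),
              organism_frequency(doc, om, labels3),
              mesh_features(doc, sel),
              title_features(doc, glex, olex),
              term_species_weights(doc, gm, om, cfg, labels3),
              term_count_feature(doc, gm, gl),
              additional_gene_names(doc, gm, om, tab))
  expect_equal(full$numeric[sort(names(full$numeric))],
               manual[sort(names(manual))])
  expect_identical(unname(full$categorical["jn"]), "genetics")

  # removing a family changes only that family's features
  no_ts <- assemble_features(bundle, parse_feature_set("F1+OF+NT+AGN"),
                             mesh_selector = sel, corpus_gene_list = gl)
  kept <- setdiff(names(full$numeric), names(no_ts$numeric))
  expect_true(all(startsWith(kept, "ts:")))

  expect_error(assemble_features(bundle, feature_config(enabled = c("MH"))),
               "mesh selector")
  expect_error(assemble_features(bundle, feature_config(enabled = c("NT"))),
               "gene list")
})

test_that("feature-set names parse with the published aliases", {
  expect_setequal(parse_feature_set("F1")$enabled, c("GN", "MH", "JN", "DT"))
  expect_setequal(parse_feature_set("F1+TS")$enabled,
                  c("GN", "MH", "JN", "DT", "TS"))
  expect_setequal(parse_feature_set("full")$enabled,
                  c("GN", "OF", "MH", "DT", "TS", "JN", "NT", "AGN"))
  expect_setequal(parse_feature_set("F1+ADN")$enabled,
                  c("GN", "MH", "JN", "DT", "AGN"))
  expect_identical(parse_feature_set("F1+TS+OF+NT+AND")$enabled,
                   parse_feature_set("F1+TS+OF+NT+AGN")$enabled)
  expect_error(parse_feature_set("F1+XX"), "unknown")
})
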