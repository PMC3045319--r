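# Shared fixtures, built in code.

# A multi-species abstract: two mouse mentions, one two-token fly mention,
# plus species outside the default label set (zebrafish, Bombyx mori).
multi_species_doc <- function() {
  body <- paste(
    "Coatomer subunits are conserved across species.",
    "We characterized Copg genes from mouse, zebrafish,",
    "Drosophila melanogaster and Bombyx mori.",
    "Mouse Copg1 showed ubiquitous expression with the highest level in testis.",
    "Zebrafish copg2 was biallelically expressed in hybrid larvae.")
  document(doc_id = "pmid-x", title = "Characterization of Copg genes",
           journal = "Genomics",
           sections = list(section(heading = "Abstract", kind = "abstract",
                                   sentences = tokenize(body))))
}

tiny_gene_lexicon <- function() {
  genes <- c("Copg1", "Copg2", "Adh", "CDC28", "IL2")
  lexicon(genes, genes, kind = "gene", provenance = "test fixture")
}

# Single-section document from explicit sentence token vectors.
doc_from_tokens <- function(token_lists, kind = "abstract", doc_id = "d1",
                            ...) {
  offset <- 0L
  sents <- lapply(token_lists, function(toks) {
    s <- sentence(toks, offset)
    offset <<- offset + nchar(paste(toks, collapse = " ")) + 2L
    s
  })
  document(doc_id = doc_id,
           sections = list(section(kind = kind, sentences = sents)), ...)
}

# Minimal feature vector for learner tests.
fv <- function(doc_id, num = numeric(0), cat = character(0)) {
  structure(list(doc_id = doc_id, numeric = num, categorical = cat,
                 config = feature_config()),
            class = "orgfocus_feature_vector")
}

# Small labelled corpus of feature vectors with separable per-class counts.
separable_vectors <- function(n_per_class = 6L, seed = 42L) {
  classes <- c("fly", "mouse", "yeast")
  vecs <- list(); labels <- character(0)
  set.seed(seed)
  for (cl in classes) {
    for (i in seq_len(n_per_class)) {
      num <- stats::setNames(c(3 + rpois(1, 2), rpois(1, 1), rpois(1, 1)),
                             paste0("gn:", c(cl, setdiff(classes, cl))))
      vecs[[length(vecs) + 1L]] <- fv(sprintf("%s-%d", cl, i), num)
      labels <- c(labels, cl)
    }
  }
  list(vectors = vecs, labels = labels)
}
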