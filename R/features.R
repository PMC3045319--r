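# The eight document feature extractors and their assembly into one
# feature vector per document.

FEATURE_FAMILIES <- c("GN", "OF", "MH", "DT", "TS", "JN", "NT", "AGN")

#' Feature configuration
#'
#' @param enabled Non-empty subset of the eight feature families:
#'   GN (per-document top-n gene counts), OF (organism mention frequency),
#'   MH (per-class frequent MeSH headings), DT (title organism/gene
#'   indicators), TS (distance-weighted term-species score), JN (journal
#'   name), NT (count of corpus top-n genes present), AGN (additional gene
#'   names for co-sentence gene-species pairs).
#' @param n_top_genes Cap `n` on ranked gene lists (default 100).
#' @param mesh_per_class Number of MeSH headings selected per class
#'   (default 3).
#' @param ts_decay Term-species distance decay: `"inverse_distance"`
#'   (`1/(1+d)`, default) or `"exponential"` (`2^-d`).
#' @return An object of class `orgfocus_feature_config`.
#' @export
feature_config <- function(enabled = c("GN", "MH", "JN", "DT"),
                           n_top_genes = 100L, mesh_per_class = 3L,
                           ts_decay = c("inverse_distance", "exponential")) {
  enabled <- unique(toupper(enabled))
  if (length(enabled) == 0L) abort_input("at least one feature family required")
  bad <- setdiff(enabled, FEATURE_FAMILIES)
  if (length(bad)) abort_input("unknown feature families: ",
                               paste(bad, collapse = ", "))
  if (n_top_genes < 1L) abort_input("n_top_genes must be >= 1")
  if (mesh_per_class < 1L) abort_input("mesh_per_class must be >= 1")
  ts_decay <- match.arg(ts_decay)
  structure(list(enabled = enabled, n_top_genes = as.integer(n_top_genes),
                 mesh_per_class = as.integer(mesh_per_class),
                 ts_decay = ts_decay),
            class = "orgfocus_feature_config")
}

#' Parse a feature-set name
#'
#' Accepts the naming used in the ablation experiments: `"F1"` is the basic
#' set (GN, MH, JN, DT); `"F1+TS"`, `"F1+OF"`, `"F1+NT"`, `"F1+AGN"` add
#' one family; `"full"` enables all eight; arbitrary `+`-separated
#' combinations such as `"F1+TS+OF+NT+AGN"` work too. `"ADN"` and `"AND"`
#' are accepted as aliases for `AGN`.
#'
#' @param name Feature-set name.
#' @param ... Further arguments to [feature_config()].
#' @return An `orgfocus_feature_config`.
#' @export
parse_feature_set <- function(name, ...) {
  parts <- toupper(strsplit(trimws(name), "+", fixed = TRUE)[[1]])
  parts[parts %in% c("ADN", "AND")] <- "AGN"
  enabled <- character(0)
  for (p in parts) {
    if (p == "F1") enabled <- c(enabled, "GN", "MH", "JN", "DT")
    else if (p == "FULL") enabled <- c(enabled, FEATURE_FAMILIES)
    else if (p %in% FEATURE_FAMILIES) enabled <- c(enabled, p)
    else abort_input("unknown feature-set component: ", p)
  }
  feature_config(enabled = unique(enabled), ...)
}

#' Gene-name features (GN)
#'
#' One count feature per gene in the document's frequency-ranked top-n
#' gene list, named `gn:<symbol>`.
#'
#' @param doc A document (unused beyond interface symmetry).
#' @param gene_mentions Gene-mention data.frame for the document.
#' @param config Feature configuration (supplies `n_top_genes`).
#' @return Named numeric vector.
#' @export
gene_name_features <- function(doc, gene_mentions, config = feature_config()) {
  gl <- rank_genes(gene_mentions, n_cap = config$n_top_genes)
  if (nrow(gl$ranked) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(as.numeric(gl$ranked$freq), paste0("gn:", gl$ranked$gene))
}

#' Organism-frequency features (OF)
#'
#' Raw per-label organism mention counts over the document, named
#' `of:<label>`; labels with no mention get 0.
#'
#' @param doc A document (interface symmetry).
#' @param organism_mentions Organism-mention data.frame.
#' @param labels The configured organism label set.
#' @return Named numeric vector, one entry per label.
#' @export
organism_frequency <- function(doc, organism_mentions,
                               labels = c("fly", "mouse", "yeast")) {
  counts <- table(factor(organism_mentions$canonical, levels = labels))
  stats::setNames(as.numeric(counts), paste0("of:", labels))
}

#' Fit the MeSH-heading selector (MH)
#'
#' Selects, for each class, the `mesh_per_class` most frequent MeSH
#' headings among that class's training documents (frequency, then
#' lexicographic tie-break). Selection must be fit on training folds only.
#'
#' @param docs Training documents with gold labels.
#' @param mesh_per_class Headings per class.
#' @return Object of class `orgfocus_mesh_selector`: per-class selected
#'   headings and their union.
#' @export
fit_mesh_selector <- function(docs, mesh_per_class = 3L) {
  labels <- vapply(docs, `[[`, "", "gold_label")
  if (anyNA(labels)) abort_input("MeSH selection requires gold labels")
  per_class <- list()
  for (cl in sort(unique(labels))) {
    headings <- unlist(lapply(docs[labels == cl], `[[`, "mesh"))
    if (length(headings) == 0L) {
      per_class[[cl]] <- character(0)
      next
    }
    tab <- table(headings)
    df <- data.frame(h = names(tab), n = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n, df$h), , drop = FALSE]
    per_class[[cl]] <- utils::head(df$h, mesh_per_class)
  }
  sel <- structure(list(per_class = per_class,
                        union = sort(unique(unlist(per_class)))),
                   class = "orgfocus_mesh_selector")
  if (length(sel$union) == 0L) {
    warning("training corpus carries no MeSH headings; MH features will be absent",
            call. = FALSE)
  }
  sel
}

#' MeSH-heading features (MH)
#'
#' Binary indicators `mh:<heading>` over the selector's union of selected
#' headings.
#'
#' @param doc A document.
#' @param selector A fitted [fit_mesh_selector()] object.
#' @return Named numeric vector (possibly empty).
#' @export
mesh_features <- function(doc, selector) {
  if (length(selector$union) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  stats::setNames(as.numeric(selector$union %in% doc$mesh),
                  paste0("mh:", selector$union))
}

#' Title features (DT)
#'
#' Per-label organism-in-title indicators `dt:org:<label>` plus
#' `dt:gene:<symbol>` indicators for lexicon genes appearing in the title.
#'
#' @param doc A document.
#' @param gene_lexicon Gene lexicon (or `NULL`).
#' @param organism_lexicon Organism lexicon.
#' @return Named numeric vector.
#' @export
title_features <- function(doc, gene_lexicon, organism_lexicon) {
  title_doc <- document(doc_id = paste0(doc$doc_id, ":title"),
                        title = doc$title,
                        sections = list(section(kind = "other",
                                                sentences = tokenize(doc$title))))
  labels <- lexicon_labels(organism_lexicon)
  orgs <- tag_organism_mentions(title_doc, organism_lexicon)
  out <- stats::setNames(as.numeric(labels %in% orgs$canonical),
                         paste0("dt:org:", labels))
  genes <- tag_gene_mentions(title_doc, gene_lexicon)
  if (nrow(genes) > 0L) {
    g <- sort(unique(genes$canonical))
    out <- c(out, stats::setNames(rep(1, length(g)), paste0("dt:gene:", g)))
  }
  out
}

ts_decay_fn <- function(name) {
  switch(name,
         inverse_distance = function(d) 1 / (1 + d),
         exponential = function(d) 2^(-d),
         abort_input("unknown ts_decay: ", name))
}

#' Term-species distance weights (TS)
#'
#' For every gene-mention/organism-mention pair within the same sentence,
#' the organism receives a contribution decaying with the token distance
#' `d` between the two mentions (default `1/(1+d)`); contributions are
#' tallied per label over the whole article and emitted as `ts:<label>`.
#' Pairs in different sentences contribute nothing.
#'
#' @param doc A document (interface symmetry).
#' @param gene_mentions,organism_mentions Mention data.frames with
#'   sentence/token coordinates.
#' @param config Feature configuration (supplies the decay).
#' @param labels The configured organism label set.
#' @return Named numeric vector, one entry per label.
#' @export
term_species_weights <- function(doc, gene_mentions, organism_mentions,
                                 config = feature_config(),
                                 labels = c("fly", "mouse", "yeast")) {
  decay <- ts_decay_fn(config$ts_decay)
  totals <- stats::setNames(numeric(length(labels)), labels)
  if (nrow(gene_mentions) > 0L && nrow(organism_mentions) > 0L) {
    pairs <- merge(gene_mentions[, c("section_index", "sentence_index",
                                     "token_index")],
                   organism_mentions[, c("section_index", "sentence_index",
                                         "token_index", "canonical")],
                   by = c("section_index", "sentence_index"),
                   suffixes = c("_gene", "_org"))
    if (nrow(pairs) > 0L) {
      w <- decay(abs(pairs$token_index_gene - pairs$token_index_org))
      agg <- tapply(w, pairs$canonical, sum)
      totals[names(agg)] <- totals[names(agg)] +
        ifelse(is.na(as.numeric(agg)), 0, as.numeric(agg))
    }
  }
  stats::setNames(as.numeric(totals), paste0("ts:", labels))
}

#' Journal-name feature (JN)
#'
#' Single categorical feature `jn`: the journal string case-folded and
#' trimmed; absent when the document has no journal.
#'
#' @param doc A document.
#' @return Named character vector of length 0 or 1.
#' @export
journal_feature <- function(doc) {
  j <- tolower(trimws(doc$journal))
  if (!nzchar(j)) return(stats::setNames(character(0), character(0)))
  stats::setNames(j, "jn")
}

#' Fit the corpus-level frequent-gene list (for NT)
#'
#' Pools gene mentions over the training documents and ranks the top-n
#' genes by frequency. Must be fit on training folds only.
#'
#' @param gene_mentions List of gene-mention data.frames (training docs).
#' @param n_top_genes List cap (default 100).
#' @return An `orgfocus_gene_list`.
#' @export
fit_corpus_gene_list <- function(gene_mentions, n_top_genes = 100L) {
  pooled <- do.call(rbind, c(gene_mentions, list(empty_mentions())))
  rank_genes(pooled, n_cap = n_top_genes)
}

#' Term-count feature (NT)
#'
#' The number of distinct genes from the corpus-level top-n frequent gene
#' list occurring in the document.
#'
#' @param doc A document (interface symmetry).
#' @param gene_mentions Gene mentions of the document.
#' @param corpus_gene_list A fitted [fit_corpus_gene_list()].
#' @return Named numeric vector `c(nt = <count>)`.
#' @export
term_count_feature <- function(doc, gene_mentions, corpus_gene_list) {
  present <- unique(gene_mentions$canonical)
  c(nt = sum(present %in% corpus_gene_list$ranked$gene))
}

#' Additional-gene-name features (AGN)
#'
#' For every gene/organism pair co-occurring in a sentence, the (gene,
#' organism) key is looked up in a local synonym table (e.g. ("IL2",
#' mouse) -> "Interleukin"); each hit contributes a count feature
#' `agn:<additional name>`. Pairs absent from the table contribute
#' nothing.
#'
#' @param doc A document (interface symmetry).
#' @param gene_mentions,organism_mentions Mention data.frames.
#' @param synonym_table data.frame from [load_synonym_table()].
#' @return Named numeric vector.
#' @export
additional_gene_names <- function(doc, gene_mentions, organism_mentions,
                                  synonym_table) {
  empty <- stats::setNames(numeric(0), character(0))
  if (nrow(gene_mentions) == 0L || nrow(organism_mentions) == 0L ||
      is.null(synonym_table) || nrow(synonym_table) == 0L) {
    return(empty)
  }
  pairs <- merge(gene_mentions[, c("section_index", "sentence_index",
                                   "canonical")],
                 organism_mentions[, c("section_index", "sentence_index",
                                       "canonical")],
                 by = c("section_index", "sentence_index"),
                 suffixes = c("_gene", "_org"))
  if (nrow(pairs) == 0L) return(empty)
  key <- paste0(pairs$canonical_gene, "\r", pairs$canonical_org)
  tab_key <- paste0(synonym_table$gene, "\r", synonym_table$organism)
  idx <- match(key, tab_key)
  hit <- !is.na(idx)
  if (!any(hit)) return(empty)
  names_hit <- synonym_table$additional[idx[hit]]
  counts <- table(names_hit)
  stats::setNames(as.numeric(counts), paste0("agn:", names(counts)))
}

#' Compute the fold-independent feature bundle of a document
#'
#' Collects everything the per-family extractors need that does not depend
#' on training-fold selectors: mentions-derived counts, TS weights, title
#' indicators, journal token, raw MeSH headings and the distinct gene set.
#' [assemble_features()] turns a bundle plus fold-level selectors into a
#' feature vector; precomputing bundles makes repeated cross-validation
#' cheap.
#'
#' @param doc A document.
#' @param gene_mentions,organism_mentions Mention data.frames.
#' @param config Feature configuration.
#' @param gene_lexicon,organism_lexicon Lexicons (DT family).
#' @param synonym_table AGN synonym table (or `NULL`).
#' @return Object of class `orgfocus_feature_bundle`.
#' @export
compute_feature_bundle <- function(doc, gene_mentions, organism_mentions,
                                   config = feature_config(),
                                   gene_lexicon = NULL,
                                   organism_lexicon = default_organism_lexicon(),
                                   synonym_table = NULL) {
  labels <- lexicon_labels(organism_lexicon)
  structure(list(
    doc_id = doc$doc_id,
    gold_label = doc$gold_label,
    gn = gene_name_features(doc, gene_mentions, config),
    of = organism_frequency(doc, organism_mentions, labels),
    ts = term_species_weights(doc, gene_mentions, organism_mentions,
                              config, labels),
    dt = title_features(doc, gene_lexicon, organism_lexicon),
    jn = journal_feature(doc),
    agn = additional_gene_names(doc, gene_mentions, organism_mentions,
                                synonym_table),
    mesh = doc$mesh,
    genes = unique(gene_mentions$canonical)
  ), class = "orgfocus_feature_bundle")
}

#' Assemble a document feature vector
#'
#' Union of the enabled feature families; disabled families are absent
#' entirely (the ablation semantics: removing a family changes only that
#' family's features). MH and NT require fold-fitted selectors.
#'
#' @param bundle An [compute_feature_bundle()] result (or a document, in
#'   which case mentions and context must be supplied via `...` arguments
#'   of [compute_feature_bundle()]).
#' @param config Feature configuration.
#' @param mesh_selector Fitted [fit_mesh_selector()] (required when MH
#'   enabled).
#' @param corpus_gene_list Fitted [fit_corpus_gene_list()] (required when
#'   NT enabled).
#' @param ... Passed to [compute_feature_bundle()] when `bundle` is a
#'   document.
#' @return Object of class `orgfocus_feature_vector`: `doc_id`, `numeric`
#'   (named numeric features), `categorical` (named character features).
#' @export
assemble_features <- function(bundle, config = feature_config(),
                              mesh_selector = NULL, corpus_gene_list = NULL,
                              ...) {
  if (inherits(bundle, "orgfocus_document")) {
    bundle <- compute_feature_bundle(bundle, config = config, ...)
  }
  stopifnot(inherits(bundle, "orgfocus_feature_bundle"))
  en <- config$enabled
  if ("MH" %in% en && is.null(mesh_selector)) {
    abort_input("MH enabled but no fitted mesh selector supplied")
  }
  if ("NT" %in% en && is.null(corpus_gene_list)) {
    abort_input("NT enabled but no fitted corpus gene list supplied")
  }
  num <- numeric(0)
  if ("GN" %in% en) num <- c(num, bundle$gn)
  if ("OF" %in% en) num <- c(num, bundle$of)
  if ("MH" %in% en) {
    sel <- mesh_selector$union
    if (length(sel)) {
      num <- c(num, stats::setNames(as.numeric(sel %in% bundle$mesh),
                                    paste0("mh:", sel)))
    }
  }
  if ("DT" %in% en) num <- c(num, bundle$dt)
  if ("TS" %in% en) num <- c(num, bundle$ts)
  if ("NT" %in% en) {
    num <- c(num, c(nt = sum(bundle$genes %in% corpus_gene_list$ranked$gene)))
  }
  if ("AGN" %in% en) num <- c(num, bundle$agn)
  cat_feats <- if ("JN" %in% en) bundle$jn else
    stats::setNames(character(0), character(0))
  structure(list(doc_id = bundle$doc_id, numeric = num,
                 categorical = cat_feats, config = config),
            class = "orgfocus_feature_vector")
}

#' @export
print.orgfocus_feature_vector <- function(x, ...) {
  cat(sprintf("<feature vector %s> %d numeric + %d categorical features [%s]\n",
              x$doc_id, length(x$numeric), length(x$categorical),
              paste(x$config$enabled, collapse = ",")))
  invisible(x)
}
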