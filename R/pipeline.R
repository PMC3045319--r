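# Pipeline configuration and per-document preparation shared by the
# cross-validation, ablation and workflow entry points.

#' Pipeline configuration
#'
#' Bundles the resources and switches of the document-processing pipeline:
#' lexicons, the optional synonym table, content selection, the gene
#' pattern rule, simulated tagger noise, and whether rule-triaged documents
#' count toward evaluation totals.
#'
#' @param gene_lexicon Gene lexicon (or `NULL`: pattern rule only).
#' @param organism_lexicon Organism lexicon; defines the label set.
#' @param synonym_table AGN synonym table (or `NULL`).
#' @param content_selection Restrict full-text documents to abstract,
#'   introduction, results and conclusion sections before tagging
#'   (default `TRUE`; switch off to replicate the no-selection ablation).
#' @param reference_distribution Optional reference gene-section
#'   distribution for the heading-less content-selection fallback.
#' @param pattern_rule Enable the symbol-like gene pattern rule.
#' @param tag_noise `NULL`, or `list(fp_rate=, fn_rate=)` to corrupt gene
#'   mentions after tagging (simulating an imperfect statistical tagger).
#' @param score_rule_docs Include title-rule-triaged documents in scoring
#'   (they are always excluded from learner training).
#' @param learner_args Extra arguments passed to the learner's train
#'   function.
#' @return Object of class `orgfocus_pipeline`.
#' @export
pipeline_config <- function(gene_lexicon = NULL,
                            organism_lexicon = default_organism_lexicon(),
                            synonym_table = NULL,
                            content_selection = TRUE,
                            reference_distribution = NULL,
                            pattern_rule = FALSE,
                            tag_noise = NULL,
                            score_rule_docs = TRUE,
                            learner_args = list()) {
  if (!is.null(tag_noise)) {
    stopifnot(is.list(tag_noise),
              all(c("fp_rate", "fn_rate") %in% names(tag_noise)))
  }
  structure(list(gene_lexicon = gene_lexicon,
                 organism_lexicon = organism_lexicon,
                 synonym_table = synonym_table,
                 content_selection = isTRUE(content_selection),
                 reference_distribution = reference_distribution,
                 pattern_rule = isTRUE(pattern_rule),
                 tag_noise = tag_noise,
                 score_rule_docs = isTRUE(score_rule_docs),
                 learner_args = learner_args),
            class = "orgfocus_pipeline")
}

#' Prepare a corpus for classification
#'
#' Runs the fold-independent stages once per document: title triage,
#' content selection, gene and organism tagging (with optional simulated
#' tagger noise), and the feature bundle. The result feeds
#' [k_fold_cv()], [repeated_cv()], [ablation_run()] and [run_workflow()].
#'
#' @param docs List of documents.
#' @param config Feature configuration.
#' @param pipeline A [pipeline_config()].
#' @param seed Seed for the (optional) tagger-noise injection.
#' @return Object of class `orgfocus_prepared`: parallel lists of bundles,
#'   triage results, gene mentions, plus gold labels and the label set.
#' @export
prepare_corpus <- function(docs, config = feature_config(),
                           pipeline = pipeline_config(), seed = 1L) {
  labels <- lexicon_labels(pipeline$organism_lexicon)
  n <- length(docs)
  bundles <- vector("list", n)
  triage <- vector("list", n)
  gene_mentions <- vector("list", n)
  for (i in seq_len(n)) {
    doc <- docs[[i]]
    triage[[i]] <- classify_by_title(doc, pipeline$organism_lexicon)
    sel <- doc
    if (pipeline$content_selection && length(doc$sections) > 0L) {
      gm_for_sel <- if (is.null(pipeline$reference_distribution)) NULL else
        tag_gene_mentions(doc, pipeline$gene_lexicon, pipeline$pattern_rule)
      sel <- select_content(doc, ref = pipeline$reference_distribution,
                            gene_mentions = gm_for_sel)
    }
    gm <- tag_gene_mentions(sel, pipeline$gene_lexicon, pipeline$pattern_rule)
    if (!is.null(pipeline$tag_noise)) {
      gm <- corrupt_gene_tags(gm,
                              fp_rate = pipeline$tag_noise$fp_rate,
                              fn_rate = pipeline$tag_noise$fn_rate,
                              seed = derive_seed(seed, i), doc = sel)
    }
    om <- tag_organism_mentions(sel, pipeline$organism_lexicon)
    gene_mentions[[i]] <- gm
    bundles[[i]] <- compute_feature_bundle(
      sel, gm, om, config = config,
      gene_lexicon = pipeline$gene_lexicon,
      organism_lexicon = pipeline$organism_lexicon,
      synonym_table = pipeline$synonym_table)
  }
  structure(list(bundles = bundles, triage = triage,
                 gene_mentions = gene_mentions,
                 doc_ids = vapply(docs, `[[`, "", "doc_id"),
                 gold = vapply(docs, `[[`, "", "gold_label"),
                 labels = labels, config = config),
            class = "orgfocus_prepared")
}
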