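# End-to-end workflow: normalize -> title rule -> tag -> content-select ->
# features -> learner -> evaluate.

#' Run the classification workflow end to end
#'
#' Orchestrates the full pipeline on a labelled corpus: title-rule triage
#' (triaged documents bypass the learner), content selection, tagging,
#' feature extraction and either k-fold cross-validated evaluation
#' (`mode = "evaluate"`) or training on the whole corpus followed by
#' classification (`mode = "classify"`, optionally against a held-out
#' corpus).
#'
#' @param docs List of documents (e.g. from [read_corpus()] or
#'   [generate_corpus()]).
#' @param feature_set Feature-set name (see [parse_feature_set()]).
#' @param learner_name Registered learner name.
#' @param k Folds for evaluation mode.
#' @param seed RNG seed (mandatory for any stochastic step).
#' @param pipeline A [pipeline_config()].
#' @param mode `"evaluate"` or `"classify"`.
#' @param new_docs Documents to classify in classify mode (defaults to
#'   `docs`).
#' @param abstract_only Project documents to abstracts first.
#' @return For evaluate mode the [k_fold_cv()] result; for classify mode a
#'   list with the trained `model` and a `predictions` data.frame.
#' @export
run_workflow <- function(docs, feature_set = "full", learner_name = "nb",
                         k = 10L, seed = 1L,
                         pipeline = pipeline_config(),
                         mode = c("evaluate", "classify"),
                         new_docs = NULL, abstract_only = FALSE) {
  mode <- match.arg(mode)
  config <- parse_feature_set(feature_set)
  if (isTRUE(abstract_only)) docs <- abstract_only_corpus(docs)
  if (mode == "evaluate") {
    return(k_fold_cv(docs, learner_name = learner_name, config = config,
                     k = k, seed = seed, pipeline = pipeline))
  }
  prepared <- prepare_corpus(docs, config, pipeline, seed = seed)
  is_rule <- vapply(prepared$triage, `[[`, TRUE, "rule_fired")
  train_idx <- which(!is_rule)
  mesh_selector <- if ("MH" %in% config$enabled) {
    suppressWarnings(fit_mesh_selector(prepared$bundles[train_idx],
                                       config$mesh_per_class))
  } else NULL
  gene_list <- if ("NT" %in% config$enabled) {
    fit_corpus_gene_list(prepared$gene_mentions[train_idx],
                         config$n_top_genes)
  } else NULL
  assemble_prep <- function(prep, i) {
    assemble_features(prep$bundles[[i]], config,
                      mesh_selector = mesh_selector,
                      corpus_gene_list = gene_list)
  }
  learner <- get_learner(learner_name)
  # a corpus resolved entirely by the title rule never invokes the learner
  model <- if (length(train_idx) == 0L) NULL else
    do.call(learner$train,
            c(list(vectors = lapply(train_idx,
                                    function(i) assemble_prep(prepared, i)),
                   labels = prepared$gold[train_idx],
                   seed = seed),
              pipeline$learner_args))
  target <- if (is.null(new_docs)) prepared else
    prepare_corpus(if (isTRUE(abstract_only)) abstract_only_corpus(new_docs)
                   else new_docs, config, pipeline, seed = seed)
  preds <- vapply(seq_along(target$bundles), function(i) {
    if (target$triage[[i]]$rule_fired) return(target$triage[[i]]$label)
    if (is.null(model)) {
      abort_input("no trained model: every training document was ",
                  "title-rule triaged but document ", target$doc_ids[i],
                  " is undecided")
    }
    posterior_label(learner$predict(model, assemble_prep(target, i)))
  }, "")
  list(model = model,
       predictions = data.frame(
         doc_id = target$doc_ids, predicted = preds,
         rule_fired = vapply(target$triage, `[[`, TRUE, "rule_fired"),
         gold = target$gold, stringsAsFactors = FALSE))
}
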