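# Scoring, stratified k-fold and repeated cross-validation, the corrected
# resampled t-test, and the feature-ablation harness.

#' One-vs-rest confusion counts
#'
#' Reduces multi-class predictions to binary counts for one positive
#' class: TP (gold and predicted positive), FN (gold positive, predicted
#' other), FP (gold other, predicted positive), TN (both other).
#'
#' @param gold,predicted Aligned label vectors.
#' @param positive_class The class scored as positive.
#' @return Object of class `orgfocus_confusion` with fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_counts <- function(gold, predicted, positive_class) {
  stopifnot(length(gold) == length(predicted))
  gp <- gold == positive_class
  pp <- predicted == positive_class
  structure(list(tp = sum(gp & pp), fp = sum(!gp & pp),
                 fn = sum(gp & !pp), tn = sum(!gp & !pp)),
            class = "orgfocus_confusion")
}

#' Precision, recall and F-score from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)`; a zero denominator
#' yields 0 with a warning.
#'
#' @param cm An [confusion_counts()] object.
#' @return List with `precision`, `recall`, `f_score`.
#' @export
precision_recall_f <- function(cm) {
  p <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else {
    warning("zero positive predictions: precision set to 0", call. = FALSE)
    0
  }
  r <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else {
    warning("zero positive gold labels: recall set to 0", call. = FALSE)
    0
  }
  list(precision = p, recall = r, f_score = f_from_precision_recall(p, r))
}

#' Harmonic-mean F-score from precision and recall
#'
#' @param p,r Precision and recall in `[0, 1]`.
#' @return `2PR/(P+R)`, or 0 when `P + R = 0`.
#' @export
f_from_precision_recall <- function(p, r) {
  ifelse(p + r > 0, 2 * p * r / (p + r), 0)
}

#' Macro-averaged F-score
#'
#' Mean of one-vs-rest F-scores over the classes.
#'
#' @param gold,predicted Aligned label vectors.
#' @param classes Label set (defaults to classes present in `gold`).
#' @return Macro-averaged F in `[0, 1]`.
#' @export
macro_f_score <- function(gold, predicted, classes = sort(unique(gold))) {
  f <- vapply(classes, function(cl) {
    cm <- confusion_counts(gold, predicted, cl)
    suppressWarnings(precision_recall_f(cm)$f_score)
  }, 0)
  mean(f)
}

#' Stratified fold assignment
#'
#' Per-class proportions are preserved: within each class, shuffled
#' indices are dealt cyclically over the k folds. Deterministic under
#' `seed`.
#'
#' @param labels Gold label vector.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold assignment in `1..k`, parallel to `labels`.
#' @export
make_folds <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2L)
  tab <- table(labels)
  if (any(tab < k)) {
    abort_input("class smaller than k: ",
                paste(names(tab)[tab < k], collapse = ", "))
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Train on the non-triaged training portion of one fold split and predict
# its test portion. Returns a data.frame of predictions for the fold.
eval_fold <- function(prepared, folds, fold, learner_name, pipeline, seed,
                      config = prepared$config) {
  learner <- get_learner(learner_name)
  is_rule <- vapply(prepared$triage, `[[`, TRUE, "rule_fired")
  train_idx <- which(folds != fold & !is_rule)
  test_idx <- which(folds == fold)
  if (length(train_idx) == 0L) abort_input("empty training fold")
  mesh_selector <- if ("MH" %in% config$enabled) {
    suppressWarnings(fit_mesh_selector(prepared$bundles[train_idx],
                                       config$mesh_per_class))
  } else NULL
  gene_list <- if ("NT" %in% config$enabled) {
    fit_corpus_gene_list(prepared$gene_mentions[train_idx],
                         config$n_top_genes)
  } else NULL
  assemble <- function(i) {
    assemble_features(prepared$bundles[[i]], config,
                      mesh_selector = mesh_selector,
                      corpus_gene_list = gene_list)
  }
  train_vecs <- lapply(train_idx, assemble)
  model <- do.call(learner$train,
                   c(list(vectors = train_vecs,
                          labels = prepared$gold[train_idx],
                          seed = derive_seed(seed, fold)),
                     pipeline$learner_args))
  pred <- character(length(test_idx))
  rule_fired <- logical(length(test_idx))
  for (j in seq_along(test_idx)) {
    i <- test_idx[j]
    if (is_rule[i]) {
      pred[j] <- prepared$triage[[i]]$label
      rule_fired[j] <- TRUE
    } else {
      pred[j] <- posterior_label(learner$predict(model, assemble(i)))
    }
  }
  data.frame(doc_id = prepared$doc_ids[test_idx],
             gold = prepared$gold[test_idx],
             predicted = pred, fold = fold, rule_fired = rule_fired,
             stringsAsFactors = FALSE)
}

score_predictions <- function(preds, classes, score_rule_docs = TRUE) {
  if (!score_rule_docs) preds <- preds[!preds$rule_fired, , drop = FALSE]
  rows <- lapply(classes, function(cl) {
    m <- suppressWarnings(precision_recall_f(
      confusion_counts(preds$gold, preds$predicted, cl)))
    data.frame(class = cl, precision = m$precision, recall = m$recall,
               f = m$f_score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Stratified k-fold cross-validation
#'
#' Full-pipeline evaluation: title-rule-triaged documents are scored with
#' their rule labels and excluded from learner training; the MeSH selector
#' and corpus gene list are refit inside each training fold (no test
#' leakage); folds are stratified and deterministic under `seed`.
#'
#' @param docs List of gold-labelled documents (or an
#'   [prepare_corpus()] result).
#' @param learner_name Registered learner name (`"nb"`, `"nb_bag"`,
#'   `"nb_boost"`, or a plug-in).
#' @param config Feature configuration.
#' @param k Number of folds (default 10).
#' @param seed RNG seed.
#' @param pipeline A [pipeline_config()].
#' @return Object of class `orgfocus_cv`: pooled `predictions`,
#'   `per_class` pooled metrics, `per_fold` per-class metrics,
#'   `fold_macro_f`, pooled `macro_f`, and the fold assignment.
#' @export
k_fold_cv <- function(docs, learner_name = "nb", config = feature_config(),
                      k = 10L, seed = 1L, pipeline = pipeline_config()) {
  prepared <- if (inherits(docs, "orgfocus_prepared")) docs else
    prepare_corpus(docs, config, pipeline, seed = seed)
  folds <- make_folds(prepared$gold, k, seed = seed)
  preds <- do.call(rbind, lapply(seq_len(k), function(f) {
    eval_fold(prepared, folds, f, learner_name, pipeline, seed)
  }))
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    sc <- score_predictions(preds[preds$fold == f, , drop = FALSE],
                            prepared$labels, pipeline$score_rule_docs)
    cbind(fold = f, sc)
  }))
  fold_macro_f <- vapply(seq_len(k), function(f) {
    mean(per_fold$f[per_fold$fold == f])
  }, 0)
  per_class <- score_predictions(preds, prepared$labels,
                                 pipeline$score_rule_docs)
  structure(list(predictions = preds, per_class = per_class,
                 per_fold = per_fold, fold_macro_f = fold_macro_f,
                 macro_f = mean(per_class$f), folds = folds, k = k,
                 seed = seed, learner = learner_name, config = prepared$config),
            class = "orgfocus_cv")
}

#' @export
print.orgfocus_cv <- function(x, ...) {
  cat(sprintf("<%d-fold CV> learner=%s features=%s macro-F=%.3f\n",
              x$k, x$learner, paste(x$config$enabled, collapse = "+"),
              x$macro_f))
  df <- x$per_class
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-8s P=%.3f R=%.3f F=%.3f\n", df$class[i],
                df$precision[i], df$recall[i], df$f[i]))
  }
  invisible(x)
}

#' Specification of one arm of a paired comparison
#'
#' @param learner_name Registered learner name.
#' @param config Feature configuration.
#' @param abstract_only Project documents to their abstract before the
#'   pipeline (the full-text versus abstract comparison).
#' @return List of class `orgfocus_cv_spec`.
#' @export
cv_spec <- function(learner_name = "nb", config = feature_config(),
                    abstract_only = FALSE) {
  structure(list(learner_name = learner_name, config = config,
                 abstract_only = isTRUE(abstract_only)),
            class = "orgfocus_cv_spec")
}

#' Repeated (runs x k) paired cross-validation
#'
#' Evaluates two specifications on identical fold partitions in each of
#' `runs` k-fold repetitions and returns the runs*k paired per-fold
#' macro-F differences (spec A minus spec B), the input to
#' [corrected_resampled_ttest()].
#'
#' @param docs Gold-labelled documents.
#' @param spec_a,spec_b [cv_spec()] objects.
#' @param runs Number of repetitions (default 10).
#' @param k Folds per repetition (default 10).
#' @param seed RNG seed.
#' @param pipeline A [pipeline_config()].
#' @return Object of class `orgfocus_repeated_cv`: `diffs`, per-fold
#'   `scores_a` and `scores_b`, and the average train/test sizes.
#' @export
repeated_cv <- function(docs, spec_a, spec_b, runs = 10L, k = 10L,
                        seed = 1L, pipeline = pipeline_config()) {
  prep_for <- function(spec) {
    d <- if (spec$abstract_only) abstract_only_corpus(docs) else docs
    prepare_corpus(d, spec$config, pipeline, seed = seed)
  }
  prep_a <- prep_for(spec_a)
  # bundles depend only on n_top_genes and ts_decay, not on the enabled
  # families, so specs differing only in families share one preparation
  same_bundles <- identical(spec_b$abstract_only, spec_a$abstract_only) &&
    identical(spec_b$config$n_top_genes, spec_a$config$n_top_genes) &&
    identical(spec_b$config$ts_decay, spec_a$config$ts_decay)
  prep_b <- if (same_bundles) prep_a else prep_for(spec_b)
  gold <- prep_a$gold
  scores_a <- numeric(0); scores_b <- numeric(0)
  for (r in seq_len(runs)) {
    folds <- make_folds(gold, k, seed = derive_seed(seed, r))
    for (f in seq_len(k)) {
      pa <- eval_fold(prep_a, folds, f, spec_a$learner_name, pipeline,
                      derive_seed(seed, r * 1000L + f),
                      config = spec_a$config)
      pb <- eval_fold(prep_b, folds, f, spec_b$learner_name, pipeline,
                      derive_seed(seed, r * 1000L + f),
                      config = spec_b$config)
      if (!pipeline$score_rule_docs) {
        pa <- pa[!pa$rule_fired, , drop = FALSE]
        pb <- pb[!pb$rule_fired, , drop = FALSE]
      }
      scores_a <- c(scores_a, macro_f_score(pa$gold, pa$predicted,
                                            prep_a$labels))
      scores_b <- c(scores_b, macro_f_score(pb$gold, pb$predicted,
                                            prep_b$labels))
    }
  }
  n <- length(gold)
  structure(list(diffs = scores_a - scores_b, scores_a = scores_a,
                 scores_b = scores_b, runs = runs, k = k,
                 n_train = n * (k - 1) / k, n_test = n / k),
            class = "orgfocus_repeated_cv")
}

#' Corrected resampled t-test
#'
#' Paired t-test for repeated cross-validation whose variance term is
#' inflated by the test/train size ratio to account for overlapping
#' training sets:
#' `t = mean(d) / sqrt((1/J + n_test/n_train) * var(d))` with `J`
#' differences and unbiased sample variance, compared against Student's t
#' with `J - 1` degrees of freedom (two-tailed). With the correction term
#' zeroed it reduces to the classic paired t statistic. Zero variance with
#' zero mean gives `t = 0, p = 1`; zero variance with nonzero mean is
#' flagged degenerate with `p = 0`.
#'
#' @param diffs Paired per-fold score differences (length >= 2), or an
#'   [repeated_cv()] result.
#' @param n_train,n_test Training and test set sizes per fold (ignored
#'   when `diffs` is a `orgfocus_repeated_cv`).
#' @return List with `t`, `p_value`, `df`, `mean_diff`, `degenerate`.
#' @export
corrected_resampled_ttest <- function(diffs, n_train = NULL, n_test = NULL) {
  if (inherits(diffs, "orgfocus_repeated_cv")) {
    n_train <- diffs$n_train
    n_test <- diffs$n_test
    diffs <- diffs$diffs
  }
  J <- length(diffs)
  stopifnot(J >= 2L, !is.null(n_train), !is.null(n_test), n_train > 0)
  m <- mean(diffs)
  v <- stats::var(diffs)
  if (v == 0) {
    if (m == 0) {
      return(list(t = 0, p_value = 1, df = J - 1L, mean_diff = 0,
                  degenerate = FALSE))
    }
    return(list(t = sign(m) * Inf, p_value = 0, df = J - 1L, mean_diff = m,
                degenerate = TRUE))
  }
  t_stat <- m / sqrt((1 / J + n_test / n_train) * v)
  p <- 2 * stats::pt(-abs(t_stat), df = J - 1L)
  list(t = t_stat, p_value = p, df = J - 1L, mean_diff = m,
       degenerate = FALSE)
}

#' Feature/learner ablation grid
#'
#' Evaluates every (learner, feature set) combination by k-fold
#' cross-validation on identical fold partitions and tabulates per-class
#' and macro-averaged precision/recall/F.
#'
#' @param docs Gold-labelled documents.
#' @param learner_names Character vector of registered learner names.
#' @param feature_sets Character vector of feature-set names (see
#'   [parse_feature_set()]).
#' @param k,seed,pipeline As for [k_fold_cv()].
#' @param ... Further arguments to [parse_feature_set()].
#' @return Object of class `orgfocus_ablation`: a data.frame grid
#'   (`model`, `feature_set`, `class`, `precision`, `recall`, `f`) with a
#'   `"macro"` class row per cell, plus metadata.
#' @export
ablation_run <- function(docs, learner_names = "nb",
                         feature_sets = c("F1", "F1+TS"), k = 10L,
                         seed = 1L, pipeline = pipeline_config(), ...) {
  rows <- list()
  for (fs in feature_sets) {
    config <- parse_feature_set(fs, ...)
    prepared <- prepare_corpus(docs, config, pipeline, seed = seed)
    for (ln in learner_names) {
      cv <- k_fold_cv(prepared, learner_name = ln, k = k, seed = seed,
                      pipeline = pipeline)
      grid <- rbind(cv$per_class,
                    data.frame(class = "macro",
                               precision = mean(cv$per_class$precision),
                               recall = mean(cv$per_class$recall),
                               f = cv$macro_f, stringsAsFactors = FALSE))
      rows[[length(rows) + 1L]] <- cbind(model = ln, feature_set = fs, grid)
    }
  }
  structure(list(grid = do.call(rbind, rows), k = k, seed = seed),
            class = "orgfocus_ablation")
}

#' @export
print.orgfocus_ablation <- function(x, ...) {
  cat(format_ablation(x), sep = "\n")
  invisible(x)
}

#' Format an ablation report as an aligned-column table
#'
#' @param report An [ablation_run()] result.
#' @return Character vector of lines (model x feature-set x class x
#'   P/R/F).
#' @export
format_ablation <- function(report) {
  g <- report$grid
  header <- sprintf("%-10s %-16s %-8s %9s %9s %9s",
                    "model", "feature_set", "class", "P", "R", "F")
  body <- sprintf("%-10s %-16s %-8s %9.3f %9.3f %9.3f",
                  g$model, g$feature_set, g$class, g$precision, g$recall, g$f)
  c(header, body)
}

#' Write an ablation report as CSV
#'
#' @param report An [ablation_run()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ablation_csv <- function(report, path) {
  utils::write.csv(report$grid, path, row.names = FALSE)
  invisible(path)
}
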