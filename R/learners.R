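# Multinomial Naive Bayes with add-alpha smoothing, bagging and
# AdaBoost.M1 ensembles over it, a section-sequence aggregation classifier,
# and a plug-in registry for external learners.

#' Train a multinomial Naive Bayes model
#'
#' Count-valued features follow a multinomial event model with add-alpha
#' smoothing over the training feature domain; categorical features (the
#' journal name) get their own per-class conditional table with add-alpha
#' smoothing over the observed category domain, keeping the independence
#' factorization correct for mixed feature types. Supports per-example
#' weights (used by AdaBoost).
#'
#' @param vectors List of `orgfocus_feature_vector` objects.
#' @param labels Character vector of gold labels, parallel to `vectors`.
#' @param alpha Smoothing pseudo-count (default 1).
#' @param weights Optional non-negative example weights.
#' @param classes Optional label set; every class must have at least one
#'   (positive-weight) example.
#' @return Object of class `orgfocus_nb`.
#' @export
train_naive_bayes <- function(vectors, labels, alpha = 1, weights = NULL,
                              classes = NULL) {
  n <- length(vectors)
  stopifnot(n == length(labels), n > 0L, alpha > 0)
  labels <- as.character(labels)
  weights <- weights %||% rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  # normalize weights to mean 1 so that uniform weighting reproduces the
  # unweighted model exactly under the same smoothing
  weights <- weights * n / sum(weights)
  classes <- classes %||% sort(unique(labels))
  if (length(classes) < 2L) abort_input("need at least two classes")
  class_w <- vapply(classes, function(cl) sum(weights[labels == cl]), 0)
  if (any(class_w <= 0)) {
    abort_input("class with zero examples: ",
                paste(classes[class_w <= 0], collapse = ", "))
  }
  num_list <- lapply(vectors, `[[`, "numeric")
  feat_names <- sort(unique(unlist(lapply(num_list, names))))
  n_class <- length(classes)
  n_feat <- length(feat_names)
  counts <- matrix(0, nrow = n_class, ncol = n_feat,
                   dimnames = list(classes, feat_names))
  if (n_feat > 0L) {
    lens <- lengths(num_list)
    all_vals <- unlist(num_list, use.names = FALSE) *
      rep.int(weights, lens)
    all_fidx <- match(unlist(lapply(num_list, names), use.names = FALSE),
                      feat_names)
    all_cidx <- rep.int(match(labels, classes), lens)
    if (length(all_vals)) {
      lin <- (all_fidx - 1L) * n_class + all_cidx
      agg <- rowsum(all_vals, lin)
      counts[as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  totals <- rowSums(counts)
  loglik <- if (n_feat > 0L) {
    log(counts + alpha) - log(totals + alpha * n_feat)
  } else counts
  # categorical conditionals
  cat_list <- lapply(vectors, `[[`, "categorical")
  cat_names <- sort(unique(unlist(lapply(cat_list, names))))
  cat_tables <- list()
  for (f in cat_names) {
    vals <- vapply(cat_list, function(x) {
      if (f %in% names(x)) unname(x[[f]]) else NA_character_
    }, "")
    domain <- sort(unique(vals[!is.na(vals)]))
    logp <- matrix(NA_real_, nrow = n_class, ncol = length(domain),
                   dimnames = list(classes, domain))
    for (ci in seq_len(n_class)) {
      in_class <- labels == classes[ci] & !is.na(vals)
      cw <- vapply(domain, function(v) sum(weights[in_class & vals == v]), 0)
      logp[ci, ] <- log(cw + alpha) - log(sum(cw) + alpha * length(domain))
    }
    cat_tables[[f]] <- list(domain = domain, logp = logp)
  }
  structure(list(classes = classes,
                 log_priors = stats::setNames(log(class_w / sum(class_w)),
                                              classes),
                 feat_names = feat_names,
                 loglik = loglik,
                 cat_tables = cat_tables,
                 alpha = alpha),
            class = "orgfocus_nb")
}

#' @export
print.orgfocus_nb <- function(x, ...) {
  cat(sprintf("<naive Bayes> %d classes (%s), %d count features, %d categorical, alpha=%g\n",
              length(x$classes), paste(x$classes, collapse = ","),
              length(x$feat_names), length(x$cat_tables), x$alpha))
  invisible(x)
}

#' Posterior over labels for one feature vector
#'
#' Generic prediction interface shared by Naive Bayes models, ensembles
#' and plug-in learners. Feature names unseen in training are ignored, as
#' are categorical values outside the training domain; a vector carrying
#' no known evidence yields the class priors.
#'
#' @param model A trained model.
#' @param vector An `orgfocus_feature_vector`.
#' @return Named probability vector over classes (class
#'   `orgfocus_posterior`), summing to 1.
#' @export
predict_posterior <- function(model, vector) UseMethod("predict_posterior")

#' @rdname predict_posterior
#' @export
predict_posterior.orgfocus_nb <- function(model, vector) {
  scores <- model$log_priors
  x <- vector$numeric
  if (length(x) > 0L && length(model$feat_names) > 0L) {
    idx <- match(names(x), model$feat_names)
    keep <- !is.na(idx)
    if (any(keep)) {
      scores <- scores +
        as.numeric(model$loglik[, idx[keep], drop = FALSE] %*% x[keep])
    }
  }
  cx <- vector$categorical
  for (f in names(cx)) {
    tab <- model$cat_tables[[f]]
    if (is.null(tab)) next
    v <- unname(cx[[f]])
    if (v %in% tab$domain) scores <- scores + tab$logp[, v]
  }
  lse <- log_sum_exp(scores)
  structure(stats::setNames(exp(scores - lse), model$classes),
            class = "orgfocus_posterior")
}

#' Most probable label of a posterior
#'
#' Ties are broken deterministically by label order (first label wins).
#'
#' @param posterior A named probability vector.
#' @return The argmax label.
#' @export
posterior_label <- function(posterior) {
  names(posterior)[which.max(posterior)]
}

#' Train a bagging ensemble of Naive Bayes models
#'
#' `n_bags` bootstrap resamples (with replacement, original size), one
#' Naive Bayes member per bag, equal member weights. A resample missing a
#' class is redrawn (at most 100 attempts). Deterministic under `seed`.
#'
#' @param vectors,labels,alpha As for [train_naive_bayes()].
#' @param n_bags Number of bootstrap members (default 10).
#' @param seed RNG seed.
#' @return Object of class `orgfocus_ensemble` with `method = "bagging"`.
#' @export
train_bagging <- function(vectors, labels, n_bags = 10L, alpha = 1,
                          seed = NULL) {
  stopifnot(n_bags >= 1L)
  n <- length(vectors)
  classes <- sort(unique(as.character(labels)))
  members <- with_seed(seed, {
    lapply(seq_len(n_bags), function(b) {
      for (attempt in seq_len(100L)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (all(classes %in% labels[idx])) {
          return(train_naive_bayes(vectors[idx], labels[idx], alpha = alpha,
                                   classes = classes))
        }
      }
      abort_input("bootstrap resample missing a class after 100 attempts")
    })
  })
  structure(list(members = members, weights = rep(1 / n_bags, n_bags),
                 method = "bagging", classes = classes, seed = seed),
            class = "orgfocus_ensemble")
}

#' Train an AdaBoost.M1 ensemble of Naive Bayes models
#'
#' Multiclass AdaBoost.M1 with weighted Naive Bayes base learners: round
#' t trains on the current example weights, the weighted training error
#' eps determines the member weight `ln((1-eps)/eps)`, correctly
#' classified examples are down-weighted by `eps/(1-eps)`, and the loop
#' terminates early when eps reaches 0 or 0.5.
#'
#' @param vectors,labels,alpha As for [train_naive_bayes()].
#' @param rounds Maximum boosting rounds (default 10).
#' @param seed Kept for interface symmetry (the procedure is
#'   deterministic).
#' @return Object of class `orgfocus_ensemble` with `method = "adaboost"`.
#' @export
train_adaboost <- function(vectors, labels, rounds = 10L, alpha = 1,
                           seed = NULL) {
  stopifnot(rounds >= 1L)
  n <- length(vectors)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  w <- rep(1 / n, n)
  members <- list()
  mweights <- numeric(0)
  for (t in seq_len(rounds)) {
    model <- train_naive_bayes(vectors, labels, alpha = alpha, weights = w,
                               classes = classes)
    preds <- vapply(vectors,
                    function(v) posterior_label(predict_posterior(model, v)),
                    "")
    wrong <- preds != labels
    eps <- sum(w[wrong]) / sum(w)
    if (eps == 0) {
      members[[length(members) + 1L]] <- model
      mweights <- c(mweights, log((1 - 1e-10) / 1e-10))
      break
    }
    if (eps >= 0.5) {
      if (length(members) == 0L) {
        members[[1L]] <- model
        mweights <- 1
      }
      break
    }
    beta <- eps / (1 - eps)
    members[[length(members) + 1L]] <- model
    mweights <- c(mweights, log(1 / beta))
    w[!wrong] <- w[!wrong] * beta
    w <- w / sum(w)
  }
  structure(list(members = members, weights = mweights, method = "adaboost",
                 classes = classes, seed = seed),
            class = "orgfocus_ensemble")
}

#' @export
print.orgfocus_ensemble <- function(x, ...) {
  cat(sprintf("<%s ensemble> %d members, classes: %s\n",
              x$method, length(x$members), paste(x$classes, collapse = ",")))
  invisible(x)
}

#' @rdname predict_posterior
#' @export
predict_posterior.orgfocus_ensemble <- function(model, vector) {
  posts <- lapply(model$members, predict_posterior, vector = vector)
  if (model$method == "bagging") {
    w <- model$weights / sum(model$weights)
    p <- Reduce(`+`, Map(function(po, wi) wi * as.numeric(po), posts, w))
    p <- stats::setNames(p / sum(p), model$classes)
  } else {
    votes <- stats::setNames(numeric(length(model$classes)), model$classes)
    for (i in seq_along(posts)) {
      votes[posterior_label(posts[[i]])] <- votes[posterior_label(posts[[i]])] +
        model$weights[i]
    }
    p <- if (sum(votes) > 0) votes / sum(votes) else
      stats::setNames(rep(1 / length(votes), length(votes)), model$classes)
  }
  structure(p, class = "orgfocus_posterior")
}

#' Classify a document by aggregating section-level predictions
#'
#' Two-stage scheme echoing sequence labelling over sections: each section
#' is classified on its own feature vector, and the document label is the
#' argmax of the length-normalized sum of section log-posteriors,
#' optionally weighted per section kind. Needs no section-level gold
#' labels.
#'
#' @param model A model trained on section-level feature vectors.
#' @param doc A [document()] with at least one section.
#' @param featurize Function mapping a single-section document to an
#'   `orgfocus_feature_vector`.
#' @param section_weights Optional named weights per section kind
#'   (default uniform).
#' @return The predicted organism label.
#' @export
classify_by_sections <- function(model, doc, featurize,
                                 section_weights = NULL) {
  if (length(doc$sections) == 0L) abort_input("document has zero sections")
  total <- NULL
  wsum <- 0
  for (sec in doc$sections) {
    sub <- doc
    sub$sections <- list(sec)
    post <- predict_posterior(model, featurize(sub))
    w <- if (is.null(section_weights)) 1 else
      (section_weights[[sec$kind]] %||% 1)
    lp <- log(pmax(as.numeric(post), 1e-300))
    total <- if (is.null(total)) w * lp else total + w * lp
    wsum <- wsum + w
  }
  scores <- stats::setNames(total / wsum, model$classes)
  names(scores)[which.max(scores)]
}

# ---- plug-in learner registry ----------------------------------------------

.learner_registry <- new.env(parent = emptyenv())

#' Register a learner
#'
#' Plug-in interface for benchmarking external learners on the same folds
#' as the built-in ones: a learner is a `train(vectors, labels, seed, ...)`
#' function returning a model and a `predict(model, vector)` function
#' returning a label posterior. `"nb"`, `"nb_bag"` and `"nb_boost"` are
#' pre-registered.
#'
#' @param name Learner name (used by evaluation and the CLI).
#' @param train_fn Training function.
#' @param predict_fn Prediction function.
#' @param overwrite Allow replacing an existing registration.
#' @return Invisibly, the name.
#' @export
register_learner <- function(name, train_fn, predict_fn, overwrite = FALSE) {
  stopifnot(is.character(name), nzchar(name),
            is.function(train_fn), is.function(predict_fn))
  if (!overwrite && exists(name, envir = .learner_registry, inherits = FALSE)) {
    abort_input("learner already registered: ", name)
  }
  assign(name, list(train = train_fn, predict = predict_fn),
         envir = .learner_registry)
  invisible(name)
}

#' @rdname register_learner
#' @export
list_learners <- function() sort(ls(.learner_registry))

get_learner <- function(name) {
  if (!exists(name, envir = .learner_registry, inherits = FALSE)) {
    abort_input("unknown learner: ", name,
                " (registered: ", paste(list_learners(), collapse = ", "), ")")
  }
  get(name, envir = .learner_registry, inherits = FALSE)
}

register_builtin_learners <- function() {
  register_learner("nb",
    function(vectors, labels, seed = NULL, alpha = 1, ...) {
      train_naive_bayes(vectors, labels, alpha = alpha)
    },
    predict_posterior, overwrite = TRUE)
  register_learner("nb_bag",
    function(vectors, labels, seed = NULL, n_bags = 10L, alpha = 1, ...) {
      train_bagging(vectors, labels, n_bags = n_bags, alpha = alpha,
                    seed = seed)
    },
    predict_posterior, overwrite = TRUE)
  register_learner("nb_boost",
    function(vectors, labels, seed = NULL, rounds = 10L, alpha = 1, ...) {
      train_adaboost(vectors, labels, rounds = rounds, alpha = alpha,
                     seed = seed)
    },
    predict_posterior, overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_learners()
}

# ---- model serialization ---------------------------------------------------

#' Write a trained model to a versioned JSON file
#'
#' Doubles are written at 17 significant digits so that
#' [read_model()] followed by prediction reproduces training-time
#' predictions bit-exactly.
#'
#' @param model An `orgfocus_nb` or `orgfocus_ensemble`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  payload <- list(format_version = 1L, model = model_to_list(model))
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

model_to_list <- function(model) {
  if (inherits(model, "orgfocus_nb")) {
    list(type = "nb", classes = model$classes,
         log_priors = unname(model$log_priors),
         feat_names = model$feat_names,
         loglik = if (length(model$feat_names)) unclass(model$loglik) else
           matrix(0, length(model$classes), 0),
         cat_tables = lapply(model$cat_tables, function(tab) {
           list(domain = tab$domain, logp = unclass(tab$logp))
         }),
         alpha = model$alpha)
  } else if (inherits(model, "orgfocus_ensemble")) {
    list(type = "ensemble", method = model$method, classes = model$classes,
         weights = model$weights,
         members = lapply(model$members, model_to_list))
  } else {
    abort_input("cannot serialize model of class ",
                paste(class(model), collapse = "/"))
  }
}

#' Read a model written by [write_model()]
#'
#' @param path Path to the model file.
#' @return The deserialized model.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort_input("model file does not exist: ", path)
  payload <- jsonlite::fromJSON(paste(readLines(path, warn = FALSE),
                                      collapse = "\n"),
                                simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  if (is.null(payload$format_version) || payload$format_version != 1L) {
    abort_input("unsupported model file version")
  }
  list_to_model(payload$model)
}

list_to_model <- function(x) {
  if (identical(x$type, "nb")) {
    classes <- as.character(x$classes)
    feat_names <- as.character(x$feat_names)
    loglik <- matrix(as.numeric(unlist(x$loglik)), nrow = length(classes),
                     dimnames = list(classes, feat_names))
    cat_tables <- lapply(x$cat_tables, function(tab) {
      domain <- as.character(tab$domain)
      list(domain = domain,
           logp = matrix(as.numeric(unlist(tab$logp)), nrow = length(classes),
                         dimnames = list(classes, domain)))
    })
    structure(list(classes = classes,
                   log_priors = stats::setNames(as.numeric(x$log_priors),
                                                classes),
                   feat_names = feat_names, loglik = loglik,
                   cat_tables = cat_tables, alpha = as.numeric(x$alpha)),
              class = "orgfocus_nb")
  } else if (identical(x$type, "ensemble")) {
    members <- lapply(x$members, list_to_model)
    structure(list(members = members, weights = as.numeric(x$weights),
                   method = as.character(x$method),
                   classes = as.character(x$classes), seed = NULL),
              class = "orgfocus_ensemble")
  } else {
    abort_input("unknown model type in file")
  }
}
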