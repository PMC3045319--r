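test_that("naive Bayes smoothing matches hand arithmetic", {
  vecs <- list(fv("x1", c(a = 3, b = 1)), fv("y1", c(a = 1, b = 3)))
  model <- train_naive_bayes(vecs, c("X", "Y"), alpha = 1)
  expect_equal(exp(model$loglik["X", "a"]), 4 / 6)
  expect_equal(exp(model$loglik["Y", "a"]), 2 / 6)

  post <- predict_posterior(model, fv("q", c(a = 1)))
  expect_equal(unname(post[["X"]]), 2 / 3)

  # no evidence -> priors
  expect_equal(unname(as.numeric(predict_posterior(model, fv("q")))),
               c(0.5, 0.5))
  expect_equal(unname(as.numeric(predict_posterior(model,
                                                   fv("q", c(zz = 5))))),
               c(0.5, 0.5))

  expect_error(train_naive_bayes(list(fv("a", c(x = 1))), "X"),
               "two classes")
})

test_that("duplicating the training set preserves priors and count proportions", {
  vecs <- list(fv("x1", c(a = 3, b = 1)), fv("y1", c(a = 1, b = 3)))
  m1 <- train_naive_bayes(vecs, c("X", "Y"))
  m2 <- train_naive_bayes(c(vecs, vecs), c("X", "Y", "X", "Y"))
  expect_equal(m1$log_priors, m2$log_priors)
  # conditionals are count-proportional: identical in the small-alpha limit
  # (with a fixed pseudo-count the smoothed estimates shrink differently)
  m1s <- train_naive_bayes(vecs, c("X", "Y"), alpha = 1e-9)
  m2s <- train_naive_bayes(c(vecs, vecs), c("X", "Y", "X", "Y"),
                           alpha = 1e-9)
  expect_equal(m1s$loglik, m2s$loglik, tolerance = 1e-8)
  # equal per-example weights reproduce the unweighted model exactly
  m3 <- train_naive_bayes(vecs, c("X", "Y"), weights = c(7, 7))
  expect_equal(m1$loglik, m3$loglik)
})

test_that("naive Bayes equals brute-force Bayes enumeration on toy problems", {
  classes <- c("A", "B", "C")
  feats <- c("f1", "f2", "f3")
  for (rep_seed in 1:20) {
    set.seed(rep_seed)
    n <- 12L
    labels <- sample(classes, n, replace = TRUE)
    while (length(unique(labels)) < 3L) labels <- sample(classes, n, TRUE)
    counts <- matrix(rpois(n * 3, 1.2), nrow = n,
                     dimnames = list(NULL, feats))
    vecs <- lapply(seq_len(n), function(i) {
      fv(paste0("d", i), counts[i, ],
         cat = stats::setNames(c("ja", "jb")[i %% 2L + 1L], "jn"))
    })
    cats <- vapply(vecs, function(v) v$categorical[["jn"]], "")
    alpha <- 1
    model <- train_naive_bayes(vecs, labels, alpha = alpha)
    # query vector
    q <- fv("q", stats::setNames(rpois(3, 1), feats),
            cat = c(jn = sample(c("ja", "jb"), 1)))
    got <- predict_posterior(model, q)
    # independent oracle: direct arithmetic over counts
    logjoint <- vapply(classes, function(cl) {
      idx <- labels == cl
      lp <- log(sum(idx) / n)
      tot <- sum(counts[idx, , drop = FALSE])
      for (f in feats) {
        p_f <- (sum(counts[idx, f]) + alpha) / (tot + alpha * length(feats))
        lp <- lp + q$numeric[[f]] * log(p_f)
      }
      dom <- sort(unique(cats))
      n_v <- sum(cats[idx] == q$categorical[["jn"]])
      lp + log((n_v + alpha) / (sum(idx) + alpha * length(dom)))
    }, 0)
    oracle <- exp(logjoint - max(logjoint))
    oracle <- oracle / sum(oracle)
    expect_equal(unname(as.numeric(got)), unname(oracle), tolerance = 1e-9)
  }
})

test_that("count scaling shifts scores monotonically but preserves ranking", {
  vecs <- list(fv("x1", c(a = 4, b = 1)), fv("x2", c(a = 5, b = 2)),
               fv("y1", c(a = 1, b = 4)), fv("y2", c(a = 2, b = 5)))
  model <- train_naive_bayes(vecs, c("X", "X", "Y", "Y"))
  for (k in c(1, 2, 5)) {
    post <- predict_posterior(model, fv("q", c(a = 3 * k, b = 1 * k)))
    expect_identical(posterior_label(post), "X")
  }
})

test_that("bagging is seed-reproducible and redraws degenerate resamples", {
  d <- separable_vectors()
  e1 <- train_bagging(d$vectors, d$labels, n_bags = 5L, seed = 7)
  e2 <- train_bagging(d$vectors, d$labels, n_bags = 5L, seed = 7)
  expect_identical(e1, e2)
  expect_length(e1$members, 5L)
  expect_equal(e1$weights, rep(0.2, 5))

  one <- train_bagging(d$vectors, d$labels, n_bags = 1L, seed = 1)
  expect_length(one$members, 1L)
  expect_s3_class(one$members[[1]], "orgfocus_nb")

  # training-set accuracy close to the single model's
  acc <- function(model) {
    preds <- vapply(d$vectors,
                    function(v) posterior_label(predict_posterior(model, v)),
                    "")
    mean(preds == d$labels)
  }
  nb <- train_naive_bayes(d$vectors, d$labels)
  bag <- train_bagging(d$vectors, d$labels, n_bags = 25L, seed = 11)
  expect_gte(acc(bag), acc(nb) - 0.02)
})

test_that("adaboost stops early on zero error and matches the weight recursion", {
  d <- separable_vectors()
  ens <- train_adaboost(d$vectors, d$labels, rounds = 5L)
  if (length(ens$members) == 1L) {
    # zero training error at round one
    preds <- vapply(d$vectors, function(v)
      posterior_label(predict_posterior(ens$members[[1]], v)), "")
    expect_identical(preds, d$labels)
  }

  # a noisier problem that boosting cannot fit perfectly
  set.seed(5)
  vecs <- lapply(1:30, function(i) fv(paste0("d", i),
                                      c(a = rpois(1, 2), b = rpois(1, 2))))
  labels <- rep(c("X", "Y"), 15)
  ens2 <- train_adaboost(vecs, labels, rounds = 4L)
  # oracle: replay AdaBoost.M1 weight recursion from the member predictions
  n <- length(vecs)
  w <- rep(1 / n, n)
  for (t in seq_along(ens2$members)) {
    preds <- vapply(vecs, function(v)
      posterior_label(predict_posterior(ens2$members[[t]], v)), "")
    eps <- sum(w[preds != labels]) / sum(w)
    if (eps == 0 || eps >= 0.5) break
    expect_equal(ens2$weights[t], log((1 - eps) / eps), tolerance = 1e-12)
    beta <- eps / (1 - eps)
    w[preds == labels] <- w[preds == labels] * beta
    w <- w / sum(w)
  }

  # first round with uniform weights equals plain naive Bayes
  nb <- train_naive_bayes(vecs, labels)
  expect_equal(ens2$members[[1]]$loglik, nb$loglik)
  expect_equal(ens2$members[[1]]$log_priors, nb$log_priors)
})

test_that("ensemble prediction aggregates members as documented", {
  vecs <- list(fv("x1", c(a = 3, b = 1)), fv("y1", c(a = 1, b = 3)))
  nb <- train_naive_bayes(vecs, c("X", "Y"))
  one <- structure(list(members = list(nb), weights = 1, method = "bagging",
                        classes = nb$classes, seed = NULL),
                   class = "orgfocus_ensemble")
  q <- fv("q", c(a = 2))
  expect_equal(as.numeric(predict_posterior(one, q)),
               as.numeric(predict_posterior(nb, q)))

  two <- structure(list(members = list(nb, nb), weights = c(0.5, 0.5),
                        method = "bagging", classes = nb$classes,
                        seed = NULL), class = "orgfocus_ensemble")
  expect_equal(as.numeric(predict_posterior(two, q)),
               as.numeric(predict_posterior(nb, q)))

  # adaboost: weighted argmax votes; 2 votes X (weights 1.0, 0.5) vs 1 vote Y
  nb_y <- train_naive_bayes(list(fv("a", c(a = 1, b = 3)),
                                 fv("b", c(a = 3, b = 1))), c("X", "Y"))
  voted <- structure(list(members = list(nb, nb_y, nb),
                          weights = c(1.0, 1.0, 0.5), method = "adaboost",
                          classes = nb$classes, seed = NULL),
                     class = "orgfocus_ensemble")
  post <- predict_posterior(voted, q)   # nb votes X, nb_y votes Y
  expect_identical(posterior_label(post), "X")
  expect_equal(unname(post[["X"]]), 1.5 / 2.5)
})

test_that("section aggregation matches whole-document prediction on one section", {
  glex <- tiny_gene_lexicon()
  olex <- default_organism_lexicon()
  labels3 <- c("fly", "mouse", "yeast")
  featurize <- function(d) {
    om <- tag_organism_mentions(d, olex)
    fv(d$doc_id, organism_frequency(d, om, labels3))
  }
  train_docs <- list(doc_from_tokens(list(c("a", "drosophila")), doc_id = "f"),
                     doc_from_tokens(list(c("a", "mouse")), doc_id = "m"),
                     doc_from_tokens(list(c("a", "yeast")), doc_id = "y"))
  model <- train_naive_bayes(lapply(train_docs, featurize),
                             c("fly", "mouse", "yeast"))
  single <- doc_from_tokens(list(c("the", "drosophila", "genome")),
                            doc_id = "s")
  expect_identical(classify_by_sections(model, single, featurize),
                   posterior_label(predict_posterior(model,
                                                     featurize(single))))

  # majority of equally confident sections wins
  multi <- document("mm", title = "t", sections = list(
    section(kind = "abstract", sentences = tokenize("drosophila here.")),
    section(kind = "results", sentences = tokenize("drosophila again.")),
    section(kind = "conclusion", sentences = tokenize("mouse once."))))
  expect_identical(classify_by_sections(model, multi, featurize), "fly")
})

test_that("the learner registry accepts plug-ins and rejects collisions", {
  name <- "constant_fly_test"
  on.exit(rm(list = name, envir = orgfocus:::.learner_registry), add = TRUE)
  register_learner(name,
                   train_fn = function(vectors, labels, seed = NULL, ...) {
                     structure(list(label = "fly"), class = "const_model")
                   },
                   predict_fn = function(model, vector) {
                     stats::setNames(c(1, 0, 0), c("fly", "mouse", "yeast"))
                   })
  expect_true(name %in% list_learners())
  expect_error(register_learner(name, function(...) NULL, function(...) NULL),
               "already registered")
  expect_true(all(c("nb", "nb_bag", "nb_boost") %in% list_learners()))
})

test_that("model serialization round-trips predictions bit-exactly", {
  d <- separable_vectors()
  jn_vecs <- lapply(seq_along(d$vectors), function(i) {
    v <- d$vectors[[i]]
    v$categorical <- stats::setNames(sample(c("ja", "jb"), 1), "jn")
    v
  })
  nb <- train_naive_bayes(jn_vecs, d$labels)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(nb, path)
  nb2 <- read_model(path)
  for (v in jn_vecs[1:5]) {
    expect_identical(as.numeric(predict_posterior(nb, v)),
                     as.numeric(predict_posterior(nb2, v)))
  }

  ens <- train_bagging(d$vectors, d$labels, n_bags = 3L, seed = 2)
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(ens, path2)
  ens2 <- read_model(path2)
  for (v in d$vectors[1:5]) {
    expect_identical(as.numeric(predict_posterior(ens, v)),
                     as.numeric(predict_posterior(ens2, v)))
  }
})
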