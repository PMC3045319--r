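# Seeded generator of labelled pseudo-articles with the statistical
# structure the classification pipeline assumes: per-class gene
# vocabularies with a shared ambiguous pool, organism mentions at
# configurable rates, planted gene-species co-sentence pairs with
# controlled token distances, planted MeSH headings, journal pools, a
# title-rule branch, and a configurable multi-species fraction.

#' Synthetic-corpus generator configuration
#'
#' The defaults emulate a corpus with strong per-class signal: each class
#' has its own Zipf-distributed gene vocabulary plus a shared ambiguous
#' pool, organism self-mentions at a realistic per-sentence rate, about 5%
#' of articles reporting multiple species, and about 5% of titles naming
#' exactly the focus organism (the fraction the title triage rule
#' resolves). Tagger-noise rates mirror a statistical gene tagger's
#' reported full-text operating point (72.6% precision / 66.7% recall) and
#' are carried in the config for pipelines that opt in; the generator
#' itself emits clean mentions.
#'
#' @param docs_per_class Documents per class (default 300).
#' @param labels Organism label set.
#' @param genes_per_class Class-exclusive gene vocabulary size.
#' @param shared_genes Size of the gene pool shared across classes.
#' @param shared_gene_rate Probability a gene token is drawn from the
#'   shared pool.
#' @param zipf_exponent Zipf exponent of gene frequencies.
#' @param gene_sentence_rate Probability a sentence carries gene tokens.
#' @param organism_sentence_rate Per-sentence probability of an own-label
#'   organism mention.
#' @param other_organism_rate Per-sentence probability of a stray
#'   other-label organism mention (0 by default: in the default corpus
#'   other species appear only in multi-species articles).
#' @param pair_rate Probability a sentence is a planted gene-species pair
#'   with controlled token distance.
#' @param pair_distance_range Inclusive token-distance range of planted
#'   pairs.
#' @param multi_species_rate Fraction of articles mentioning a second
#'   species (default 0.05).
#' @param title_rule_rate Fraction of titles naming exactly the focus
#'   organism (default 0.05).
#' @param section_plan Named integer vector: sentences per section kind.
#' @param tokens_per_sentence Background tokens per sentence.
#' @param mesh_planted_per_class Planted per-class MeSH headings.
#' @param mesh_attach_prob Probability each planted heading is attached.
#' @param mesh_shared If `TRUE`, planted headings are identical across
#'   classes (uninformative).
#' @param journals_shared_only If `TRUE`, all classes share one journal
#'   pool (uninformative).
#' @param journal_class_prob Probability of drawing the journal from the
#'   class pool rather than the shared pool.
#' @param ambiguous_abstract If `TRUE`, abstract sentences carry equal-rate
#'   organism mentions for all labels and no gene signal.
#' @param signal_sections Section kinds eligible for gene/pair signal
#'   (`NULL` = all).
#' @param abstract_only Generate abstract-only documents.
#' @param gene_tag_fp,gene_tag_fn Tagger noise rates carried for
#'   [corrupt_gene_tags()] users (defaults 0.27 / 0.33).
#' @param seed RNG seed.
#' @return Object of class `orgfocus_generator_config`.
#' @export
generator_config <- function(docs_per_class = 300L,
                             labels = c("fly", "mouse", "yeast"),
                             genes_per_class = 40L,
                             shared_genes = 20L,
                             shared_gene_rate = 0.3,
                             zipf_exponent = 1,
                             gene_sentence_rate = 0.6,
                             organism_sentence_rate = 0.25,
                             other_organism_rate = 0,
                             pair_rate = 0.2,
                             pair_distance_range = c(1L, 6L),
                             multi_species_rate = 0.05,
                             title_rule_rate = 0.05,
                             section_plan = c(abstract = 3L, introduction = 4L,
                                              methods = 4L, results = 5L,
                                              discussion = 3L, conclusion = 2L),
                             tokens_per_sentence = 10L,
                             mesh_planted_per_class = 3L,
                             mesh_attach_prob = 0.7,
                             mesh_shared = FALSE,
                             journals_shared_only = FALSE,
                             journal_class_prob = 0.6,
                             ambiguous_abstract = FALSE,
                             signal_sections = NULL,
                             abstract_only = FALSE,
                             gene_tag_fp = 0.27,
                             gene_tag_fn = 0.33,
                             seed = 1L) {
  rates <- c(shared_gene_rate, gene_sentence_rate, organism_sentence_rate,
             other_organism_rate, pair_rate, multi_species_rate,
             title_rule_rate, mesh_attach_prob, journal_class_prob,
             gene_tag_fp, gene_tag_fn)
  if (any(rates < 0 | rates > 1)) abort_input("all rates must be in [0, 1]")
  if (docs_per_class < 1L) abort_input("docs_per_class must be >= 1")
  if (length(labels) == 0L) {
    abort_input("label set is empty but title_rule_rate/generation needs labels")
  }
  if (genes_per_class + shared_genes < 1L) {
    abort_input("need a non-empty gene vocabulary")
  }
  if (isTRUE(abstract_only)) section_plan <- c(abstract = 5L)
  if (!all(names(section_plan) %in% SECTION_KINDS)) {
    abort_input("section_plan kinds must be canonical section kinds")
  }
  structure(as.list(environment())[setdiff(names(formals(generator_config)),
                                           "rates")],
            class = "orgfocus_generator_config")
}

# Organism surface forms inserted in generated text (all present in the
# default organism lexicon).
GENERATOR_SURFACES <- list(
  fly = c("Drosophila", "fly"),
  mouse = c("mouse", "mice"),
  yeast = c("yeast", "Saccharomyces"))

generator_surface <- function(label) {
  s <- GENERATOR_SURFACES[[label]]
  if (is.null(s)) paste0(label) else s
}

build_vocabulary <- function(cfg) {
  class_genes <- lapply(cfg$labels, function(l) {
    if (cfg$genes_per_class == 0L) character(0) else
      sprintf("%sG%02d", toupper(substr(l, 1, 2)), seq_len(cfg$genes_per_class))
  })
  names(class_genes) <- cfg$labels
  shared <- if (cfg$shared_genes == 0L) character(0) else
    sprintf("SHG%02d", seq_len(cfg$shared_genes))
  mesh <- lapply(cfg$labels, function(l) {
    if (cfg$mesh_shared) sprintf("MH-shared-%d", seq_len(cfg$mesh_planted_per_class))
    else sprintf("MH-%s-%d", l, seq_len(cfg$mesh_planted_per_class))
  })
  names(mesh) <- cfg$labels
  journals <- lapply(cfg$labels, function(l) {
    if (cfg$journals_shared_only) c("J Shared Res", "J Shared Biol")
    else sprintf("J %s Res %d", l, 1:3)
  })
  names(journals) <- cfg$labels
  list(class_genes = class_genes, shared_genes = shared,
       background = sprintf("w%03d", seq_len(300L)),
       mesh = mesh,
       mesh_background = sprintf("MH-bg-%d", 1:6),
       journals = journals,
       shared_journals = c("J Shared Res", "J Shared Biol"))
}

zipf_sample <- function(n_items, exponent) {
  if (n_items == 1L) return(1L)
  p <- seq_len(n_items)^(-exponent)
  sample.int(n_items, 1L, prob = p / sum(p))
}

sample_gene <- function(label, cfg, vocab) {
  own <- vocab$class_genes[[label]]
  shared <- vocab$shared_genes
  use_shared <- length(shared) > 0L &&
    (length(own) == 0L || stats::runif(1) < cfg$shared_gene_rate)
  pool <- if (use_shared) shared else own
  pool[zipf_sample(length(pool), cfg$zipf_exponent)]
}

# Build one sentence: background tokens with optional inserted gene tokens,
# organism mentions and a planted gene-species pair. Returns tokens plus
# any planted pair (gene, label, distance).
generate_sentence <- function(label, cfg, vocab, allow_signal, kind) {
  toks <- sample(vocab$background, cfg$tokens_per_sentence, replace = TRUE)
  pair <- NULL
  if (cfg$ambiguous_abstract && kind == "abstract") {
    for (l in cfg$labels) {
      if (stats::runif(1) < cfg$organism_sentence_rate) {
        pos <- sample.int(length(toks) + 1L, 1L)
        toks <- append(toks, generator_surface(l)[1], after = pos - 1L)
      }
    }
    return(list(tokens = toks, pair = NULL))
  }
  if (allow_signal && stats::runif(1) < cfg$pair_rate) {
    d <- cfg$pair_distance_range[1] +
      sample.int(cfg$pair_distance_range[2] - cfg$pair_distance_range[1] + 1L,
                 1L) - 1L
    g <- sample_gene(label, cfg, vocab)
    o <- generator_surface(label)[1]
    need <- d + 1L
    if (length(toks) < need) toks <- rep_len(toks, need)
    p <- sample.int(length(toks) - d, 1L)
    toks[p] <- g
    toks[p + d] <- o
    return(list(tokens = toks,
                pair = data.frame(gene = g, label = label, distance = d,
                                  stringsAsFactors = FALSE)))
  }
  if (allow_signal && stats::runif(1) < cfg$gene_sentence_rate) {
    for (j in seq_len(sample(1:2, 1L))) {
      toks[sample.int(length(toks), 1L)] <- sample_gene(label, cfg, vocab)
    }
  }
  if (stats::runif(1) < cfg$organism_sentence_rate) {
    pos <- sample.int(length(toks) + 1L, 1L)
    toks <- append(toks, sample(generator_surface(label), 1L), after = pos - 1L)
  }
  others <- setdiff(cfg$labels, label)
  if (length(others) && cfg$other_organism_rate > 0 &&
      stats::runif(1) < cfg$other_organism_rate) {
    l <- sample(others, 1L)
    pos <- sample.int(length(toks) + 1L, 1L)
    toks <- append(toks, generator_surface(l)[1], after = pos - 1L)
  }
  list(tokens = toks, pair = pair)
}

make_section_from_tokens <- function(kind, token_lists) {
  offset <- 0L
  sents <- vector("list", length(token_lists))
  for (i in seq_along(token_lists)) {
    sents[[i]] <- sentence(token_lists[[i]], offset)
    offset <- offset + nchar(paste(token_lists[[i]], collapse = " ")) + 2L
  }
  section(heading = tools::toTitleCase(kind), kind = kind, sentences = sents)
}

#' Generate one labelled pseudo-article
#'
#' Uses the caller's RNG stream (call inside [generate_corpus()] or under a
#' fixed seed).
#'
#' @param label Gold organism label.
#' @param cfg A [generator_config()].
#' @param vocab Vocabulary from the generator (internal; rebuilt if
#'   `NULL`).
#' @param doc_id Document identifier.
#' @return List with `document` and `truth` (gold label, title-rule flag,
#'   multi-species flag, planted pairs).
#' @export
generate_document <- function(label, cfg, vocab = NULL, doc_id = "doc-1") {
  vocab <- vocab %||% build_vocabulary(cfg)
  pairs <- list()
  sections <- list()
  for (kind in names(cfg$section_plan)) {
    allow_signal <- is.null(cfg$signal_sections) ||
      kind %in% cfg$signal_sections
    token_lists <- list()
    for (s in seq_len(cfg$section_plan[[kind]])) {
      sen <- generate_sentence(label, cfg, vocab, allow_signal, kind)
      token_lists[[s]] <- sen$tokens
      if (!is.null(sen$pair)) pairs[[length(pairs) + 1L]] <- sen$pair
    }
    sections[[length(sections) + 1L]] <- make_section_from_tokens(kind,
                                                                  token_lists)
  }
  multi_species <- FALSE
  others <- setdiff(cfg$labels, label)
  if (length(others) && stats::runif(1) < cfg$multi_species_rate) {
    multi_species <- TRUE
    other <- sample(others, 1L)
    last <- length(sections)
    extra <- list(
      c(sample(vocab$background, 6L, replace = TRUE),
        generator_surface(label)[1]),
      c(sample(vocab$background, 6L, replace = TRUE),
        generator_surface(other)[1]))
    old <- lapply(sections[[last]]$sentences, `[[`, "tokens")
    sections[[last]] <- make_section_from_tokens(sections[[last]]$kind,
                                                 c(old, extra))
  }
  title_rule <- stats::runif(1) < cfg$title_rule_rate
  title <- if (title_rule) {
    paste("Gene expression analysis in", generator_surface(label)[1])
  } else {
    paste("Regulation of", sample_gene(label, cfg, vocab),
          "under", sample(vocab$background, 1L), "conditions")
  }
  mesh <- character(0)
  planted <- vocab$mesh[[label]]
  mesh <- planted[stats::runif(length(planted)) < cfg$mesh_attach_prob]
  mesh <- c(mesh, sample(vocab$mesh_background, 2L))
  journal <- if (stats::runif(1) < cfg$journal_class_prob) {
    sample(vocab$journals[[label]], 1L)
  } else {
    sample(vocab$shared_journals, 1L)
  }
  doc <- document(doc_id = doc_id, title = title, journal = journal,
                  mesh = mesh, sections = sections, gold_label = label)
  pairs_df <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(gene = character(), label = character(), distance = integer(),
               stringsAsFactors = FALSE)
  list(document = doc,
       truth = list(doc_id = doc_id, label = label, title_rule = title_rule,
                    multi_species = multi_species, pairs = pairs_df))
}

#' Generate a labelled synthetic corpus
#'
#' Deterministic under the config seed: the same config yields an
#' identical corpus. Returns the documents, the per-document ground truth
#' (gold labels, title-rule and multi-species flags, planted gene-species
#' pairs with distances), and a gene lexicon covering the generated
#' vocabulary for use by the tagger.
#'
#' @param cfg A [generator_config()].
#' @return Object of class `orgfocus_corpus`: `documents`, `truth`
#'   (data.frame), `pairs` (per-doc list), `gene_lexicon`, `config`.
#' @export
generate_corpus <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "orgfocus_generator_config"))
  with_seed(cfg$seed, {
    vocab <- build_vocabulary(cfg)
    docs <- list()
    truth_rows <- list()
    pairs <- list()
    for (label in cfg$labels) {
      for (i in seq_len(cfg$docs_per_class)) {
        doc_id <- sprintf("%s-%04d", label, i)
        g <- generate_document(label, cfg, vocab, doc_id)
        docs[[length(docs) + 1L]] <- g$document
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          doc_id = doc_id, label = label, title_rule = g$truth$title_rule,
          multi_species = g$truth$multi_species,
          n_pairs = nrow(g$truth$pairs), stringsAsFactors = FALSE)
        pairs[[doc_id]] <- g$truth$pairs
      }
    }
    all_genes <- sort(unique(c(unlist(vocab$class_genes), vocab$shared_genes)))
    structure(list(documents = docs,
                   truth = do.call(rbind, truth_rows),
                   pairs = pairs,
                   gene_lexicon = lexicon(all_genes, all_genes, kind = "gene",
                                          provenance = "synthetic generator"),
                   config = cfg),
              class = "orgfocus_corpus")
  })
}

#' @export
print.orgfocus_corpus <- function(x, ...) {
  cat(sprintf("<synthetic corpus> %d documents (%s), %d planted pairs, seed=%s\n",
              length(x$documents),
              paste(sprintf("%s:%d", names(table(x$truth$label)),
                            as.integer(table(x$truth$label))), collapse = ", "),
              sum(x$truth$n_pairs), format(x$config$seed)))
  invisible(x)
}

#' Corrupt gene mentions with tagger-style noise
#'
#' Drops each true mention with probability `fn_rate` and injects spurious
#' mentions (surface/canonical `FPG<k>`) at a rate derived from `fp_rate`
#' so that the expected false-positive fraction of the output approximates
#' `fp_rate`. Seeded and deterministic; `fp_rate = fn_rate = 0` is the
#' identity.
#'
#' @param mentions Gene-mention data.frame.
#' @param fp_rate Target false-positive fraction (in `[0, 1)`).
#' @param fn_rate Per-mention drop probability.
#' @param seed RNG seed (`NULL`: use the current stream).
#' @param doc Optional document supplying valid coordinates for injected
#'   mentions; without it coordinates are resampled from the input
#'   mentions.
#' @return The corrupted mention data.frame, in document order.
#' @export
corrupt_gene_tags <- function(mentions, fp_rate = 0.27, fn_rate = 0.33,
                              seed = NULL, doc = NULL) {
  stopifnot(fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate <= 1)
  with_seed(seed, {
    n <- nrow(mentions)
    keep <- if (n > 0L) stats::runif(n) >= fn_rate else logical(0)
    out <- mentions[keep, , drop = FALSE]
    n_fp <- if (n > 0L && fp_rate > 0) {
      stats::rbinom(1L, n, fp_rate / (1 - fp_rate))
    } else 0L
    if (n_fp > 0L) {
      coords <- if (!is.null(doc)) {
        tk <- doc_tokens(doc)
        if (nrow(tk) == 0L) NULL else
          tk[sample.int(nrow(tk), n_fp, replace = TRUE),
             c("section_index", "sentence_index", "token_index"), drop = FALSE]
      } else if (n > 0L) {
        mentions[sample.int(n, n_fp, replace = TRUE),
                 c("section_index", "sentence_index", "token_index"),
                 drop = FALSE]
      } else NULL
      if (!is.null(coords)) {
        fp <- data.frame(surface = sprintf("FPG%d", seq_len(n_fp)),
                         canonical = sprintf("FPG%d", seq_len(n_fp)),
                         kind = "gene",
                         section_index = coords$section_index,
                         sentence_index = coords$sentence_index,
                         token_index = coords$token_index,
                         stringsAsFactors = FALSE)
        out <- rbind(out, fp)
      }
    }
    out <- out[order(out$section_index, out$sentence_index, out$token_index), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Ambiguity-stressed generator preset
#'
#' A corpus where the basic feature families are uninformative by
#' construction -- gene vocabulary fully shared across classes, identical
#' planted MeSH headings, one shared journal pool, organism-free titles,
#' and equal-rate mentions of every organism in every article -- while
#' planted gene-species co-sentence pairs still point at the true focus
#' organism. Isolates the contribution of the term-species distance
#' feature.
#'
#' @param docs_per_class Documents per class (default 80).
#' @param seed RNG seed.
#' @param ... Overrides passed to [generator_config()].
#' @return An `orgfocus_generator_config`.
#' @export
ambiguity_stressed_config <- function(docs_per_class = 80L, seed = 1L, ...) {
  generator_config(docs_per_class = docs_per_class,
                   genes_per_class = 0L, shared_genes = 40L,
                   shared_gene_rate = 1,
                   organism_sentence_rate = 0.2, other_organism_rate = 0.2,
                   pair_rate = 0.3,
                   multi_species_rate = 0, title_rule_rate = 0,
                   mesh_shared = TRUE, journals_shared_only = TRUE,
                   seed = seed, ...)
}

#' Full-text-advantage generator preset
#'
#' Plants the discriminative gene-species pairs and gene signal outside
#' the abstract (introduction, results, conclusion) and makes abstracts
#' carry equal-rate organism mentions for every label with no gene
#' signal; document-level metadata (MeSH, journal, title) is made
#' uninformative so that the full-text versus abstract-only contrast
#' reflects body content.
#'
#' @param docs_per_class Documents per class (default 120).
#' @param seed RNG seed.
#' @param ... Overrides passed to [generator_config()].
#' @return An `orgfocus_generator_config`.
#' @export
fulltext_advantage_config <- function(docs_per_class = 120L, seed = 1L, ...) {
  generator_config(docs_per_class = docs_per_class,
                   ambiguous_abstract = TRUE,
                   signal_sections = c("introduction", "results",
                                       "conclusion"),
                   mesh_shared = TRUE, journals_shared_only = TRUE,
                   title_rule_rate = 0, multi_species_rate = 0,
                   organism_sentence_rate = 0.3, pair_rate = 0.3,
                   seed = seed, ...)
}

#' Write generator ground truth as line-delimited records
#'
#' @param corpus An [generate_corpus()] result.
#' @param path Output path.
#' @return Number of records written.
#' @export
write_ground_truth <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus$truth))) {
    row <- corpus$truth[i, ]
    rec <- list(doc_id = jsonlite::unbox(row$doc_id),
                label = jsonlite::unbox(row$label),
                title_rule = jsonlite::unbox(row$title_rule),
                multi_species = jsonlite::unbox(row$multi_species),
                pairs = corpus$pairs[[row$doc_id]])
    writeLines(jsonlite::toJSON(rec, auto_unbox = FALSE, digits = I(10)), con)
  }
  nrow(corpus$truth)
}
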