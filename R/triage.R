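# Rule-based first-pass classification by title and gene-distribution
# content selection.

#' Classify a document by its title
#'
#' The heuristic triage rule: if the title mentions exactly one distinct
#' organism from the lexicon the document is labelled with that organism
#' immediately and bypasses the statistical classifier; zero or two or more
#' distinct organisms leave it `"undecided"`. Repeated mentions of the same
#' organism count once.
#'
#' @param doc A [document()].
#' @param organism_lexicon An organism lexicon.
#' @return List with `label` (an organism label or `"undecided"`) and
#'   `rule_fired` (logical), class `orgfocus_triage`.
#' @export
classify_by_title <- function(doc, organism_lexicon) {
  title_doc <- document(doc_id = paste0(doc$doc_id, ":title"),
                        title = doc$title,
                        sections = list(section(kind = "other",
                                                sentences = tokenize(doc$title))))
  mentions <- tag_organism_mentions(title_doc, organism_lexicon)
  labels <- unique(mentions$canonical)
  if (length(labels) == 1L) {
    structure(list(label = labels, rule_fired = TRUE),
              class = "orgfocus_triage")
  } else {
    structure(list(label = "undecided", rule_fired = FALSE),
              class = "orgfocus_triage")
  }
}

CONTENT_KINDS <- c("abstract", "introduction", "results", "conclusion")

#' Pooled gene-mention distribution over section kinds
#'
#' Builds the reference gene-section distribution from a set of articles
#' with typed sections: gene-mention counts are pooled per section kind and
#' normalized to proportions.
#'
#' @param docs List of documents with typed sections.
#' @param gene_mentions List (parallel to `docs`) of gene-mention
#'   data.frames.
#' @return Named numeric vector of proportions over section kinds, class
#'   `orgfocus_section_distribution`.
#' @export
reference_gene_distribution <- function(docs, gene_mentions) {
  stopifnot(length(docs) == length(gene_mentions))
  counts <- stats::setNames(numeric(length(SECTION_KINDS)), SECTION_KINDS)
  for (i in seq_along(docs)) {
    m <- gene_mentions[[i]]
    if (nrow(m) == 0L) next
    kinds <- vapply(docs[[i]]$sections, `[[`, "", "kind")
    mk <- kinds[m$section_index + 1L]
    tab <- table(mk)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  total <- sum(counts)
  if (total == 0) abort_input("no gene mentions: cannot build distribution")
  structure(counts[counts > 0] / total, class = "orgfocus_section_distribution")
}

#' Similarity between two section distributions
#'
#' Cosine similarity of the weight vectors over the union of section kinds
#' (missing kinds treated as zero); symmetric, 1 for identical
#' distributions. A KL-divergence-based alternative
#' (`exp(-KL(a || b))` with smoothing) is available for sensitivity checks.
#'
#' @param a,b Named non-negative weight vectors (section distributions).
#' @param method `"cosine"` (default) or `"kl"`.
#' @return Similarity score in `[0, 1]`.
#' @export
distribution_similarity <- function(a, b, method = c("cosine", "kl")) {
  method <- match.arg(method)
  kinds <- union(names(a), names(b))
  av <- stats::setNames(numeric(length(kinds)), kinds)
  bv <- av
  av[names(a)] <- as.numeric(a)
  bv[names(b)] <- as.numeric(b)
  if (sum(av) == 0 || sum(bv) == 0) abort_input("zero distribution vector")
  if (method == "cosine") {
    sum(av * bv) / (sqrt(sum(av^2)) * sqrt(sum(bv^2)))
  } else {
    eps <- 1e-9
    ap <- (av + eps) / sum(av + eps)
    bp <- (bv + eps) / sum(bv + eps)
    exp(-sum(ap * log(ap / bp)))
  }
}

#' Select informative content sections
#'
#' Restricts a full-text document to its abstract, introduction, results
#' and conclusion sections. If the document carries recognizable section
#' kinds, exactly those four kinds are kept (methods and discussion are
#' excluded). For documents whose headings were not recognized, the body is
#' partitioned into six contiguous equal-token blocks and the 4-block
#' subset whose gene distribution is most similar to the reference
#' distribution is kept, the kept blocks being typed abstract,
#' introduction, results, conclusion in order. Abstract-only documents pass
#' through unchanged. Idempotent.
#'
#' @param doc A [document()] with at least one section.
#' @param ref Reference section distribution (needed for the heading-less
#'   fallback only).
#' @param gene_mentions Gene mentions of `doc` (fallback only).
#' @return The document restricted to the selected sections.
#' @export
select_content <- function(doc, ref = NULL, gene_mentions = NULL) {
  if (length(doc$sections) == 0L) abort_input("document has zero sections")
  kinds <- vapply(doc$sections, `[[`, "", "kind")
  if (any(kinds %in% CONTENT_KINDS)) {
    doc$sections <- doc$sections[kinds %in% CONTENT_KINDS]
    return(doc)
  }
  if (is.null(ref) || is.null(gene_mentions)) return(doc)
  select_content_by_distribution(doc, ref, gene_mentions)
}

# Heading-less fallback: six contiguous blocks of (approximately) equal
# token count; exhaustive search over the 15 4-block subsets.
select_content_by_distribution <- function(doc, ref, gene_mentions) {
  toks <- doc_tokens(doc)
  n_tok <- nrow(toks)
  if (n_tok == 0L) return(doc)
  # cumulative token position of each sentence start
  sent_key <- paste(toks$section_index, toks$sentence_index)
  sent_ids <- unique(sent_key)
  if (length(sent_ids) < 6L) return(doc)
  sent_sizes <- as.numeric(table(factor(sent_key, levels = sent_ids)))
  cum <- cumsum(sent_sizes)
  block_of_sentence <- pmin(6L, ceiling(cum / (n_tok / 6)))
  # guarantee all 6 blocks non-empty by monotone correction
  block_of_sentence <- cummax(block_of_sentence)
  names(block_of_sentence) <- sent_ids
  gm_key <- paste(gene_mentions$section_index, gene_mentions$sentence_index)
  gm_block <- block_of_sentence[gm_key]
  counts <- as.numeric(table(factor(gm_block, levels = 1:6)))
  if (sum(counts) == 0) return(doc)
  ref_vec <- stats::setNames(numeric(length(CONTENT_KINDS)), CONTENT_KINDS)
  common <- intersect(names(ref), CONTENT_KINDS)
  ref_vec[common] <- as.numeric(ref[common])
  combos <- utils::combn(6L, 4L)
  best <- NULL; best_sim <- -Inf
  for (j in seq_len(ncol(combos))) {
    sel <- combos[, j]
    v <- counts[sel]
    if (sum(v) == 0 || sum(ref_vec) == 0) next
    sim <- distribution_similarity(stats::setNames(v, CONTENT_KINDS), ref_vec)
    if (sim > best_sim + 1e-12) {
      best_sim <- sim; best <- sel
    }
  }
  if (is.null(best)) return(doc)
  # rebuild the document: kept blocks become typed sections in order
  new_sections <- list()
  for (bi in seq_along(best)) {
    b <- best[bi]
    ids <- sent_ids[block_of_sentence == b]
    sents <- list()
    for (id in ids) {
      parts <- as.integer(strsplit(id, " ", fixed = TRUE)[[1]])
      sents[[length(sents) + 1L]] <-
        doc$sections[[parts[1] + 1L]]$sentences[[parts[2] + 1L]]
    }
    new_sections[[bi]] <- section(heading = "", kind = CONTENT_KINDS[bi],
                                  sentences = sents)
  }
  doc$sections <- new_sections
  doc
}
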