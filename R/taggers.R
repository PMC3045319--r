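# Lexicon-driven gene and organism mention tagging (deterministic,
# interface-compatible stand-in for a statistical gene NER tool), plus
# gene-frequency ranking.

#' Build a lexicon from a surface/canonical table
#'
#' @param surfaces Character vector of surface forms (patterns).
#' @param canonicals Character vector of canonical symbols/labels, same
#'   length.
#' @param kind `"gene"` (case-sensitive matching) or `"organism"`
#'   (case-insensitive, multi-token longest match).
#' @param provenance Free-text note on where the lexicon came from.
#' @return An object of class `orgfocus_lexicon`.
#' @export
lexicon <- function(surfaces, canonicals, kind = c("gene", "organism"),
                    provenance = "in-memory") {
  kind <- match.arg(kind)
  surfaces <- as.character(surfaces)
  canonicals <- as.character(canonicals)
  if (length(surfaces) != length(canonicals)) {
    abort_input("surfaces and canonicals must have equal length")
  }
  if (any(!nzchar(surfaces))) abort_input("empty surface form in lexicon")
  if (any(!nzchar(canonicals))) abort_input("empty canonical form in lexicon")
  # silently deduplicate identical pairs; conflicting canonicals are an error
  key <- if (kind == "organism") tolower(surfaces) else surfaces
  dup <- !duplicated(paste0(key, "\r", canonicals))
  surfaces <- surfaces[dup]; canonicals <- canonicals[dup]; key <- key[dup]
  conflict <- key[duplicated(key)]
  if (length(conflict)) {
    abort_input("conflicting canonical forms for surface(s): ",
                paste(unique(conflict), collapse = ", "))
  }
  structure(list(surfaces = surfaces, canonicals = canonicals, kind = kind,
                 provenance = provenance),
            class = "orgfocus_lexicon")
}

#' @export
print.orgfocus_lexicon <- function(x, ...) {
  cat(sprintf("<%s lexicon> %d surface forms, %d canonical forms (%s)\n",
              x$kind, length(x$surfaces), length(unique(x$canonicals)),
              x$provenance))
  invisible(x)
}

#' Load a lexicon from a tab-separated file
#'
#' Two columns, `surface<TAB>canonical`; `#`-prefixed comment lines and
#' blank lines are ignored. Duplicate identical entries are deduplicated
#' silently; a surface mapped to two different canonicals is an error
#' naming the offending line.
#'
#' @param path Path to the TSV file.
#' @param kind `"gene"` or `"organism"`.
#' @return An `orgfocus_lexicon`.
#' @export
load_lexicon <- function(path, kind = c("gene", "organism")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort_input("lexicon file does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  surfaces <- character(0); canonicals <- character(0)
  for (i in which(keep)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L || !nzchar(trimws(fields[1])) ||
        !nzchar(trimws(fields[2]))) {
      abort_input(sprintf("malformed lexicon line %d in %s", i, path))
    }
    surfaces <- c(surfaces, trimws(fields[1]))
    canonicals <- c(canonicals, trimws(fields[2]))
  }
  lex <- tryCatch(lexicon(surfaces, canonicals, kind, provenance = path),
                  error = function(e) e)
  if (inherits(lex, "error")) {
    # locate the first conflicting line for the error message
    key <- if (kind == "organism") tolower(surfaces) else surfaces
    bad <- which(duplicated(key) &
                   !duplicated(paste0(key, "\r", canonicals)))[1]
    line_no <- which(keep)[bad]
    abort_input(sprintf("conflicting canonical at line %s of %s",
                        ifelse(is.na(line_no), "?", line_no), path))
  }
  lex
}

#' Default organism lexicon (fly / mouse / yeast)
#'
#' Surface forms for the three model organisms and their common synonyms
#' (NCBI-taxonomy style: drosophila, D. melanogaster, mice, murine,
#' Mus musculus, saccharomyces, S. cerevisiae, budding yeast, ...),
#' shipped with the package and extensible via [load_lexicon()].
#'
#' @return An organism `orgfocus_lexicon`.
#' @export
default_organism_lexicon <- function() {
  path <- system.file("extdata", "organism_lexicon.tsv", package = "orgfocus")
  load_lexicon(path, kind = "organism")
}

#' Labels covered by an organism lexicon
#'
#' @param lex An organism lexicon.
#' @return Sorted character vector of organism labels.
#' @export
lexicon_labels <- function(lex) {
  stopifnot(inherits(lex, "orgfocus_lexicon"), lex$kind == "organism")
  sort(unique(lex$canonicals))
}

empty_mentions <- function() {
  data.frame(surface = character(), canonical = character(),
             kind = character(), section_index = integer(),
             sentence_index = integer(), token_index = integer(),
             stringsAsFactors = FALSE)
}

#' Tag organism mentions
#'
#' Longest-match, case-insensitive matching of lexicon surface forms over
#' token n-grams; multi-token forms such as "Drosophila melanogaster" match
#' as a single mention and suppress overlapping shorter matches. Mentions
#' are returned in document order with 0-based section/sentence/token
#' coordinates.
#'
#' @param doc A tokenized [document()].
#' @param lex An organism `orgfocus_lexicon`.
#' @return A mention data.frame (`surface`, `canonical`, `kind`,
#'   `section_index`, `sentence_index`, `token_index`).
#' @export
tag_organism_mentions <- function(doc, lex) {
  stopifnot(lex$kind == "organism")
  surf_tokens <- lapply(strsplit(tolower(lex$surfaces), "\\s+"), function(w) {
    w <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", w)
    w[nzchar(w)]
  })
  lens <- lengths(surf_tokens)
  map <- split(lex$canonicals, vapply(surf_tokens, paste, "", collapse = " "))
  map <- vapply(map, `[[`, "", 1)
  max_n <- max(lens, 1L)
  rows <- list()
  for (si in seq_along(doc$sections)) {
    sents <- doc$sections[[si]]$sentences
    for (ti in seq_along(sents)) {
      toks <- sents[[ti]]$tokens
      if (length(toks) == 0L) next
      low <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", tolower(toks))
      covered <- rep(FALSE, length(toks))
      for (n in seq(min(max_n, length(toks)), 1L)) {
        if (length(toks) < n) next
        starts <- seq_len(length(toks) - n + 1L)
        grams <- if (n == 1L) low else
          vapply(starts, function(s) paste(low[s:(s + n - 1L)], collapse = " "), "")
        hit <- grams %in% names(map)
        for (s in starts[hit]) {
          span <- s:(s + n - 1L)
          if (any(covered[span])) next
          covered[span] <- TRUE
          rows[[length(rows) + 1L]] <- data.frame(
            surface = paste(toks[span], collapse = " "),
            canonical = unname(map[[paste(low[span], collapse = " ")]]),
            kind = "organism",
            section_index = si - 1L, sentence_index = ti - 1L,
            token_index = s - 1L, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_mentions())
  out <- do.call(rbind, rows)
  out <- out[order(out$section_index, out$sentence_index, out$token_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tag gene mentions
#'
#' Exact case-sensitive single-token match against the gene lexicon (gene
#' symbol case is semantic: "Copg1" and "COPG1" differ). An optional
#' pattern rule additionally tags symbol-like tokens mixing letters and
#' digits (e.g. "IL2"), canonicalized to their surface form; it is off by
#' default.
#'
#' @param doc A tokenized [document()].
#' @param lex A gene `orgfocus_lexicon` (may be empty).
#' @param pattern_rule If `TRUE`, also tag letter+digit symbol-like tokens
#'   absent from the lexicon.
#' @return A mention data.frame as for [tag_organism_mentions()].
#' @export
tag_gene_mentions <- function(doc, lex = NULL, pattern_rule = FALSE) {
  if (!is.null(lex)) stopifnot(lex$kind == "gene")
  surfaces <- if (is.null(lex)) character(0) else lex$surfaces
  canon <- if (is.null(lex)) character(0) else lex$canonicals
  toks_df <- doc_tokens(doc)
  if (nrow(toks_df) == 0L) return(empty_mentions())
  idx <- match(toks_df$token, surfaces)
  is_lex <- !is.na(idx)
  is_pat <- rep(FALSE, nrow(toks_df))
  if (isTRUE(pattern_rule)) {
    is_pat <- !is_lex &
      grepl("^[A-Za-z][A-Za-z0-9-]*$", toks_df$token) &
      grepl("[0-9]", toks_df$token) &
      grepl("[A-Za-z]", toks_df$token)
  }
  keep <- is_lex | is_pat
  if (!any(keep)) return(empty_mentions())
  out <- data.frame(
    surface = toks_df$token[keep],
    canonical = ifelse(is_lex[keep], canon[idx[keep]], toks_df$token[keep]),
    kind = "gene",
    section_index = toks_df$section_index[keep],
    sentence_index = toks_df$sentence_index[keep],
    token_index = toks_df$token_index[keep],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Rank genes by document frequency
#'
#' Frequency-ranked gene list capped at `n_cap`, ties broken
#' lexicographically by symbol.
#'
#' @param mentions A gene-mention data.frame.
#' @param n_cap Maximum list length (default 100).
#' @return An object of class `orgfocus_gene_list` with a `ranked`
#'   data.frame (`gene`, `freq`) and the cap.
#' @export
rank_genes <- function(mentions, n_cap = 100L) {
  stopifnot(n_cap >= 1L)
  if (nrow(mentions) > 0L && any(mentions$kind != "gene")) {
    abort_input("rank_genes expects gene-kind mentions")
  }
  tab <- table(mentions$canonical)
  if (length(tab)) {
    df <- data.frame(gene = names(tab), freq = as.integer(tab),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$freq, df$gene), , drop = FALSE]
    df <- utils::head(df, n_cap)
    rownames(df) <- NULL
  } else {
    df <- data.frame(gene = character(), freq = integer(),
                     stringsAsFactors = FALSE)
  }
  structure(list(ranked = df, n_cap = as.integer(n_cap)),
            class = "orgfocus_gene_list")
}

#' Load a (gene, organism) -> additional-name synonym table
#'
#' Three tab-separated columns: `gene<TAB>organism<TAB>additional_name`;
#' `#` comments allowed. Used by the additional-gene-name feature in place
#' of live protein-database queries.
#'
#' @param path Path to the TSV file; defaults to the small table shipped
#'   with the package.
#' @return data.frame with columns `gene`, `organism`, `additional`.
#' @export
load_synonym_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_synonyms.tsv",
                                package = "orgfocus")
  if (!file.exists(path)) abort_input("synonym table does not exist: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- lapply(which(keep), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 3L) {
      abort_input(sprintf("malformed synonym line %d in %s", i, path))
    }
    data.frame(gene = trimws(fields[1]), organism = trimws(fields[2]),
               additional = trimws(fields[3]), stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(gene = character(), organism = character(),
                      additional = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
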