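# Document data model, corpus formats, cleaning, section segmentation and
# tokenization.

SECTION_KINDS <- c("abstract", "introduction", "methods", "results",
                   "discussion", "conclusion", "other")

# Heading synonyms -> canonical section kind. Matching is case-insensitive
# after stripping leading numbering and punctuation.
HEADING_TABLE <- c(
  "abstract"                 = "abstract",
  "summary"                  = "abstract",
  "introduction"             = "introduction",
  "background"               = "introduction",
  "methods"                  = "methods",
  "method"                   = "methods",
  "materials and methods"    = "methods",
  "material and methods"     = "methods",
  "experimental procedures"  = "methods",
  "experiment"               = "methods",
  "experiments"              = "methods",
  "results"                  = "results",
  "result"                   = "results",
  "findings"                 = "results",
  "results and discussion"   = "results",
  "discussion"               = "discussion",
  "conclusion"               = "conclusion",
  "conclusions"              = "conclusion",
  "concluding remarks"       = "conclusion"
)

# Words whose trailing period never ends a sentence.
DEFAULT_ABBREVIATIONS <- c("e.g.", "i.e.", "al.", "fig.", "figs.", "cf.",
                           "vs.", "no.", "ref.", "sp.", "spp.", "etc.")

#' Construct a sentence
#'
#' A sentence is the unit over which the term-species distance feature is
#' computed: an ordered token vector plus the character offset of the
#' sentence within its section text.
#'
#' @param tokens Character vector of surface tokens, in order.
#' @param char_offset 0-based start position of the sentence in the section
#'   text.
#' @return An object of class `orgfocus_sentence`.
#' @export
sentence <- function(tokens, char_offset = 0L) {
  structure(list(tokens = as.character(tokens),
                 char_offset = as.integer(char_offset)),
            class = "orgfocus_sentence")
}

#' Construct a document section
#'
#' @param heading Section heading as printed (possibly empty).
#' @param kind Canonical section kind; if `NULL`, derived from `heading`
#'   via the shipped heading-synonym table.
#' @param sentences List of [sentence()] objects in document order.
#' @return An object of class `orgfocus_section`.
#' @export
section <- function(heading = "", kind = NULL, sentences = list()) {
  kind <- kind %||% normalize_heading(heading)
  kind <- match.arg(kind, SECTION_KINDS)
  structure(list(heading = as.character(heading), kind = kind,
                 sentences = sentences),
            class = "orgfocus_section")
}

#' Construct a document
#'
#' The central record of the pipeline: one article or abstract with its
#' title, journal name, MeSH headings, ordered typed sections, and an
#' optional gold focus-organism label.
#'
#' @param doc_id Non-empty identifier, unique within a corpus.
#' @param title Document title text.
#' @param journal Journal name (may be empty).
#' @param mesh Character vector of MeSH headings (may be empty).
#' @param sections List of [section()] objects.
#' @param gold_label Optional gold organism label (`NA` if unlabelled).
#' @return An object of class `orgfocus_document`.
#' @export
document <- function(doc_id, title = "", journal = "", mesh = character(),
                     sections = list(), gold_label = NA_character_) {
  if (!nzchar(doc_id)) abort_input("doc_id must be non-empty")
  structure(list(doc_id = as.character(doc_id),
                 title = as.character(title),
                 journal = as.character(journal),
                 mesh = as.character(mesh),
                 sections = sections,
                 gold_label = as.character(gold_label)),
            class = "orgfocus_document")
}

#' @export
print.orgfocus_document <- function(x, ...) {
  n_sent <- sum(vapply(x$sections, function(s) length(s$sentences), 1L))
  cat(sprintf("<document %s> \"%s\"\n", x$doc_id, x$title))
  cat(sprintf("  journal: %s | mesh: %d | sections: %d (%s) | sentences: %d | gold: %s\n",
              if (nzchar(x$journal)) x$journal else "<none>",
              length(x$mesh), length(x$sections),
              paste(vapply(x$sections, `[[`, "", "kind"), collapse = ","),
              n_sent, x$gold_label))
  invisible(x)
}

#' Map a section heading to its canonical kind
#'
#' Case-insensitive lookup after stripping leading numbering (e.g.
#' `"1. Introduction"`) and surrounding punctuation. Unrecognized headings
#' map to `"other"`.
#'
#' @param heading Heading text.
#' @return One of `"abstract"`, `"introduction"`, `"methods"`, `"results"`,
#'   `"discussion"`, `"conclusion"`, `"other"`.
#' @export
normalize_heading <- function(heading) {
  key <- tolower(trimws(heading))
  key <- sub("^[0-9ivxlc]+[.):]*\\s*", "", key)   # strip "1." / "IV)" numbering
  key <- gsub("^[[:punct:][:space:]]+|[[:punct:][:space:]]+$", "", key)
  key <- gsub("\\s+", " ", key)
  key <- gsub(" & ", " and ", key, fixed = TRUE)
  if (key %in% names(HEADING_TABLE)) unname(HEADING_TABLE[[key]]) else "other"
}

#' Tokenize text into sentences
#'
#' Deterministic rule-based tokenization: sentences split on terminal
#' punctuation (`.`, `!`, `?`) followed by whitespace or end of text, with
#' an abbreviation guard list; single capital-letter initials (`"D."`,
#' `"B."`) never end a sentence, so binomials like "D. melanogaster" stay
#' intact. Tokens are whitespace-delimited with leading/trailing punctuation
#' stripped; hyphens and digits inside tokens are preserved, so gene symbols
#' like "Copg1" remain single tokens.
#'
#' @param text Input text (possibly empty).
#' @param abbreviations Guard list of abbreviation words (with trailing
#'   period); for multi-word guards only the final word is consulted.
#' @return List of [sentence()] objects; empty list for empty text.
#' @export
tokenize <- function(text, abbreviations = DEFAULT_ABBREVIATIONS) {
  text <- as.character(text)
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) return(list())
  guard <- tolower(vapply(strsplit(abbreviations, "\\s+"),
                          function(w) w[length(w)], ""))
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  boundaries <- integer(0)
  i <- 1L
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      # consume a run of terminal punctuation
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?", "\"", "'", ")")) {
        j <- j + 1L
      }
      at_end <- j >= n || grepl("^\\s$", chars[j + 1L])
      if (at_end && chars[i] == ".") {
        # find the word containing this period
        k <- i - 1L
        while (k >= 1L && !grepl("^\\s$", chars[k])) k <- k - 1L
        word <- paste(chars[(k + 1L):i], collapse = "")
        guarded <- tolower(word) %in% guard || grepl("^[A-Z]\\.$", word)
        if (!guarded) boundaries <- c(boundaries, j)
      } else if (at_end) {
        boundaries <- c(boundaries, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  out <- list()
  for (s in seq_along(starts)) {
    seg <- substr(text, starts[s], ends[s])
    lead_ws <- attr(regexpr("^\\s*", seg), "match.length")
    toks <- tokenize_words(seg)
    if (length(toks) == 0L) next
    out[[length(out) + 1L]] <- sentence(toks, starts[s] - 1L + lead_ws)
  }
  out
}

# Split a sentence segment into tokens: whitespace-delimited, surrounding
# punctuation stripped, internal hyphens/digits/periods kept.
tokenize_words <- function(seg) {
  raw <- strsplit(trimws(seg), "\\s+")[[1]]
  toks <- gsub("^[^A-Za-z0-9]+|[^A-Za-z0-9]+$", "", raw)
  toks[nzchar(toks)]
}

#' Clean raw text into a document
#'
#' Whitespace is collapsed, control characters removed, and section
#' headings detected line-wise and mapped to canonical kinds via
#' [normalize_heading()]. A body with no recognizable headings becomes a
#' single section of kind `"other"`.
#'
#' @param raw_title Title text.
#' @param raw_body Body text (possibly empty for abstract-only input).
#' @param doc_id Document identifier.
#' @param journal,mesh,gold_label Optional metadata.
#' @return An [document()] object.
#' @export
normalize_document <- function(raw_title, raw_body = "", doc_id = "doc",
                               journal = "", mesh = character(),
                               gold_label = NA_character_) {
  clean <- function(x) {
    x <- gsub("[\x01-\x08\x0b\x0c\x0e-\x1f]", "", x)
    x
  }
  raw_title <- clean(as.character(raw_title %||% ""))
  raw_body <- clean(as.character(raw_body %||% ""))
  title <- gsub("\\s+", " ", trimws(raw_title))
  if (!nzchar(title) && !nzchar(trimws(raw_body))) {
    abort_input("document has empty title and empty body")
  }
  sections <- list()
  if (nzchar(trimws(raw_body))) {
    lines <- strsplit(raw_body, "\n", fixed = TRUE)[[1]]
    cur_heading <- ""
    cur_lines <- character(0)
    flush <- function() {
      body <- gsub("\\s+", " ", trimws(paste(cur_lines, collapse = " ")))
      if (!nzchar(body) && !nzchar(cur_heading)) return(NULL)
      section(heading = cur_heading, sentences = tokenize(body))
    }
    for (ln in lines) {
      is_heading <- nzchar(trimws(ln)) &&
        length(strsplit(trimws(ln), "\\s+")[[1]]) <= 6L &&
        normalize_heading(ln) != "other"
      if (is_heading) {
        sec <- flush()
        if (!is.null(sec)) sections[[length(sections) + 1L]] <- sec
        cur_heading <- trimws(ln)
        cur_lines <- character(0)
      } else {
        cur_lines <- c(cur_lines, ln)
      }
    }
    sec <- flush()
    if (!is.null(sec)) sections[[length(sections) + 1L]] <- sec
  }
  document(doc_id = doc_id, title = title, journal = journal, mesh = mesh,
           sections = sections, gold_label = gold_label)
}

# Canonical text of a section: sentences joined with terminal periods so
# that re-tokenization reproduces the sentence boundaries.
section_text <- function(sec) {
  if (length(sec$sentences) == 0L) return("")
  paste0(vapply(sec$sentences, function(s) paste(s$tokens, collapse = " "), ""),
         collapse = ". ") |> paste0(".")
}

#' Read a corpus
#'
#' Two formats are supported. `"records"` is line-delimited JSON, one
#' document per line with fields `doc_id`, `title`, `journal`, `mesh`,
#' `sections` (array of `{heading, text}`) and optional `label`; section
#' kinds are derived from headings and text is re-tokenized. Unparseable
#' lines are skipped with a warning and counted in the `n_skipped`
#' attribute. `"plaintext_dir"` reads one `.txt` file per document (first
#' line is the title, filename stem the id) through [normalize_document()].
#'
#' @param path File (records) or directory (plaintext_dir).
#' @param format_name `"records"` or `"plaintext_dir"`.
#' @return List of [document()] objects.
#' @export
read_corpus <- function(path, format_name = c("records", "plaintext_dir")) {
  format_name <- match.arg(format_name)
  if (!file.exists(path)) abort_input("corpus path does not exist: ", path)
  docs <- list()
  n_skipped <- 0L
  if (format_name == "records") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e) NULL)
      doc <- if (is.null(rec)) NULL else tryCatch(record_to_document(rec),
                                                  error = function(e) NULL)
      if (is.null(doc)) {
        warning(sprintf("skipping unparseable record at line %d", i),
                call. = FALSE)
        n_skipped <- n_skipped + 1L
      } else {
        docs[[length(docs) + 1L]] <- doc
      }
    }
  } else {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    for (f in files) {
      lines <- readLines(f, encoding = "UTF-8", warn = FALSE)
      title <- if (length(lines)) lines[1] else ""
      body <- if (length(lines) > 1L) paste(lines[-1], collapse = "\n") else ""
      doc <- tryCatch(
        normalize_document(title, body,
                           doc_id = sub("\\.txt$", "", basename(f))),
        error = function(e) NULL)
      if (is.null(doc)) {
        warning(sprintf("skipping unparseable file %s", basename(f)),
                call. = FALSE)
        n_skipped <- n_skipped + 1L
      } else {
        docs[[length(docs) + 1L]] <- doc
      }
    }
  }
  ids <- vapply(docs, `[[`, "", "doc_id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    abort_input("duplicate doc_id in corpus: ", paste(unique(dup), collapse = ", "))
  }
  attr(docs, "n_skipped") <- n_skipped
  docs
}

record_to_document <- function(rec) {
  if (is.null(rec$doc_id)) stop("record missing doc_id")
  secs <- lapply(rec$sections %||% list(), function(s) {
    section(heading = as.character(s$heading %||% ""),
            sentences = tokenize(as.character(s$text %||% "")))
  })
  document(doc_id = rec$doc_id,
           title = as.character(rec$title %||% ""),
           journal = as.character(rec$journal %||% ""),
           mesh = as.character(unlist(rec$mesh %||% character())),
           sections = secs,
           gold_label = as.character(rec$label %||% NA_character_))
}

#' Write a corpus in the records format
#'
#' One JSON object per line; [read_corpus()] of the written file reproduces
#' the documents field-for-field (sentence boundaries are preserved by
#' writing each sentence with a terminal period).
#'
#' @param docs List of [document()] objects.
#' @param path Output file path.
#' @return Number of records written (invisibly a count, returned visibly).
#' @export
write_corpus <- function(docs, path) {
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) abort_input("cannot write corpus to ", path))
  on.exit(close(con))
  for (doc in docs) {
    rec <- list(doc_id = jsonlite::unbox(doc$doc_id),
                title = jsonlite::unbox(doc$title),
                journal = jsonlite::unbox(doc$journal),
                mesh = as.list(doc$mesh),
                sections = lapply(doc$sections, function(s) {
                  list(heading = jsonlite::unbox(s$heading),
                       text = jsonlite::unbox(section_text(s)))
                }))
    if (!is.na(doc$gold_label)) rec$label <- jsonlite::unbox(doc$gold_label)
    writeLines(jsonlite::toJSON(rec, auto_unbox = FALSE), con)
  }
  length(docs)
}

#' Keep only the abstract of each document
#'
#' Projects a full-text corpus to abstract-only form (used for the
#' full-text versus abstract comparison).
#'
#' @param docs List of documents.
#' @return List of documents containing only sections of kind `"abstract"`.
#' @export
abstract_only_corpus <- function(docs) {
  lapply(docs, function(doc) {
    doc$sections <- Filter(function(s) s$kind == "abstract", doc$sections)
    doc
  })
}

# All tokens of a document, by section/sentence, as a data.frame with
# 0-based coordinates.
doc_tokens <- function(doc) {
  rows <- list()
  for (si in seq_along(doc$sections)) {
    sec <- doc$sections[[si]]
    for (ti in seq_along(sec$sentences)) {
      toks <- sec$sentences[[ti]]$tokens
      if (length(toks) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        section_index = si - 1L, sentence_index = ti - 1L,
        token_index = seq_along(toks) - 1L,
        token = toks, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(section_index = integer(), sentence_index = integer(),
                      token_index = integer(), token = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
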