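#' Construct a short-text corpus
#'
#' A corpus holds documents with unique ids, their raw text, lowercased
#' whitespace tokens, and optional integer gold labels. Labels of any type are
#' re-coded to dense integers `0..K-1` in order of first appearance, so a
#' written corpus reads back with identical codes.
#'
#' @param text character vector of document texts (non-empty after trimming).
#' @param id optional character vector of unique document ids; defaults to
#'   `"doc0"`, `"doc1"`, ... in input order.
#' @param label optional vector of gold categories (any atomic type); either
#'   absent or present for every document.
#' @return An object of class `mcc_corpus`: a list with elements `id`, `text`,
#'   `tokens` (list of character vectors), `label` (dense integer codes or
#'   `NULL`), `n_labels`, and `label_levels` (the original values in code
#'   order).
#' @examples
#' mcc_corpus(c("fever and cough", "stock markets fell"), label = c("med", "fin"))
#' @export
mcc_corpus <- function(text, id = NULL, label = NULL) {
  if (length(text) == 0) stop_mixcc("corpus must contain at least one document")
  text <- as.character(text)
  if (is.null(id)) id <- sprintf("doc%d", seq_along(text) - 1L)
  id <- as.character(id)
  if (length(id) != length(text)) stop_mixcc("'id' and 'text' lengths differ")
  dup <- id[duplicated(id)]
  if (length(dup) > 0)
    stop_mixcc("duplicate document id(s): ", paste(unique(dup), collapse = ", "))
  tokens <- tokenize_text(text)
  empty <- which(lengths(tokens) == 0)
  if (length(empty) > 0)
    stop_mixcc("document(s) with empty text after tokenization: ",
               paste(id[empty], collapse = ", "))
  lab <- NULL; n_labels <- NULL; levels <- NULL
  if (!is.null(label)) {
    if (length(label) != length(text))
      stop_mixcc("'label' must be absent or given for every document")
    if (anyNA(label)) stop_mixcc("labels must not contain NA")
    levels <- unique(label)                       # first-appearance order
    lab <- match(label, levels) - 1L
    n_labels <- length(levels)
  }
  structure(list(id = id, text = text, tokens = tokens,
                 label = lab, n_labels = n_labels, label_levels = levels),
            class = "mcc_corpus")
}

#' @export
print.mcc_corpus <- function(x, ...) {
  cat(sprintf("<mcc_corpus> %d documents", length(x$id)))
  if (!is.null(x$label)) cat(sprintf(", %d gold classes", x$n_labels))
  cat("\n")
  n <- min(3L, length(x$id))
  for (i in seq_len(n))
    cat(sprintf("  %s: %s\n", x$id[i],
                substr(x$text[i], 1, 60)))
  if (length(x$id) > n) cat(sprintf("  ... and %d more\n", length(x$id) - n))
  invisible(x)
}

#' @export
length.mcc_corpus <- function(x) length(x$id)

# Internal: positional subset preserving class and label coding.
subset_corpus <- function(x, idx) {
  structure(list(id = x$id[idx], text = x$text[idx], tokens = x$tokens[idx],
                 label = if (!is.null(x$label)) x$label[idx],
                 n_labels = x$n_labels, label_levels = x$label_levels),
            class = "mcc_corpus")
}

#' Read a corpus from disk
#'
#' Supports two plain-text formats: JSON lines with one record
#' `{"id": ..., "text": ..., "label": ...}` per line (`id` and `label`
#' optional), and plain text with one document per line plus an optional
#' `id,label` CSV. Labels are re-coded to dense integers `0..K-1` by first
#' appearance.
#'
#' @param path file to read (UTF-8).
#' @param format `"jsonl"` or `"lines"`.
#' @param labels for `format = "lines"`, optional path to a CSV with columns
#'   `id,label` supplying gold labels by document id.
#' @return An [mcc_corpus()].
#' @export
read_corpus <- function(path, format = c("jsonl", "lines"), labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_mixcc("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) stop_mixcc("empty corpus file: ", path)
  if (format == "jsonl") {
    ids <- character(length(lines)); texts <- character(length(lines))
    labs <- vector("list", length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop_mixcc(sprintf("line %d: malformed JSON record (%s)",
                                           i, conditionMessage(e))))
      if (is.null(rec$text) || !nzchar(trimws(as.character(rec$text)[1])))
        stop_mixcc(sprintf("line %d: missing or empty 'text'", i))
      texts[i] <- as.character(rec$text)[1]
      ids[i] <- if (!is.null(rec$id)) as.character(rec$id)[1] else
        sprintf("doc%d", i - 1L)
      if (!is.null(rec$label)) labs[[i]] <- rec$label
    }
    have <- !vapply(labs, is.null, logical(1))
    if (any(have) && !all(have))
      stop_mixcc("labels present for some records but missing on line(s): ",
                 paste(which(!have), collapse = ", "))
    label <- if (all(have)) unlist(labs) else NULL
    mcc_corpus(texts, id = ids, label = label)
  } else {
    bad <- which(!nzchar(trimws(lines)))
    if (length(bad) > 0)
      stop_mixcc("empty document on line(s): ", paste(bad, collapse = ", "))
    ids <- sprintf("doc%d", seq_along(lines) - 1L)
    label <- NULL
    if (!is.null(labels)) {
      tab <- utils::read.csv(labels, stringsAsFactors = FALSE)
      if (!all(c("id", "label") %in% names(tab)))
        stop_mixcc("label file must have columns 'id' and 'label'")
      m <- match(ids, as.character(tab$id))
      if (anyNA(m))
        stop_mixcc("label file missing id(s): ",
                   paste(ids[is.na(m)][seq_len(min(5, sum(is.na(m))))],
                         collapse = ", "))
      label <- tab$label[m]
    }
    mcc_corpus(lines, id = ids, label = label)
  }
}

#' Write a corpus as JSON lines
#'
#' One record per line with keys `id`, `text`, and (when present) the dense
#' integer `label`. Reading the file back with [read_corpus()] reproduces ids,
#' token sequences, and label codes exactly.
#'
#' @param corpus an [mcc_corpus()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "mcc_corpus"))
  n <- length(corpus$id)
  recs <- vapply(seq_len(n), function(i) {
    rec <- list(id = corpus$id[i], text = corpus$text[i])
    if (!is.null(corpus$label)) rec$label <- corpus$label[i]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(recs, path, useBytes = TRUE)
  invisible(path)
}

#' Write cluster assignments and metrics
#'
#' Writes `assignments.csv` (header `id,cluster`, rows in the order of
#' `assignments`) and, when `metrics` is non-`NULL`, `metrics.json`. Output is
#' byte-stable for identical inputs.
#'
#' @param assignments named integer vector mapping document id to cluster.
#' @param metrics optional named list of numbers (e.g. `acc`, `nmi`).
#' @param out_dir output directory, created (recursively) if needed.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(assignments, metrics = NULL, out_dir = ".") {
  if (is.null(names(assignments)))
    stop_mixcc("'assignments' must be a named vector (names are document ids)")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_mixcc("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir, "assignments.csv")
  con <- file(paths, "wb")
  writeLines(c("id,cluster",
               sprintf("%s,%d", names(assignments), as.integer(assignments))),
             con)
  close(con)
  if (!is.null(metrics)) {
    mp <- file.path(out_dir, "metrics.json")
    writeLines(as.character(jsonlite::toJSON(as.list(metrics),
                                             auto_unbox = TRUE, digits = 10)),
               mp, useBytes = TRUE)
    paths <- c(paths, mp)
  }
  invisible(paths)
}

#' Generate a synthetic topic-separable corpus
#'
#' Mixture-of-unigrams generator for testing and benchmarking: `n_topics`
#' latent topics with disjoint vocabularies (`"t{t}_w{j}"`) plus a shared
#' vocabulary (`"sh_w{j}"`). A document of topic `t` draws each of its
#' `doc_len` tokens i.i.d.: with probability `noise_rate` uniformly from the
#' shared vocabulary, otherwise uniformly from topic `t`'s vocabulary. Gold
#' labels are the topic indices; output is fully determined by `seed`.
#'
#' @param n_topics number of topics (K), at least 1.
#' @param docs_per_topic documents generated per topic.
#' @param vocab_per_topic size of each topic-specific vocabulary.
#' @param shared_vocab size of the shared vocabulary (must be positive when
#'   `noise_rate > 0`).
#' @param doc_len tokens per document, at least 1.
#' @param noise_rate probability of drawing a token from the shared vocabulary.
#' @param seed integer seed.
#' @return An [mcc_corpus()] with `n_topics * docs_per_topic` documents.
#' @examples
#' synthetic_corpus(2, 3, vocab_per_topic = 10, shared_vocab = 0,
#'                  doc_len = 5, noise_rate = 0, seed = 1)
#' @export
synthetic_corpus <- function(n_topics, docs_per_topic, vocab_per_topic = 50,
                             shared_vocab = 50, doc_len = 12,
                             noise_rate = 0.2, seed = 1) {
  if (n_topics < 1) stop_mixcc("'n_topics' must be at least 1")
  if (doc_len < 1) stop_mixcc("'doc_len' must be at least 1")
  if (docs_per_topic < 1) stop_mixcc("'docs_per_topic' must be at least 1")
  if (vocab_per_topic < 1) stop_mixcc("'vocab_per_topic' must be at least 1")
  check_prob(noise_rate, "noise_rate")
  if (noise_rate > 0 && shared_vocab < 1)
    stop_mixcc("'shared_vocab' must be positive when 'noise_rate' > 0")
  n <- n_topics * docs_per_topic
  with_seed(seed, {
    texts <- character(n)
    topics <- integer(n)
    k <- 1L
    for (t in seq_len(n_topics) - 1L) {
      topic_vocab <- sprintf("t%d_w%d", t, seq_len(vocab_per_topic) - 1L)
      for (d in seq_len(docs_per_topic)) {
        from_shared <- stats::runif(doc_len) < noise_rate
        toks <- character(doc_len)
        n_sh <- sum(from_shared)
        if (n_sh > 0)
          toks[from_shared] <- sprintf(
            "sh_w%d", sample.int(shared_vocab, n_sh, replace = TRUE) - 1L)
        if (n_sh < doc_len)
          toks[!from_shared] <- topic_vocab[
            sample.int(vocab_per_topic, doc_len - n_sh, replace = TRUE)]
        texts[k] <- paste(toks, collapse = " ")
        topics[k] <- t
        k <- k + 1L
      }
    }
    mcc_corpus(texts, label = topics)
  })
}
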