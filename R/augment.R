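#' Specify a text augmenter
#'
#' An augmenter produces a perturbed view of a document. Two explicit
#' operators are provided (`word_deletion`, `char_noise`), plus `identity` and
#' a `mask_and_fill` contract that delegates replacements to an injected
#' token predictor (e.g. a masked-language-model wrapper); no pretrained model
#' is bundled.
#'
#' @param kind one of `"word_deletion"`, `"char_noise"`, `"mask_and_fill"`,
#'   `"identity"`.
#' @param rate per-token (or per-character) perturbation probability in
#'   \code{[0, 1]}.
#' @param seed integer base seed; each document is perturbed under the
#'   sub-seed `xor(seed, document index)` so views do not depend on batching.
#' @param predictor required iff `kind = "mask_and_fill"`: a
#'   `function(tokens, positions)` receiving the token sequence with masked
#'   positions set to `"[MASK]"` and returning one replacement token per
#'   masked position.
#' @return An object of class `mcc_augmenter`.
#' @seealso [word_deletion()], [char_noise()], [mask_and_fill()],
#'   [make_view_pair()]
#' @export
augmenter <- function(kind = c("word_deletion", "char_noise", "mask_and_fill",
                               "identity"),
                      rate = 0.15, seed = 0L, predictor = NULL) {
  kind <- match.arg(kind)
  check_prob(rate, "rate")
  if (kind == "mask_and_fill" && !is.function(predictor))
    stop_mixcc("'mask_and_fill' requires a predictor function")
  if (kind != "mask_and_fill" && !is.null(predictor))
    stop_mixcc("'predictor' is only meaningful for kind = 'mask_and_fill'")
  structure(list(kind = kind, rate = rate, seed = as.integer(seed),
                 predictor = predictor),
            class = "mcc_augmenter")
}

#' @export
print.mcc_augmenter <- function(x, ...) {
  cat(sprintf("<mcc_augmenter> %s (rate %.3g)\n", x$kind, x$rate))
  invisible(x)
}

#' Randomly delete tokens
#'
#' Each token is deleted independently with probability `rate`; if every token
#' would be deleted, one uniformly chosen token is retained, so the output is
#' never empty. Relative order is preserved.
#'
#' @param tokens non-empty character vector.
#' @param rate deletion probability in \code{[0, 1]}.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return Character vector of surviving tokens.
#' @export
word_deletion <- function(tokens, rate, seed = 0L) {
  if (length(tokens) == 0) stop_mixcc("'tokens' must be non-empty")
  check_prob(rate, "rate")
  with_seed(seed, {
    keep <- stats::runif(length(tokens)) >= rate
    if (!any(keep)) keep[sample.int(length(tokens), 1L)] <- TRUE
    tokens[keep]
  })
}

#' Randomly corrupt characters
#'
#' Per character, with probability `rate`, one uniformly chosen edit is
#' applied: substitute with a random lowercase letter, delete, or insert a
#' random lowercase letter after it. If every character would be removed, one
#' uniformly chosen original character is retained, so the output is never
#' empty.
#'
#' @param text non-empty string.
#' @param rate per-character edit probability in \code{[0, 1]}.
#' @param seed integer seed.
#' @return The corrupted string.
#' @export
char_noise <- function(text, rate, seed = 0L) {
  if (length(text) != 1 || !nzchar(text)) stop_mixcc("'text' must be a non-empty string")
  check_prob(rate, "rate")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  with_seed(seed, {
    hit <- stats::runif(length(chars)) < rate
    out <- vector("list", length(chars))
    for (i in seq_along(chars)) {
      if (!hit[i]) { out[[i]] <- chars[i]; next }
      op <- sample.int(3L, 1L)
      out[[i]] <- switch(op,
        letters[sample.int(26L, 1L)],                       # substitute
        character(0),                                       # delete
        c(chars[i], letters[sample.int(26L, 1L)]))          # insert after
    }
    res <- unlist(out)
    if (length(res) == 0) res <- chars[sample.int(length(chars), 1L)]
    paste(res, collapse = "")
  })
}

#' Mask tokens and fill with a predictor
#'
#' Each position is masked independently with probability `rate`; masked
#' positions are set to `"[MASK]"` and handed to `predictor(tokens,
#' positions)`, whose return values replace them. Sequence length is
#' preserved; with a deterministic predictor the result is deterministic given
#' the seed.
#'
#' @param tokens non-empty character vector.
#' @param rate masking probability in \code{[0, 1]}.
#' @param predictor `function(tokens, positions)` returning one replacement
#'   token per masked position.
#' @param seed integer seed.
#' @return Character vector of the same length as `tokens`.
#' @export
mask_and_fill <- function(tokens, rate, predictor, seed = 0L) {
  if (length(tokens) == 0) stop_mixcc("'tokens' must be non-empty")
  check_prob(rate, "rate")
  if (!is.function(predictor)) stop_mixcc("'predictor' must be a function")
  pos <- with_seed(seed, which(stats::runif(length(tokens)) < rate))
  if (length(pos) == 0) return(tokens)
  masked <- tokens
  masked[pos] <- "[MASK]"
  repl <- tryCatch(predictor(masked, pos), error = function(e)
    stop_mixcc(sprintf("predictor failed at position(s) %s: %s",
                       paste(pos, collapse = ","), conditionMessage(e))))
  if (length(repl) != length(pos))
    stop_mixcc(sprintf(
      "predictor returned %d replacement(s) for %d masked position(s)",
      length(repl), length(pos)))
  out <- tokens
  out[pos] <- as.character(repl)
  out
}

# Apply an augmenter to one document's tokens under an explicit seed.
# char_noise operates on the joined text and re-tokenizes; if corruption
# destroys every token boundary a uniformly chosen original token is kept.
apply_augmenter <- function(aug, tokens, seed) {
  switch(aug$kind,
    identity = tokens,
    word_deletion = word_deletion(tokens, aug$rate, seed),
    mask_and_fill = mask_and_fill(tokens, aug$rate, aug$predictor, seed),
    char_noise = {
      out <- char_noise(paste(tokens, collapse = " "), aug$rate, seed)
      toks <- tokenize_text(out)[[1]]
      if (length(toks) == 0)
        toks <- with_seed(derive_seed(seed, 997L),
                          tokens[sample.int(length(tokens), 1L)])
      toks
    })
}

#' Build the two augmented views of a batch
#'
#' Applies augmenters `u1` and `u2` document-wise to a batch, producing three
#' index-aligned token batches (original, view 1, view 2). Same-index entries
#' across the batches are positive pairs; cross-index entries are negative
#' pairs. Each document is perturbed under the sub-seed
#' `xor(augmenter seed, document index)`, so views are independent of how the
#' corpus was split into batches.
#'
#' @param batch an [mcc_corpus()] (typically a mini-batch subset).
#' @param u1,u2 [augmenter()] specifications for the two views.
#' @param indices integer identities of the documents (their positions in the
#'   full corpus); defaults to `seq_along(batch$id)`.
#' @return An object of class `mcc_view_pair`: list with `ids` and the three
#'   aligned token batches `original`, `view1`, `view2`.
#' @export
make_view_pair <- function(batch, u1, u2, indices = NULL) {
  stopifnot(inherits(batch, "mcc_corpus"),
            inherits(u1, "mcc_augmenter"), inherits(u2, "mcc_augmenter"))
  n <- length(batch$id)
  if (n == 0) stop_mixcc("batch must be non-empty")
  indices <- indices %||% seq_len(n)
  aug_one <- function(aug, i) {
    tryCatch(apply_augmenter(aug, batch$tokens[[i]],
                             sub_seed(aug$seed, indices[i])),
             error = function(e)
               stop_mixcc(sprintf("augmentation failed for document '%s': %s",
                                  batch$id[i], conditionMessage(e))))
  }
  structure(list(ids = batch$id,
                 original = batch$tokens,
                 view1 = lapply(seq_len(n), function(i) aug_one(u1, i)),
                 view2 = lapply(seq_len(n), function(i) aug_one(u2, i))),
            class = "mcc_view_pair")
}
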