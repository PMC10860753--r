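# Internal helpers: seeded RNG scoping, seed derivation, tokenization.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Sets the RNG seed, evaluates `code`, and restores the caller's RNG state,
#' so that no exported routine touches global random state.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Per-document sub-seed: seed XOR index, masked to a non-negative 31-bit int so
# results do not depend on how a corpus is partitioned into batches.
sub_seed <- function(seed, index) {
  bitwAnd(bitwXor(as.integer(seed), as.integer(index)), 2147483647L)
}

# Derive independent seed streams from a run seed and integer tags
# (polynomial hash mod a 31-bit prime; always non-negative).
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483629
  for (cmp in c(...)) h <- (h * 1009 + as.numeric(cmp) + 1) %% 2147483629
  as.integer(h)
}

#' Tokenize text
#'
#' Lowercased whitespace tokenization used throughout the package: the text is
#' lowercased and split on runs of whitespace; empty fragments are dropped.
#'
#' @param x character vector of texts.
#' @return A list of character vectors, one per input text.
#' @examples
#' tokenize_text("Fever and  cough")
#' @export
tokenize_text <- function(x) {
  out <- strsplit(tolower(trimws(x)), "[[:space:]]+")
  lapply(out, function(t) t[nzchar(t)])
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

stop_mixcc <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop_mixcc(sprintf("'%s' must be a single probability in [0, 1]", name))
  x
}
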