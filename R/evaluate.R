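# Clustering evaluation: Hungarian-matched accuracy and NMI.

# Minimum-cost perfect assignment on a square cost matrix (Hungarian
# algorithm with potentials, O(n^3)). Returns match[row] = column.
solve_assignment_min <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) stop_mixcc("cost matrix must be square")
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)   # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) match[p[j + 1]] <- j
  match
}

contingency_matrix <- function(pred, gold) {
  pred <- factor(pred); gold <- factor(gold)
  unclass(table(pred, gold))
}

#' Hungarian-matched clustering accuracy
#'
#' The fraction of documents correctly assigned under the best one-to-one
#' mapping between predicted clusters and gold classes, found by optimal
#' assignment on the contingency matrix (zero-padded to square when the
#' numbers of clusters differ). Invariant under any relabeling of either
#' partition.
#'
#' @param pred,gold label vectors of equal length (any atomic type).
#' @return Accuracy in \code{[0, 1]}.
#' @examples
#' clustering_accuracy(c(1, 0, 0), c(0, 1, 1))  # 1: a pure relabeling
#' @export
clustering_accuracy <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop_mixcc("'pred' and 'gold' must have equal length")
  if (length(pred) == 0) stop_mixcc("empty label vectors")
  cont <- contingency_matrix(pred, gold)
  m <- max(dim(cont))
  padded <- matrix(0, m, m)
  padded[seq_len(nrow(cont)), seq_len(ncol(cont))] <- cont
  match <- solve_assignment_min(-padded)
  sum(padded[cbind(seq_len(m), match)]) / length(pred)
}

entropy_nats <- function(counts) {
  pr <- counts[counts > 0] / sum(counts)
  -sum(pr * log(pr))
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions divided by the arithmetic
#' mean of their entropies (natural logarithms; the base cancels). Returns 1
#' when the partitions are identical up to relabeling — including the
#' degenerate case where both are single clusters — and 0 when exactly one
#' partition has zero entropy.
#'
#' @param pred,gold label vectors of equal length.
#' @return NMI in \code{[0, 1]}.
#' @export
nmi <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop_mixcc("'pred' and 'gold' must have equal length")
  if (length(pred) == 0) stop_mixcc("empty label vectors")
  cont <- contingency_matrix(pred, gold)
  n <- sum(cont)
  hp <- entropy_nats(rowSums(cont))
  hg <- entropy_nats(colSums(cont))
  if (hp == 0 && hg == 0) return(1)
  if (hp == 0 || hg == 0) return(0)
  a <- rowSums(cont); b <- colSums(cont)
  nz <- which(cont > 0, arr.ind = TRUE)
  mi <- sum(cont[nz] / n * log(cont[nz] * n / (a[nz[, 1]] * b[nz[, 2]])))
  max(0, min(1, mi / ((hp + hg) / 2)))
}

#' Evaluate assignments against a labeled corpus
#'
#' Aligns predicted cluster assignments (a named vector keyed by document id)
#' with the corpus gold labels and computes Hungarian-matched accuracy, NMI,
#' and the contingency matrix.
#'
#' @param assignments named integer vector, one entry per corpus document.
#' @param corpus an [mcc_corpus()] with gold labels.
#' @return An object of class `mcc_eval`: list with `acc`, `nmi`,
#'   `contingency` (predicted clusters x gold classes), and `n`.
#' @export
evaluate_clustering <- function(assignments, corpus) {
  stopifnot(inherits(corpus, "mcc_corpus"))
  if (is.null(corpus$label))
    stop_mixcc("corpus has no gold labels to evaluate against")
  if (is.null(names(assignments)))
    stop_mixcc("'assignments' must be named by document id")
  m <- match(corpus$id, names(assignments))
  if (anyNA(m))
    stop_mixcc("assignments missing for document id(s): ",
               paste(corpus$id[is.na(m)][seq_len(min(5, sum(is.na(m))))],
                     collapse = ", "))
  pred <- as.integer(assignments[m])
  gold <- corpus$label
  structure(list(acc = clustering_accuracy(pred, gold),
                 nmi = nmi(pred, gold),
                 contingency = contingency_matrix(pred, gold),
                 n = length(gold)),
            class = "mcc_eval")
}

#' @export
print.mcc_eval <- function(x, ...) {
  cat(sprintf("<mcc_eval> n = %d  ACC = %.4f  NMI = %.4f\n", x$n, x$acc, x$nmi))
  invisible(x)
}
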