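#' Construct a score matrix
#'
#' A score matrix holds the per-class confidence scores that `N` classifiers
#' (rows) assign to `C` classes (columns) for a single input sample. Softmax
#' outputs satisfy the row-sum-one constraint by construction; arbitrary
#' nonnegative scores can be brought to it with [normalize_scores()].
#'
#' @param scores numeric matrix (or object coercible to one), models in rows,
#'   classes in columns. All entries must be finite and nonnegative.
#' @param model_ids character vector of row labels; defaults to existing
#'   rownames or `M1..MN`.
#' @param class_ids character vector of column labels; defaults to existing
#'   colnames or `C1..CC`.
#' @return a numeric matrix of class `score_matrix` with `model_ids` as
#'   rownames and `class_ids` as colnames.
#' @examples
#' score_matrix(rbind(c(0.9, 0.1), c(0.6, 0.4)))
#' @export
score_matrix <- function(scores, model_ids = NULL, class_ids = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (nrow(scores) < 1L) stop_data("score matrix needs at least one model row")
  if (ncol(scores) < 2L) stop_data("score matrix needs at least two classes")
  bad <- which(!is.finite(scores) | scores < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(scores))
    stop_data(sprintf(
      "invalid confidence score at model %d, class %d: %s",
      i[1L], i[2L], format(scores[bad[1L]])))
  }
  rownames(scores) <- model_ids %||% rownames(scores) %||%
    paste0("M", seq_len(nrow(scores)))
  colnames(scores) <- class_ids %||% colnames(scores) %||%
    paste0("C", seq_len(ncol(scores)))
  if (length(rownames(scores)) != nrow(scores) ||
      length(colnames(scores)) != ncol(scores)) {
    stop_data("model_ids/class_ids lengths do not match the score grid")
  }
  structure(scores, class = c("score_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix: %d model(s) x %d class(es)>\n", nrow(x), ncol(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Test whether each model row sums to one
#'
#' @param scores a [score_matrix()] (or plain matrix).
#' @param tol absolute tolerance on each row sum.
#' @return logical scalar.
#' @export
is_normalized <- function(scores, tol = 1e-9) {
  all(abs(rowSums(scores) - 1) <= tol)
}

#' Normalize confidence scores row-wise
#'
#' Divides each model row by its sum so rows sum to one, preserving the
#' proportions between class scores. A row of all zeros carries no preference
#' and is mapped to the uniform distribution `1/C`.
#'
#' @param raw a [score_matrix()] or numeric matrix of nonnegative finite
#'   scores.
#' @return a normalized `score_matrix`.
#' @examples
#' normalize_scores(rbind(c(2, 2), c(3, 1)))
#' @export
normalize_scores <- function(raw) {
  m <- score_matrix(raw,
                    model_ids = rownames(raw), class_ids = colnames(raw))
  s <- rowSums(m)
  zero <- s == 0
  s[zero] <- 1
  out <- m / s
  out[zero, ] <- 1 / ncol(m)
  score_matrix(out, model_ids = rownames(m), class_ids = colnames(m))
}

# Internal: validate a list of score matrices shares one N x C shape and the
# same class labels; returns the list with score_matrix class enforced.
check_batch <- function(samples) {
  if (!length(samples)) return(samples)
  samples <- lapply(samples, function(s) {
    score_matrix(s, model_ids = rownames(s), class_ids = colnames(s))
  })
  d <- vapply(samples, dim, integer(2L))
  if (any(d[1L, ] != d[1L, 1L]) || any(d[2L, ] != d[2L, 1L])) {
    stop_data("all samples in a batch must share the same N x C shape")
  }
  samples
}
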