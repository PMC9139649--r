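#' Classical score-combination rules
#'
#' The three standard decision-level combiners used as baselines for fuzzy
#' rank level fusion, all over the same [score_matrix()] input:
#' \itemize{
#'   \item `sum_rule()`: per-class sum of confidences, predict the argmax;
#'   \item `product_rule()`: per-class product of confidences, predict the
#'     argmax (a single zero score annihilates a class — no epsilon flooring
#'     unless `floor` is set);
#'   \item `majority_vote()`: each model votes for its own argmax class; the
#'     class with most votes wins. Vote ties fall back to the sum rule over
#'     the tied classes, then to the lowest class index.
#' }
#' All argmax ties break towards the lowest class index for determinism.
#'
#' @param scores a normalized [score_matrix()].
#' @param auto_normalize logical; renormalize unnormalized rows instead of
#'   erroring.
#' @param floor optional nonnegative value substituted for zero scores in the
#'   product rule (off by default; zeros then annihilate).
#' @return an object of class `baseline_result`: list with `combined_scores`
#'   (per-class sums/products, or vote counts for majority voting),
#'   `predicted_class`, `predicted_label`, `rule`, and for majority voting
#'   `votes` (each model's argmax class index).
#' @examples
#' s <- score_matrix(rbind(c(0.7, 0.3), c(0.2, 0.8)))
#' sum_rule(s)
#' product_rule(s)
#' majority_vote(s)
#' @name baseline_fusion
NULL

baseline_input <- function(scores, auto_normalize) {
  scores <- score_matrix(scores, rownames(scores), colnames(scores))
  if (!is_normalized(scores)) {
    if (auto_normalize) scores <- normalize_scores(scores)
    else stop_data("score rows must sum to 1; normalize first or set auto_normalize = TRUE")
  }
  scores
}

baseline_result <- function(combined, rule, votes = NULL,
                            pred = which.max(combined)) {
  structure(list(
    combined_scores = combined,
    predicted_class = as.integer(pred),
    predicted_label = names(combined)[pred],
    rule = rule,
    votes = votes
  ), class = "baseline_result")
}

#' @rdname baseline_fusion
#' @export
sum_rule <- function(scores, auto_normalize = FALSE) {
  s <- baseline_input(scores, auto_normalize)
  baseline_result(colSums(s), "sum")
}

#' @rdname baseline_fusion
#' @export
product_rule <- function(scores, auto_normalize = FALSE, floor = NULL) {
  s <- baseline_input(scores, auto_normalize)
  m <- unclass(s)
  if (!is.null(floor)) {
    if (!is.numeric(floor) || floor < 0) stop_usage("floor must be >= 0")
    m[m == 0] <- floor
  }
  fc <- apply(m, 2, prod)
  names(fc) <- colnames(s)
  baseline_result(fc, "product")
}

#' @rdname baseline_fusion
#' @export
majority_vote <- function(scores, auto_normalize = FALSE) {
  s <- baseline_input(scores, auto_normalize)
  votes <- apply(unclass(s), 1, which.max)  # ties -> lowest index
  counts <- tabulate(votes, nbins = ncol(s))
  names(counts) <- colnames(s)
  top <- which(counts == max(counts))
  if (length(top) > 1L) {
    # cascade: sum rule restricted to the tied classes, then lowest index
    sums <- colSums(s)[top]
    top <- top[which.max(sums)]
  }
  baseline_result(counts, "majority", votes = as.integer(votes), pred = top)
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("<baseline_result: %s rule>\n", x$rule))
  print(x$combined_scores, ...)
  cat("predicted:", x$predicted_label,
      sprintf("(class %d)\n", x$predicted_class))
  invisible(x)
}

#' Fuse one sample with a named rule
#'
#' Dispatch helper used by the batch and CLI layers: applies fuzzy rank level
#' fusion or one of the baseline combiners selected by name.
#'
#' @param scores a normalized [score_matrix()].
#' @param rule one of `"frlf"`, `"sum"`, `"product"`, `"majority"`.
#' @param params a [fusion_params()] (used by `"frlf"` only).
#' @param auto_normalize logical, see [frlf_fuse()].
#' @return an `frlf_result` or `baseline_result`.
#' @export
fuse_scores <- function(scores, rule = c("frlf", "sum", "product", "majority"),
                        params = fusion_params(), auto_normalize = FALSE) {
  rule <- match.arg(rule)
  switch(rule,
    frlf = frlf_fuse(scores, params, auto_normalize),
    sum = sum_rule(scores, auto_normalize),
    product = product_rule(scores, auto_normalize),
    majority = majority_vote(scores, auto_normalize))
}
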