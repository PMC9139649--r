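#' Fusion hyperparameters
#'
#' Bundles the hyperparameters of fuzzy rank level fusion: the size of the
#' per-model top-K set, the rank and confidence penalties substituted for
#' classes outside a model's top-K set, and the variance of the Gaussian used
#' to turn confidences into fuzzy ranks.
#'
#' The defaults (`k = 1`, `rank_penalty = 0.33`, `conf_penalty = 0.05`,
#' `variance = 1`) are the values tuned for binary DaTscan classification;
#' both penalties push a class that misses a model's top-K set away from
#' winning.
#'
#' @param k positive integer, size of each model's top-K fuzzy-ranked set.
#' @param rank_penalty nonnegative rank substituted outside the top-K set.
#' @param conf_penalty nonnegative confidence substituted outside the top-K
#'   set.
#' @param variance positive variance of the Gaussian in the fuzzy rank.
#' @return a list of class `fusion_params`.
#' @export
fusion_params <- function(k = 1L, rank_penalty = 0.33, conf_penalty = 0.05,
                          variance = 1.0) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop_usage("k must be a positive integer")
  }
  for (nm in c("rank_penalty", "conf_penalty", "variance")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_usage(nm, " must be a finite number")
    }
  }
  if (rank_penalty < 0 || conf_penalty < 0) {
    stop_usage("penalties must be nonnegative")
  }
  if (variance <= 0) stop_usage("variance must be > 0")
  structure(list(k = k, rank_penalty = rank_penalty,
                 conf_penalty = conf_penalty, variance = variance),
            class = "fusion_params")
}

#' Fuzzy rank of a confidence score
#'
#' Maps a confidence score to a rank via the complement of a Gaussian density
#' centred at the ideal confidence 1:
#' `r(cs) = 1 - exp(-(cs - 1)^2 / (2 * variance))`.
#' A perfectly confident score gets rank 0 (best); as the score falls to 0 the
#' rank rises towards `1 - exp(-1/(2 * variance))` (about 0.393 at unit
#' variance). The map is strictly decreasing in the score on \[0, 1\], so
#' smaller rank means stronger support — the fuzzy analogue of rank 1.
#'
#' @param cs numeric vector of confidence scores in \[0, 1\].
#' @param variance positive Gaussian variance (default 1).
#' @return numeric vector of fuzzy ranks.
#' @examples
#' fuzzy_rank(c(1, 0.9, 0))
#' @export
fuzzy_rank <- function(cs, variance = 1.0) {
  if (!is.numeric(variance) || length(variance) != 1L ||
      !is.finite(variance) || variance <= 0) {
    stop_usage("variance must be a positive number")
  }
  1 - exp(-((cs - 1)^2) / (2 * variance))
}

#' Fuzzy rank matrix of a score matrix
#'
#' Applies [fuzzy_rank()] elementwise to a normalized score matrix.
#'
#' @param scores a normalized [score_matrix()].
#' @param params a [fusion_params()] (only `variance` is used).
#' @return matrix of fuzzy ranks with the same dimnames, class
#'   `fuzzy_rank_matrix`.
#' @export
fuzzy_rank_matrix <- function(scores, params = fusion_params()) {
  scores <- score_matrix(scores, rownames(scores), colnames(scores))
  r <- fuzzy_rank(unclass(scores), params$variance)
  structure(r, class = c("fuzzy_rank_matrix", "matrix", "array"))
}

#' Per-model top-K classes by fuzzy rank
#'
#' For each model, the `k` classes with the smallest fuzzy rank (i.e. highest
#' support). Ties are broken towards the lowest class index, so the result is
#' deterministic.
#'
#' @param ranks a matrix of fuzzy ranks (models x classes).
#' @param k integer, `1 <= k <= ncol(ranks)`.
#' @return a list with one integer vector of class indices per model, ordered
#'   by increasing rank.
#' @export
top_k_classes <- function(ranks, k = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > ncol(ranks)) {
    stop_usage("k must satisfy 1 <= k <= number of classes (", ncol(ranks), ")")
  }
  lapply(seq_len(nrow(ranks)), function(i) {
    order(ranks[i, ])[seq_len(k)]  # order() is stable: ties -> lowest index
  })
}

#' Fuse one sample's confidence scores by fuzzy rank level fusion
#'
#' Implements the full decision rule. Each model's confidences are converted
#' to fuzzy ranks; each model contributes its top-K set. For every class `c`:
#' \itemize{
#'   \item the rank sum `RS_c` adds the class's fuzzy rank over models whose
#'     top-K set contains it, substituting `rank_penalty` otherwise;
#'   \item the confidence-sum complement `CSS_c` is one minus the mean of the
#'     class's confidences over models, with `conf_penalty` substituted
#'     outside the top-K set;
#'   \item the final score is `FS_c = RS_c * CSS_c`.
#' }
#' The predicted class minimizes the final score (fuzzy rank 0 is ideal), with
#' ties broken towards the lowest class index.
#'
#' @param scores a normalized [score_matrix()] (rows sum to one). Set
#'   `auto_normalize = TRUE` to renormalize unnormalized input instead of
#'   erroring.
#' @param params a [fusion_params()].
#' @param auto_normalize logical; renormalize rows that do not sum to one.
#' @return an object of class `frlf_result`: list with `rank_sums`,
#'   `conf_complements`, `final_scores` (all named by class),
#'   `predicted_class` (integer index), `predicted_label`, and `top_k_sets`
#'   (per-model class indices).
#' @examples
#' s <- score_matrix(rbind(c(0.9, 0.1), c(0.6, 0.4)))
#' frlf_fuse(s)
#' @export
frlf_fuse <- function(scores, params = fusion_params(),
                      auto_normalize = FALSE) {
  scores <- score_matrix(scores, rownames(scores), colnames(scores))
  if (!inherits(params, "fusion_params")) {
    params <- do.call(fusion_params, as.list(params))
  }
  if (!is_normalized(scores)) {
    if (auto_normalize) scores <- normalize_scores(scores)
    else stop_data("score rows must sum to 1; normalize first or set auto_normalize = TRUE")
  }
  if (params$k > ncol(scores)) {
    stop_usage("k (", params$k, ") exceeds the number of classes (",
               ncol(scores), ")")
  }

  s <- unclass(scores)
  ranks <- fuzzy_rank(s, params$variance)
  topk <- top_k_classes(ranks, params$k)

  in_topk <- matrix(FALSE, nrow(s), ncol(s))
  for (i in seq_along(topk)) in_topk[i, topk[[i]]] <- TRUE

  rank_terms <- ifelse(in_topk, ranks, params$rank_penalty)
  conf_terms <- ifelse(in_topk, s, params$conf_penalty)
  rs <- colSums(rank_terms)
  css <- 1 - colMeans(conf_terms)
  fs <- rs * css
  names(rs) <- names(css) <- names(fs) <- colnames(s)

  pred <- which.min(fs)  # ties -> lowest index
  structure(list(
    rank_sums = rs,
    conf_complements = css,
    final_scores = fs,
    predicted_class = as.integer(pred),
    predicted_label = colnames(s)[pred],
    top_k_sets = topk,
    params = params
  ), class = "frlf_result")
}

#' @export
print.frlf_result <- function(x, ...) {
  cat("<frlf_result>\n")
  tab <- rbind(rank_sum = x$rank_sums,
               conf_complement = x$conf_complements,
               final_score = x$final_scores)
  print(tab, ...)
  cat("predicted:", x$predicted_label,
      sprintf("(class %d, argmin final score)\n", x$predicted_class))
  invisible(x)
}

#' Fuse a batch of samples
#'
#' Applies [frlf_fuse()] to every score matrix in a list; all samples must
#' share the same model/class layout. Order is preserved and the result is
#' deterministic.
#'
#' @param samples list of [score_matrix()] objects.
#' @inheritParams frlf_fuse
#' @return list of `frlf_result`, one per sample.
#' @export
frlf_fuse_batch <- function(samples, params = fusion_params(),
                            auto_normalize = FALSE) {
  samples <- check_batch(samples)
  lapply(samples, frlf_fuse, params = params, auto_normalize = auto_normalize)
}
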