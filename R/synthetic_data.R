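#' Configuration for the synthetic confidence-score simulator
#'
#' Describes an ensemble of base classifiers of configurable quality so the
#' fusion and evaluation machinery can be exercised without trained models or
#' imaging data. Defaults mirror a binary disease-screening test set: two
#' classes, four base models, two-thirds prevalence of the positive class
#' (86 positives to 43 negatives).
#'
#' @param n_samples number of labelled samples to simulate.
#' @param n_models number of base classifiers (default 4).
#' @param n_classes number of classes (default 2).
#' @param prevalence probability of the positive class, strictly inside
#'   (0, 1); default `86/129`. For `n_classes > 2` the remaining mass is
#'   split evenly over the other classes.
#' @param model_accuracies per-model probability of favouring the true class;
#'   length `n_models`, values in (0.5, 1\]. Default 0.93 for every model.
#' @param concentration positive sharpness of the favoured-class confidence:
#'   the favoured class receives `0.5 + 0.5 * Beta(concentration, 1)`, so
#'   larger values push rows towards one-hot (default 10, giving typical top
#'   confidences around 0.95).
#' @param class_labels labels for the classes; default `"PD"` and `"nonPD"`
#'   for two classes, `K1..Kc` otherwise. The first label is the positive
#'   class.
#' @param seed integer seed; every draw in [simulate_scores()] flows from it.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples, n_models = 4L, n_classes = 2L,
                              prevalence = 86 / 129,
                              model_accuracies = rep(0.93, n_models),
                              concentration = 10, class_labels = NULL,
                              seed = 1L) {
  n_samples <- as.integer(n_samples); n_models <- as.integer(n_models)
  n_classes <- as.integer(n_classes)
  if (is.na(n_samples) || n_samples < 1L) stop_usage("n_samples must be >= 1")
  if (is.na(n_models) || n_models < 1L) stop_usage("n_models must be >= 1")
  if (is.na(n_classes) || n_classes < 2L) stop_usage("n_classes must be >= 2")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_usage("prevalence must lie strictly inside (0, 1)")
  }
  if (length(model_accuracies) != n_models) {
    stop_usage("model_accuracies must have one entry per model")
  }
  if (any(model_accuracies <= 0.5) || any(model_accuracies > 1)) {
    stop_usage("model_accuracies must lie in (0.5, 1]")
  }
  if (!is.numeric(concentration) || concentration <= 0) {
    stop_usage("concentration must be > 0")
  }
  if (is.null(class_labels)) {
    class_labels <- if (n_classes == 2L) c("PD", "nonPD")
                    else paste0("K", seq_len(n_classes))
  }
  if (length(class_labels) != n_classes) {
    stop_usage("class_labels must have one entry per class")
  }
  structure(list(
    n_samples = n_samples, n_models = n_models, n_classes = n_classes,
    prevalence = prevalence, model_accuracies = as.numeric(model_accuracies),
    concentration = concentration, class_labels = as.character(class_labels),
    seed = as.integer(seed)), class = "simulation_config")
}

#' Simulate labelled confidence-score samples
#'
#' For each sample a true label is drawn with the configured prevalence. Each
#' model then independently favours the true class with its configured
#' accuracy, otherwise a wrong class chosen uniformly. The favoured class
#' receives confidence `0.5 + 0.5 * Beta(concentration, 1)` — always a strict
#' majority of the mass, so the favoured class is the model's argmax and the
#' realised per-model argmax accuracy matches the configured accuracy. The
#' remaining mass is split over the other classes by a symmetric Dirichlet
#' draw. Rows therefore always sum to one. Fully reproducible: the whole
#' dataset is a deterministic function of `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return list with `labels` (character vector, length `n_samples`) and
#'   `scores` (list of normalized [score_matrix()] objects, one per sample).
#' @examples
#' sim <- simulate_scores(simulation_config(5, seed = 42))
#' sim$labels
#' sim$scores[[1]]
#' @export
simulate_scores <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(cfg$seed)

  n <- cfg$n_samples; N <- cfg$n_models; C <- cfg$n_classes
  true_idx <- ifelse(stats::runif(n) < cfg$prevalence, 1L,
                     if (C == 2L) 2L else sample(2:C, n, replace = TRUE))
  model_ids <- paste0("M", seq_len(N))

  scores <- vector("list", n)
  for (s in seq_len(n)) {
    correct <- stats::runif(N) < cfg$model_accuracies
    favored <- ifelse(correct, true_idx[s],
                      vapply(seq_len(N), function(i) {
                        others <- setdiff(seq_len(C), true_idx[s])
                        if (length(others) == 1L) others
                        else sample(others, 1L)
                      }, integer(1L)))
    top <- 0.5 + 0.5 * stats::rbeta(N, cfg$concentration, 1)
    m <- matrix(0, N, C)
    for (i in seq_len(N)) {
      rest <- stats::rgamma(C - 1L, shape = 1)  # symmetric Dirichlet(1)
      rest <- rest / sum(rest) * (1 - top[i])
      m[i, favored[i]] <- top[i]
      m[i, -favored[i]] <- rest
    }
    scores[[s]] <- score_matrix(m, model_ids, cfg$class_labels)
  }
  list(labels = cfg$class_labels[true_idx], scores = scores)
}

#' Fuse simulated scores and evaluate with binary metrics
#'
#' Runs [simulate_scores()], fuses every sample with the named rule, and
#' evaluates the fused predictions against the simulated truth. Only defined
#' for binary configurations. Deterministic given the config seed.
#'
#' @param cfg a binary [simulation_config()].
#' @param rule fusion rule, see [fuse_scores()].
#' @param params a [fusion_params()] used by the `"frlf"` rule.
#' @return a [metric_report()] with the first class label as positive.
#' @export
simulate_confusion_profile <- function(cfg, rule = "frlf",
                                       params = fusion_params()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_classes != 2L) {
    stop_usage("binary metrics need a 2-class configuration")
  }
  sim <- simulate_scores(cfg)
  pred <- vapply(sim$scores, function(s) {
    fuse_scores(s, rule = rule, params = params)$predicted_label
  }, character(1L))
  metric_report(confusion(sim$labels, pred,
                          positive_label = cfg$class_labels[1L]))
}
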