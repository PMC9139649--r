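#' Confusion counts for binary classification
#'
#' Tallies true/false positives/negatives of predicted against true labels,
#' with one label designated the positive ("disease") class. Exactly two
#' distinct labels may occur across both vectors.
#'
#' @param y_true vector of true labels.
#' @param y_pred vector of predicted labels, same length.
#' @param positive_label the label counted as positive.
#' @return object of class `confusion_counts`: list with integer `tp`, `tn`,
#'   `fp`, `fn`, plus `positive_label` and `negative_label`.
#' @examples
#' confusion(c("PD", "PD", "HC"), c("PD", "HC", "HC"), positive_label = "PD")
#' @export
confusion <- function(y_true, y_pred, positive_label) {
  if (length(y_true) != length(y_pred)) {
    stop_data("y_true and y_pred lengths differ (",
              length(y_true), " vs ", length(y_pred), ")")
  }
  if (!length(y_true)) stop_data("no samples to evaluate")
  labs <- unique(c(as.character(y_true), as.character(y_pred)))
  if (!positive_label %in% labs) {
    stop_data("positive_label '", positive_label, "' absent from the labels")
  }
  if (length(labs) > 2L) {
    stop_data("binary metrics need at most two distinct labels, got: ",
              paste(labs, collapse = ", "))
  }
  negative_label <- setdiff(labs, positive_label)
  if (!length(negative_label)) negative_label <- NA_character_
  tpos <- as.character(y_true) == positive_label
  ppos <- as.character(y_pred) == positive_label
  structure(list(
    tp = sum(tpos & ppos), tn = sum(!tpos & !ppos),
    fp = sum(!tpos & ppos), fn = sum(tpos & !ppos),
    positive_label = positive_label, negative_label = negative_label
  ), class = "confusion_counts")
}

#' Assemble confusion counts directly
#'
#' @param tp,tn,fp,fn nonnegative integer counts.
#' @param positive_label label of the positive class (default `"PD"`).
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn, positive_label = "PD") {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_data("confusion counts must be nonnegative integers")
  }
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn),
                 positive_label = positive_label,
                 negative_label = NA_character_),
            class = "confusion_counts")
}

#' Recover integer confusion counts from printed sensitivity/specificity
#'
#' Published evaluations often report only sensitivity and specificity to two
#' decimals alongside the class sizes. Because `tp = sensitivity * n_pos` and
#' `tn = specificity * n_neg` must be integers, rounding recovers the exact
#' counts whenever the class sizes are small enough that no two counts round
#' to the same printed rate.
#'
#' @param sensitivity,specificity proportions in \[0, 1\] (pass 0.9419 for a
#'   printed 94.19 percent).
#' @param n_pos,n_neg positive/negative class sizes.
#' @param positive_label label of the positive class.
#' @return a `confusion_counts` object with
#'   `tp = round(sensitivity * n_pos)`, `fn = n_pos - tp`,
#'   `tn = round(specificity * n_neg)`, `fp = n_neg - tn`.
#' @examples
#' counts_from_rates(0.9419, 0.9069, n_pos = 86, n_neg = 43)
#' @export
counts_from_rates <- function(sensitivity, specificity, n_pos, n_neg,
                              positive_label = "PD") {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop_usage("sensitivity and specificity must be proportions in [0, 1]")
  }
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  confusion_counts(tp = tp, tn = tn, fp = n_neg - tn, fn = n_pos - tp,
                   positive_label = positive_label)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: positive = %s>\n", x$positive_label))
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(predicted = c("pos", "neg"),
                               actual = c("pos", "neg"))))
  invisible(x)
}

#' Binary diagnostic metric report
#'
#' Computes accuracy, precision, sensitivity (recall), specificity and
#' F1-score from confusion counts:
#' `Ac = (TP+TN)/(TP+TN+FP+FN)`, `Pr = TP/(TP+FP)`, `Sn = TP/(TP+FN)`,
#' `Sp = TN/(FP+TN)`, `F1 = 2*Pr*Sn/(Pr+Sn)`.
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' silently as 0: a table of zeros from an empty class is misleading, a
#' visible NA is not.
#'
#' @param counts a `confusion_counts` object.
#' @return object of class `metric_report`: list with `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1` as proportions (or `NA`), the source
#'   `counts`, and `percent`, the five values rendered as percentages rounded
#'   half-up to two decimals.
#' @examples
#' metric_report(confusion_counts(tp = 85, tn = 42, fp = 1, fn = 1))
#' @export
metric_report <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  total <- tp + tn + fp + fn
  if (total == 0) stop_data("no samples: all confusion counts are zero")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  pr <- safe_div(tp, tp + fp)
  sn <- safe_div(tp, tp + fn)
  f1 <- if (is.na(pr) || is.na(sn) || pr + sn == 0) NA_real_ else
    2 * pr * sn / (pr + sn)
  vals <- list(
    accuracy = (tp + tn) / total,
    precision = pr,
    sensitivity = sn,
    specificity = safe_div(tn, fp + tn),
    f1 = f1)
  structure(c(vals, list(
    percent = vapply(vals, percent2, numeric(1)),
    counts = counts)), class = "metric_report")
}

# Percentage rounded half-up to two decimals (printed tables convention).
# The tiny epsilon guards against binary representations like 98.4499999...
percent2 <- function(x) {
  if (is.na(x)) return(NA_real_)
  floor(100 * x * 100 + 0.5 + 1e-9) / 100
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>  (percent, two decimals; NA = undefined)\n")
  p <- x$percent
  for (nm in names(p)) {
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(p[[nm]])) "NA" else sprintf("%.2f%%", p[[nm]])))
  }
  invisible(x)
}

#' @export
as.data.frame.metric_report <- function(x, ...) {
  data.frame(metric = names(x$percent), percent = unname(x$percent),
             proportion = unname(unlist(x[names(x$percent)])))
}
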