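# The multi-model predictor: unweighted probability averaging over the
# per-family fine-tuned models, plus the evaluation metrics reported for
# methylation benchmarks (AUC, accuracy, F1, recall, AUPR).

#' Build an ensemble from fine-tuned members
#'
#' @param members named list of fine-tuned models (names are families);
#'   expected five, at least one required. All members must share the
#'   methylation type.
#' @param threshold decision threshold on the averaged probability
#'   (default 0.5; `p >= threshold` is called positive).
#' @return object of class `"methylm_ensemble"`.
#' @export
ensemble_model <- function(members, threshold = 0.5) {
  if (!length(members)) stop("ensemble needs at least one member",
                             call. = FALSE)
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0,1]", call. = FALSE)
  }
  types <- unique(vapply(members, function(m) m$methyl_type, character(1)))
  if (length(types) != 1L) {
    stop("ensemble members disagree on methylation type: ",
         paste(types, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(members))) {
    names(members) <- vapply(members, function(m) m$config$family,
                             character(1))
  }
  if (length(members) < 5L) {
    warning("ensemble has ", length(members),
            " member(s); averaging proceeds over the available members",
            call. = FALSE)
  }
  structure(list(members = members, methyl_type = types,
                 threshold = threshold),
            class = "methylm_ensemble")
}

#' @export
print.methylm_ensemble <- function(x, ...) {
  cat("<ensemble> ", x$methyl_type, ": ",
      paste(names(x$members), collapse = " + "),
      " (threshold ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Ensemble probability prediction
#'
#' Per sample, the unweighted arithmetic mean of the member positive-class
#' probabilities — no weighting, no re-normalization. A member failure is
#' an error naming the member.
#'
#' @param ensemble an [ensemble_model()].
#' @param samples a [methyl_dataset()].
#' @param max_len encoded length.
#' @return numeric vector of averaged probabilities.
#' @export
ensemble_predict <- function(ensemble, samples, max_len = 100L) {
  probs <- lapply(names(ensemble$members), function(nm) {
    p <- tryCatch(predict_proba(ensemble$members[[nm]], samples,
                                max_len = max_len),
                  error = function(e) {
                    stop("ensemble member '", nm, "' failed: ",
                         conditionMessage(e), call. = FALSE)
                  })
    p
  })
  rowMeans(do.call(cbind, probs))
}

#' Threshold probabilities into labels
#'
#' @param probabilities numeric vector in `[0,1]`.
#' @param threshold decision threshold; `p >= threshold` is positive.
#' @return character vector of `"positive"` / `"negative"`.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) {
    stop("threshold must be in [0,1]", call. = FALSE)
  }
  ifelse(probabilities >= threshold, "positive", "negative")
}

# Mann-Whitney AUC: probability that a random positive outscores a random
# negative, ties counted half.
auc_score <- function(scores, labels01) {
  n1 <- sum(labels01 == 1L)
  n0 <- sum(labels01 == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels01 == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Area under the precision-recall curve: step-wise integration over the
# ranked scores (average-precision convention; ties handled by processing
# equal scores as one threshold block).
aupr_score <- function(scores, labels01) {
  n1 <- sum(labels01 == 1L)
  if (n1 == 0L || all(labels01 == 1L)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels01[ord]
  area <- 0
  tp <- 0; fp <- 0
  prev_recall <- 0
  i <- 1L
  n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    tp <- tp + sum(y[i:j] == 1L)
    fp <- fp + sum(y[i:j] == 0L)
    recall <- tp / n1
    precision <- tp / (tp + fp)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
    i <- j + 1L
  }
  area
}

roc_points <- function(scores, labels01) {
  n1 <- sum(labels01 == 1L); n0 <- sum(labels01 == 0L)
  if (n1 == 0L || n0 == 0L) {
    return(data.frame(fpr = c(0, 1), tpr = c(0, 1)))
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels01[ord]; s <- scores[ord]
  keep <- c(diff(s) != 0, TRUE)
  tpr <- cumsum(y == 1L)[keep] / n1
  fpr <- cumsum(y == 0L)[keep] / n0
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Evaluate predictions against truth
#'
#' AUC is the Mann-Whitney statistic (ties count half); AUPR is the
#' step-wise area under the precision-recall curve; accuracy, F1 and recall
#' are computed at the decision threshold. With a one-class truth vector
#' AUC/AUPR are `NA` and the thresholded metrics are still computed.
#'
#' @param probabilities numeric scores in `[0,1]`.
#' @param labels truth, `"positive"`/`"negative"` (or 0/1, or logical).
#' @param threshold decision threshold (default 0.5).
#' @return object of class `"methylm_eval"`: list with `auc`, `accuracy`,
#'   `f1`, `recall`, `aupr`, `roc` (data.frame of fpr/tpr points, starting
#'   at (0,0) and ending at (1,1)) and `n_samples`.
#' @export
evaluate <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels differ in length", call. = FALSE)
  }
  y <- if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "positive")
  } else {
    as.integer(as.logical(as.numeric(labels)))
  }
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  acc <- mean(pred == y)
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else if (tp == 0 && (fp > 0 || fn > 0)) 0 else NA_real_
  structure(list(auc = auc_score(probabilities, y),
                 accuracy = acc, f1 = f1, recall = recall,
                 aupr = aupr_score(probabilities, y),
                 roc = roc_points(probabilities, y),
                 n_samples = length(y)),
            class = "methylm_eval")
}

#' @export
print.methylm_eval <- function(x, ...) {
  cat(sprintf(
    "<evaluation> n=%d  AUC %.4f  Accuracy %.4f  F1 %.4f  Recall %.4f  AUPR %.4f\n",
    x$n_samples, x$auc, x$accuracy, x$f1, x$recall, x$aupr))
  invisible(x)
}

#' Write predictions or an evaluation report
#'
#' @param ids sample ids.
#' @param probabilities predicted probabilities.
#' @param labels thresholded labels.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ids, probabilities, labels, path) {
  df <- data.frame(id = ids, probability = probabilities, label = labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param report a [evaluate()] result.
#' @rdname write_predictions
#' @export
write_roc_tsv <- function(report, path) {
  utils::write.table(report$roc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param path output path (`.json` writes JSON, otherwise TSV).
#' @rdname write_predictions
#' @export
write_eval_report <- function(report, path) {
  metrics <- report[c("auc", "accuracy", "f1", "recall", "aupr",
                      "n_samples")]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(metric = names(metrics),
                     value = unlist(metrics, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
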