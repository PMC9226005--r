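## Classification metrics (threshold and ranking based) and the
## stratified cross-validation helper.

#' Confusion-matrix metrics
#'
#' Standard precision, recall (sensitivity), specificity and F1 from
#' binary labels and binary predictions.  Undefined ratios (zero
#' denominators) are reported as `NA` with a warning, never silently 0.
#'
#' @param labels 0/1 truth vector
#' @param predictions 0/1 predicted labels, same length
#' @return list: precision, recall, specificity, f1, n_pos, n_neg
#' @examples
#' confusionMetrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusionMetrics <- function(labels, predictions) {
    if (length(labels) != length(predictions))
        stop("data error: labels and predictions differ in length")
    labels <- as.integer(labels); predictions <- as.integer(predictions)
    tp <- sum(labels == 1 & predictions == 1)
    fp <- sum(labels == 0 & predictions == 1)
    fn <- sum(labels == 1 & predictions == 0)
    tn <- sum(labels == 0 & predictions == 0)
    ratio <- function(num, den, what) {
        if (den == 0) {
            warning(what, " undefined (zero denominator)")
            return(NA_real_)
        }
        num / den
    }
    precision <- ratio(tp, tp + fp, "precision")
    recall <- ratio(tp, tp + fn, "recall")
    specificity <- ratio(tn, tn + fp, "specificity")
    f1 <- if (is.na(precision) || is.na(recall) ||
              precision + recall == 0) {
        if (!is.na(precision) && !is.na(recall))
            warning("f1 undefined (precision + recall = 0)")
        NA_real_
    } else 2 * precision * recall / (precision + recall)
    list(precision = precision, recall = recall,
         specificity = specificity, f1 = f1,
         n_pos = tp + fn, n_neg = tn + fp)
}

#' Threshold-free ranking metrics
#'
#' AUROC via the rank statistic (midranks for ties: equivalent to
#' (concordant + ties/2) / (n_pos * n_neg)), and AUPR by step-wise
#' summation of precision over recall increments with tied scores
#' processed as blocks.
#'
#' @param labels 0/1 truth vector (both classes required)
#' @param scores numeric scores, higher = more positive
#' @return list: auroc, aupr, n_pos, n_neg
#' @examples
#' rankingMetrics(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
rankingMetrics <- function(labels, scores) {
    if (length(labels) != length(scores))
        stop("data error: labels and scores differ in length")
    labels <- as.integer(labels)
    n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
    if (n_pos == 0 || n_neg == 0)
        stop("ranking metrics undefined: both classes must be present")
    r <- rank(scores)                   # midranks
    auroc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) /
        (n_pos * n_neg)
    ## AUPR: walk thresholds from the highest score down, tied scores as
    ## one block; precision at the block end weights the recall step.
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]; sc <- scores[ord]
    blocks <- cumsum(!duplicated(sc))
    tp <- 0; n_seen <- 0; prev_recall <- 0; aupr <- 0
    for (bl in unique(blocks)) {
        idx <- which(blocks == bl)
        tp <- tp + sum(lab[idx])
        n_seen <- n_seen + length(idx)
        precision <- tp / n_seen
        recall <- tp / n_pos
        aupr <- aupr + (recall - prev_recall) * precision
        prev_recall <- recall
    }
    list(auroc = auroc, aupr = aupr, n_pos = n_pos, n_neg = n_neg)
}

#' Full metric report for scored predictions
#'
#' @param labels 0/1 truth vector
#' @param scores predicted probabilities
#' @param threshold probability cut-off for the binary metrics
#' @return list combining [rankingMetrics()] and [confusionMetrics()]
#' @export
metricReport <- function(labels, scores, threshold = 0.5) {
    c(rankingMetrics(labels, scores),
      confusionMetrics(labels, as.integer(scores >= threshold))[
          c("precision", "recall", "specificity", "f1")])
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Folds are assigned per label class under a fixed seed; one model is
#' trained per fold on the remaining data and evaluated on the fold.
#'
#' @param pairs labelled pairs (small_rna_seq, site_seq, label)
#' @param config a [ModelConfig-class] used for every fold
#' @param folds number of folds (default 10)
#' @param epochs training epochs per fold (defaults to the config's)
#' @param seed fold-assignment seed
#' @return list with `per_fold` (data.frame of metrics per fold) and
#'   `mean` (column means)
#' @export
crossValidate <- function(pairs, config = ModelConfig(), folds = 10L,
                          epochs = NULL, seed = 1L) {
    n <- nrow(pairs)
    fold_of <- integer(n)
    with_seed(derive_seed(seed, "evaluate"), {
        for (lab in unique(pairs$label)) {
            idx <- which(pairs$label == lab)
            fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
    })
    rows <- vector("list", folds)
    for (f in seq_len(folds)) {
        train <- pairs[fold_of != f, , drop = FALSE]
        test <- pairs[fold_of == f, , drop = FALSE]
        net <- buildModel(config)
        net <- trainModel(net, train, epochs = epochs)
        pred <- predictPairs(net, test)
        m <- metricReport(test$label, pred$probability,
                          config@decision_threshold)
        rows[[f]] <- data.frame(fold = f, auroc = m$auroc, aupr = m$aupr,
                                f1 = m$f1, precision = m$precision,
                                recall = m$recall,
                                specificity = m$specificity)
    }
    per_fold <- do.call(rbind, rows)
    list(per_fold = per_fold,
         mean = colMeans(per_fold[, -1, drop = FALSE], na.rm = TRUE))
}
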