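# The evaluation suite: accuracy, precision, recall and the Matthews
# correlation coefficient (mcor), plus the inverse mapping from printed
# rates back to real-valued confusion counts for auditing reported tables.

#' Construct confusion counts
#'
#' @param tp,tn,fp,fn nonnegative counts; real values are allowed for
#'   rate-reconstruction audits.
#' @return a validated [ConfusionCounts-class].
#' @export
confusionCounts <- function(tp, tn, fp, fn) {
  new("ConfusionCounts", tp = as.numeric(tp), tn = as.numeric(tn),
      fp = as.numeric(fp), fn = as.numeric(fn))
}

#' Compute the metric suite from confusion counts
#'
#' \deqn{accuracy = (TP+TN)/N, \quad precision = TP/(TP+FP), \quad
#'       recall = TP/(TP+FN)}
#' \deqn{mcor = (TP \cdot TN - FP \cdot FN) /
#'       \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'
#' A zero denominator (precision, recall or any mcor factor) yields the
#' defined value 0 for that metric, with a diagnostic message, so batch
#' evaluation never aborts.
#'
#' @param counts a [ConfusionCounts-class].
#' @param loss optional mean cross-entropy to carry in the report.
#' @return a [MetricsReport-class].
#' @examples
#' computeMetrics(confusionCounts(40, 45, 5, 10))
#' @export
computeMetrics <- function(counts, loss = NA_real_) {
  stopifnot(is(counts, "ConfusionCounts"))
  validObject(counts)
  tp <- counts@tp; tn <- counts@tn; fp <- counts@fp; fn <- counts@fn
  n <- tp + tn + fp + fn
  safeRatio <- function(num, den, what) {
    if (den <= 0) {
      message(sprintf("%s has a zero denominator; reporting 0", what))
      0
    } else num / den
  }
  acc <- (tp + tn) / n
  prec <- safeRatio(tp, tp + fp, "precision")
  rec <- safeRatio(tp, tp + fn, "recall")
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcor <- if (den2 <= 0) {
    message("mcor has a zero denominator factor; reporting 0")
    0
  } else (tp * tn - fp * fn) / sqrt(den2)
  new("MetricsReport", accuracy = acc, precision = prec, recall = rec,
      mcor = mcor, loss = as.numeric(loss))
}

#' Reconstruct confusion counts from printed rates
#'
#' Inverts the metric formulas: with P = prevalence * N positives,
#' TP = recall * P, FP = TP (1 - precision)/precision, FN = P - TP and
#' TN = accuracy * N - TP. Used to audit the internal consistency of
#' published metric tables - feeding the reconstructed counts back through
#' [computeMetrics()] must reproduce the printed mcor.
#'
#' @param accuracy,recall,precision printed rates in (0, 1].
#' @param N evaluation-set size.
#' @param prevalence fraction of positive samples.
#' @return list with \code{counts} (real-valued
#'   [ConfusionCounts-class]) and \code{residual}, the consistency gap
#'   \code{|TP+TN+FP+FN - N|}.
#' @examples
#' a <- confusionFromRates(0.9795, 0.9844, 0.9747, N = 1695,
#'                         prevalence = 0.495)
#' computeMetrics(a$counts)
#' @export
confusionFromRates <- function(accuracy, recall, precision, N, prevalence) {
  rates <- c(accuracy = accuracy, recall = recall, precision = precision)
  if (any(rates <= 0) || any(rates > 1))
    stop("accuracy, recall and precision must lie in (0, 1]")
  if (N <= 0 || prevalence <= 0) stop("N and prevalence must be > 0")
  P <- prevalence * N
  tp <- recall * P
  fp <- tp * (1 - precision) / precision
  fn <- P - tp
  tn <- accuracy * N - tp
  v <- c(TP = tp, FP = fp, FN = fn, TN = tn)
  if (any(v < -1e-9))
    stop(sprintf("rates are inconsistent: reconstructed %s is negative (%g)",
                 names(v)[which.min(v)], min(v)))
  list(counts = confusionCounts(tp, tn, fp, fn),
       residual = abs(tp + tn + fp + fn - N))
}

#' Evaluate a trained model on a test partition
#'
#' Argmax predictions against labels give integer confusion counts
#' (positive class = seizure = 1); the report carries the mean softmax
#' cross-entropy over the partition.
#'
#' @param model a trained [SeizureModel-class].
#' @param dataset a [TFImageSet-class].
#' @param idx indices of the evaluation images (e.g.
#'   \code{testIdx(split)}).
#' @return list with \code{counts} ([ConfusionCounts-class]) and
#'   \code{report} ([MetricsReport-class]).
#' @export
evaluateModel <- function(model, dataset, idx) {
  stopifnot(is(dataset, "TFImageSet"))
  if (!length(idx)) stop("empty evaluation set")
  P <- predictModel(model, dataset, idx)
  y <- imageLabels(dataset)[idx]
  pred <- max.col(P) - 1L
  counts <- confusionCounts(sum(pred == 1L & y == 1L),
                            sum(pred == 0L & y == 0L),
                            sum(pred == 1L & y == 0L),
                            sum(pred == 0L & y == 1L))
  list(counts = counts,
       report = computeMetrics(counts, loss = meanCrossEntropy(P, y)))
}

#' Repeated shuffled train/evaluate runs
#'
#' The pooled protocol draws the test set at random, so single-run metrics
#' are themselves random; this repeats the split/train/evaluate cycle k
#' times and reports per-run metrics plus their arithmetic mean (the mean
#' of metrics, not the metrics of pooled counts).
#'
#' @param dataset a [TFImageSet-class].
#' @param spec a [ModelSpec-class].
#' @param config a [TrainConfig-class]; each run r uses seed
#'   \code{config@seed + r} for the split, weights and shuffling.
#' @param k number of repetitions.
#' @return list with \code{perRun} (list of [MetricsReport-class]) and
#'   \code{mean} (named numeric vector of averaged metrics).
#' @export
evaluateRepeated <- function(dataset, spec, config = trainConfig(),
                             k = 10) {
  runs <- vector("list", k)
  for (r in seq_len(k)) {
    seedR <- config@seed + r
    sp <- splitDataset(dataset, seed = seedR)
    cfgR <- config; cfgR@seed <- as.integer(seedR)
    fit <- trainModel(buildModel(spec, seed = seedR), dataset, sp, cfgR)
    runs[[r]] <- evaluateModel(fit$model, dataset, testIdx(sp))$report
  }
  pull <- function(f) vapply(runs, function(r) slot(r, f), 0)
  list(perRun = runs,
       mean = c(accuracy = mean(pull("accuracy")),
                recall = mean(pull("recall")),
                precision = mean(pull("precision")),
                mcor = mean(pull("mcor")),
                loss = mean(pull("loss"))))
}

#' Write a metrics report as JSON / a results table as CSV
#'
#' \code{writeMetricsJSON} serializes one report;
#' \code{writeMetricsTableCSV} writes rows shaped like a published results
#' table (columns model, fc_size, loss, accuracy, recall, precision,
#' mcor).
#'
#' @param report a [MetricsReport-class].
#' @param path output path.
#' @export
writeMetricsJSON <- function(report, path) {
  jsonlite::write_json(
    list(accuracy = report@accuracy, recall = report@recall,
         precision = report@precision, mcor = report@mcor,
         loss = report@loss),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeMetricsJSON
#' @param rows data.frame with columns \code{model}, \code{fc_size},
#'   \code{loss}, \code{accuracy}, \code{recall}, \code{precision},
#'   \code{mcor}.
#' @export
writeMetricsTableCSV <- function(rows, path) {
  needed <- c("model", "fc_size", "loss", "accuracy", "recall",
              "precision", "mcor")
  stopifnot(all(needed %in% names(rows)))
  utils::write.csv(rows[needed], path, row.names = FALSE)
  invisible(path)
}
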