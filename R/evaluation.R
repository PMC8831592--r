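## Ground-truth labeling (modified-response grade), cohort splitting,
## classification metrics in the non-responder-positive convention,
## Kaplan-Meier / log-rank survival comparison.

#' Modified-response (MR) grading
#'
#' Grades post-treatment response from the tumor-size reduction
#' r = (initial - residual)/initial and histopathological cellularity:
#' MR1 no reduction (r <= 0); MR2 0 < r < 30%; MR3 30--90% reduction or a
#' very low residual cellularity; MR4 > 90% reduction with residual
#' malignant cells; MR5 no malignant cells identifiable. Patients with
#' MR 1--2 are non-responders; MR 3--5 are responders.
#'
#' @param initialSize,residualSize tumor sizes (cm), >= 0
#' @param veryLowCellularity histopathological very-low residual cellularity
#' @param noMalignantCells no identifiable malignant cells
#' @return list(score, label)
#' @export
mrGrade <- function(initialSize, residualSize, veryLowCellularity = FALSE,
                    noMalignantCells = FALSE) {
  if (initialSize < 0 || residualSize < 0) stop("sizes must be >= 0")
  if (initialSize == 0 && !noMalignantCells)
    stop("initialSize must be > 0 unless noMalignantCells")
  score <- if (noMalignantCells) 5L else {
    r <- (initialSize - residualSize) / initialSize
    if (r > 0.9) 4L
    else if (veryLowCellularity || r >= 0.3) 3L
    else if (r > 0) 2L
    else 1L
  }
  list(score = score,
       label = if (score >= 3L) "responder" else "non-responder")
}

#' Stratified train/validation/test split
#'
#' Test patients are drawn per class with largest-remainder proportional
#' allocation (preserving class proportions within rounding), then the
#' validation set is drawn the same way from the remaining training pool.
#' Reproducible from `seed`.
#'
#' @param labels patient labels, or a [SyntheticCohort-class]
#' @param testFraction fraction held out as the independent test set
#' @param valFraction fraction of the remaining training pool used for
#'   validation
#' @param seed integer
#' @param nTest optional exact test-set size overriding `testFraction`
#' @return list(train, val, test) of integer indices (disjoint, exhaustive).
#' @export
stratifiedSplit <- function(labels, testFraction = 0.30, valFraction = 0.25,
                            seed = 1L, nTest = NULL) {
  if (is(labels, "SyntheticCohort")) labels <- cohortLabels(labels)
  labels <- assertLabels(labels)
  classes <- unique(labels)
  if (any(table(labels) < 2L)) stop("each class needs >= 2 members")
  n <- length(labels)
  if (is.null(nTest)) nTest <- round(testFraction * n)
  withr::with_seed(seed, {
    testIdx <- integer(0)
    perClassTest <- largestRemainder(table(labels)[classes], nTest)
    for (i in seq_along(classes)) {
      pool <- which(labels == classes[i])
      testIdx <- c(testIdx, sample(pool, perClassTest[i]))
    }
    rest <- setdiff(seq_len(n), testIdx)
    nVal <- round(valFraction * length(rest))
    perClassVal <- largestRemainder(table(labels[rest])[classes], nVal)
    valIdx <- integer(0)
    for (i in seq_along(classes)) {
      pool <- rest[labels[rest] == classes[i]]
      valIdx <- c(valIdx, sample(pool, perClassVal[i]))
    }
    list(train = sort(setdiff(rest, valIdx)), val = sort(valIdx),
         test = sort(testIdx))
  })
}

#' Classification metrics, non-responder-positive convention
#'
#' Sensitivity is the fraction of non-responders predicted non-responder;
#' specificity is the fraction of responders predicted responder; accuracy
#' is over all patients; AUC ranks patients by the predicted non-responder
#' probability (trapezoidal/midrank, via pROC). When one class is absent
#' the affected metrics are returned as NA with a warning.
#'
#' @param predictions data.frame with columns `predictedLabel` and
#'   (for AUC) `pNonResponder`, e.g. from [predictCohortFeatures()]
#' @param labels true labels
#' @return list(accuracy, sensitivity, specificity, auc, counts)
#' @export
computeMetrics <- function(predictions, labels) {
  labels <- assertLabels(labels)
  pred <- assertLabels(predictions$predictedLabel)
  if (length(pred) != length(labels) || length(pred) == 0L)
    stop("predictions and labels must be non-empty and matched")
  isNR <- labels == "non-responder"
  sens <- if (any(isNR)) mean(pred[isNR] == "non-responder") else {
    warning("no non-responders: sensitivity undefined"); NA_real_
  }
  spec <- if (any(!isNR)) mean(pred[!isNR] == "responder") else {
    warning("no responders: specificity undefined"); NA_real_
  }
  auc <- NA_real_
  if (!is.null(predictions$pNonResponder) && any(isNR) && any(!isNR)) {
    roc <- pROC::roc(response = factor(labels, levels = responseLevels),
                     predictor = predictions$pNonResponder,
                     levels = responseLevels, direction = "<",
                     quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
  }
  list(accuracy = mean(pred == labels), sensitivity = sens,
       specificity = spec, auc = auc,
       counts = c(responders = sum(!isNR), nonResponders = sum(isNR)))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring
#' (via `survival::survfit`): right-continuous, non-increasing, starting
#' at 1.
#'
#' @param records data.frame with columns `time` (months, > 0) and
#'   `event` (logical)
#' @return data.frame(time, surv, nRisk, nEvent) step function.
#' @export
kmCurve <- function(records) {
  if (nrow(records) < 1L) stop("need >= 1 record")
  if (any(records$time <= 0)) stop("times must be > 0")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  data.frame(time = fit$time, surv = fit$surv, nRisk = fit$n.risk,
             nEvent = fit$n.event)
}

#' Log-rank test between two survival groups
#'
#' One-degree-of-freedom log-rank statistic (observed vs expected events
#' under the pooled hypergeometric risk-set model, via
#' `survival::survdiff`) with the asymptotic chi-square(1) p-value.
#'
#' @param groupA,groupB data.frames with `time` and `event` columns
#' @return list(chisq, p)
#' @export
logRank <- function(groupA, groupB) {
  if (nrow(groupA) == 0L || nrow(groupB) == 0L)
    stop("both groups must be non-empty")
  df <- rbind(data.frame(time = groupA$time, event = groupA$event, g = "A"),
              data.frame(time = groupB$time, event = groupB$event, g = "B"))
  if (any(df$time <= 0)) stop("times must be > 0")
  if (sum(df$event) == 0L) {
    warning("no events: log-rank statistic undefined")
    return(list(chisq = NA_real_, p = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
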