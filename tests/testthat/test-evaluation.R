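test_that("MR grading follows the size-reduction and cellularity rules", {
  expect_equal(mrGrade(5, 5), list(score = 1L, label = "non-responder"))
  expect_equal(mrGrade(5, 4), list(score = 2L, label = "non-responder"))
  expect_equal(mrGrade(5, 3)$score, 3L)       # 40% reduction
  expect_equal(mrGrade(5, 3)$label, "responder")
  expect_equal(mrGrade(5, 0.3), list(score = 4L, label = "responder"))
  expect_equal(mrGrade(5, 6)$score, 1L)       # growth is MR1
  expect_equal(mrGrade(5, 4.5, veryLowCellularity = TRUE)$score, 3L)
  expect_equal(mrGrade(5, 0, noMalignantCells = TRUE)$score, 5L)
  expect_error(mrGrade(-1, 0), ">= 0")
  expect_error(mrGrade(0, 0), "noMalignantCells")
})

test_that("stratified splits preserve proportions and reproduce from seed", {
  labels <- rep(c("responder", "non-responder"), c(138, 43))
  sp <- stratifiedSplit(labels, 0.30, 0.25, seed = 4, nTest = 50)
  expect_length(sp$test, 50)
  expect_equal(sum(labels[sp$test] == "responder"), 38)  # 138/181 of 50
  expect_setequal(c(sp$train, sp$val, sp$test), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_length(intersect(sp$val, sp$test), 0)
  # class proportions preserved within rounding in every part
  for (part in sp) {
    frac <- mean(labels[part] == "responder")
    expect_lt(abs(frac - 138 / 181), 0.03)
  }
  sp2 <- stratifiedSplit(labels, 0.30, 0.25, seed = 4, nTest = 50)
  expect_identical(sp, sp2)
  expect_error(stratifiedSplit(c("responder", "responder", "non-responder")),
               ">= 2")
})

test_that("metrics follow the non-responder-positive convention", {
  mkPred <- function(lab, p) data.frame(predictedLabel = lab,
                                        pNonResponder = p)
  # printed test composition: 40 responders, 10 non-responders
  labels <- rep(c("responder", "non-responder"), c(40, 10))
  correctR <- 37; correctN <- 7    # 92.5% / 70%
  pred <- c(rep("responder", correctR), rep("non-responder", 40 - correctR),
            rep("non-responder", correctN), rep("responder", 10 - correctN))
  m <- computeMetrics(mkPred(pred, as.numeric(pred == "non-responder")),
                      labels)
  expect_equal(m$accuracy, 0.88)
  expect_equal(m$sensitivity, 0.7)
  expect_equal(m$specificity, 0.925)
  # accuracy identity: acc = (spec*nR + sens*nN)/n
  withr::with_seed(17, for (i in 1:10) {
    pr <- sample(c("responder", "non-responder"), 50, replace = TRUE)
    mm <- computeMetrics(mkPred(pr, stats::runif(50)), labels)
    expect_equal(mm$accuracy,
                 (mm$specificity * 40 + mm$sensitivity * 10) / 50)
  })
  # perfect predictions
  mp <- computeMetrics(mkPred(labels, as.numeric(labels == "non-responder")),
                       labels)
  expect_equal(c(mp$accuracy, mp$sensitivity, mp$specificity, mp$auc),
               c(1, 1, 1, 1))
  # degenerate all-responder classifier
  md <- computeMetrics(mkPred(rep("responder", 50), rep(0.1, 50)), labels)
  expect_equal(c(md$accuracy, md$sensitivity, md$specificity),
               c(0.8, 0, 1))
  expect_warning(
    computeMetrics(mkPred(rep("responder", 5), stats::runif(5)),
                   rep("responder", 5)),
    "sensitivity")
})

test_that("AUC equals the rank-sum (midrank) oracle", {
  withr::with_seed(18, {
    labels <- sample(rep(c("responder", "non-responder"), c(30, 12)))
    score <- round(stats::runif(42), 1)  # forces ties
  })
  m <- computeMetrics(data.frame(predictedLabel = labels,
                                 pNonResponder = score), labels)
  isN <- labels == "non-responder"
  r <- rank(score)
  aucOracle <- (sum(r[isN]) - sum(isN) * (sum(isN) + 1) / 2) /
    (sum(isN) * sum(!isN))
  expect_equal(m$auc, aucOracle, tolerance = 1e-10)
})

test_that("Kaplan-Meier estimate matches the product-limit formula", {
  rec <- withr::with_seed(19, simulateSurvivalRecords(20, 0.02, 100))
  km <- kmCurve(rec)
  # brute-force product over distinct event times
  ts <- sort(unique(rec$time[rec$event]))
  surv <- vapply(ts, function(t) {
    prod(vapply(ts[ts <= t], function(u) {
      atRisk <- sum(rec$time >= u)
      (atRisk - sum(rec$time == u & rec$event)) / atRisk
    }, numeric(1)))
  }, numeric(1))
  expect_equal(km$surv[km$nEvent > 0], surv, tolerance = 1e-12)
  expect_true(all(diff(km$surv) <= 1e-12))
  # no events: flat at 1
  censored <- data.frame(time = 1:5, event = rep(FALSE, 5))
  expect_true(all(kmCurve(censored)$surv == 1))
  # single event among n drops to (n-1)/n
  one <- data.frame(time = c(2, 3, 4, 5), event = c(TRUE, FALSE, FALSE,
                                                    FALSE))
  expect_equal(kmCurve(one)$surv[1], 3 / 4)
  expect_error(kmCurve(data.frame(time = c(0, 1), event = c(TRUE, TRUE))),
               "> 0")
})

test_that("log-rank statistic is zero for identical groups", {
  rec <- withr::with_seed(20, simulateSurvivalRecords(15, 0.03, 100))
  lr <- logRank(rec, rec)
  expect_equal(lr$chisq, 0, tolerance = 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-6)
  noEvents <- data.frame(time = 1:4, event = rep(FALSE, 4))
  expect_warning(out <- logRank(noEvents, noEvents), "no events")
  expect_true(is.na(out$p))
})

test_that("log-rank power is high for a hazard ratio of 3", {
  rejections <- withr::with_seed(22, vapply(seq_len(500), function(i) {
    a <- simulateSurvivalRecords(25, 0.02, 120, "A")
    b <- simulateSurvivalRecords(25, 0.06, 120, "B")
    logRank(a, b)$p < 0.05
  }, logical(1)))
  expect_gt(mean(rejections), 0.8)
})
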