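test_that("confusion metrics reproduce direct formula evaluation", {
  # constructed confusion matrix: TP=16 FP=3 FN=12 TN=266
  labels <- c(rep(1, 28), rep(0, 269))
  scores <- c(rep(0.9, 16), rep(0.1, 12), rep(0.9, 3), rep(0.1, 266))
  m <- confusion_and_metrics(labels, scores, 0.5)
  expect_equal(c(m$TP, m$FP, m$FN, m$TN), c(16, 3, 12, 266))
  expect_equal(m$Pre, 16 / 19, tolerance = 1e-12)
  expect_equal(m$Rec, 16 / 28, tolerance = 1e-12)
  expect_equal(m$ACC, 282 / 297, tolerance = 1e-12)
  # perfect predictor
  p <- confusion_and_metrics(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8), 0.5)
  expect_equal(c(p$ACC, p$Pre, p$Rec, p$Spe, p$F1, p$MCC), rep(1, 6))
  # balanced coin: MCC = 0
  b <- confusion_and_metrics(c(1, 1, 0, 0), c(0.9, 0.1, 0.9, 0.1), 0.5)
  expect_equal(b$MCC, 0)
})

test_that("metrics match an independent recomputation on random instances", {
  naive <- function(y, s, t) {
    pred <- ifelse(s >= t, 1, 0)
    tp <- sum(y & pred); tn <- sum(!y & !pred)
    fp <- sum(!y & pred); fn <- sum(y & !pred)
    den <- function(x) if (x == 0) NA else x
    list(ACC = (tp + tn) / length(y),
         Pre = tp / den(tp + fp), Rec = tp / den(tp + fn),
         Spe = tn / den(tn + fp),
         MCC = (tp * tn - fn * fp) /
           den(sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)))
  }
  set.seed(41)
  for (r in 1:300) {
    n <- sample(5:60, 1)
    y <- rbinom(n, 1, 0.3)
    s <- round(runif(n), 2)
    t <- runif(1)
    m <- confusion_and_metrics(y, s, t)
    o <- naive(y, s, t)
    for (k in names(o)) {
      if (is.na(o[[k]])) {
        expect_true(k %in% m$degenerate)
        expect_equal(m[[k]], 0)
      } else {
        expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
      }
    }
  }
})

test_that("MCC survives label-convention swap with score reflection", {
  set.seed(42)
  y <- rbinom(80, 1, 0.25)
  s <- runif(80)
  t <- 0.4
  m1 <- confusion_and_metrics(y, s, t)
  # swapped convention: positives<->negatives, scores reflected; calls flip
  # when the reflected threshold is adjusted to keep the same partition
  m2 <- confusion_and_metrics(1 - y, 1 - s + 1e-9, 1 - t)
  expect_equal(m2$MCC, m1$MCC, tolerance = 1e-9)
})

test_that("ROC AUC equals brute-force concordant pair counting", {
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0, 1, 0, 1)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  brute <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(43)
  for (r in 1:40) {
    n <- 50
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(runif(n), 1)  # coarse scores force ties
    expect_equal(roc_auc(y, s), brute(y, s), tolerance = 1e-9)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "one class")
})

test_that("PR AUC is 1 for perfect scores and >= prevalence behaviour holds", {
  expect_equal(pr_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8)), 1)
  set.seed(44)
  # perfect ordering: AUPRC is 1 >= prevalence
  y <- rbinom(200, 1, 0.2)
  expect_gte(pr_auc(y, y * 0.5 + 0.25), mean(y))
  # random scores: AUPRC close to prevalence in expectation (the step
  # estimator's finite-sample bias is O(1/n), so n = 500 keeps it small)
  vals <- replicate(200, {
    y <- rbinom(500, 1, 0.3)
    while (length(unique(y)) < 2) y <- rbinom(500, 1, 0.3)
    pr_auc(y, runif(500))
  })
  expect_equal(mean(vals), 0.3, tolerance = 0.03)
})

test_that("max-MCC threshold scanning matches a dense-grid oracle", {
  r <- optimal_threshold_by_mcc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$threshold, 0.5)
  expect_equal(r$mcc, 1)
  # perfect anti-predictor: no threshold beats MCC 0
  anti <- optimal_threshold_by_mcc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))
  expect_lte(anti$mcc, 0)
  set.seed(45)
  for (rep in 1:20) {
    y <- rbinom(40, 1, 0.3)
    if (length(unique(y)) < 2) next
    s <- runif(40)
    got <- optimal_threshold_by_mcc(y, s)
    grid <- seq(0, 1, length.out = 10000)
    grid_best <- max(vapply(grid, function(t)
      confusion_and_metrics(y, s, t)$MCC, 0))
    expect_equal(got$mcc, grid_best, tolerance = 1e-12)
  }
})

test_that("nonlocal contact counts obey geometry and match a double loop", {
  # straight chain: any pair with separation > 20 is >= 79.8 A apart
  X <- cbind(seq(0, by = 3.8, length.out = 50), 0, 0)
  expect_equal(nonlocal_contact_counts(X), rep(0L, 50))
  # boundary: exactly 12.0 A at separation 25 is NOT counted (strict <);
  # intermediate residues sit far away so only the end pair could count
  cnt <- nonlocal_contact_counts(rbind(c(0, 0, 0), matrix(1e3 + rnorm(72), 24, 3),
                                       c(12, 0, 0)))
  expect_equal(cnt[1], 0L)
  expect_equal(cnt[26], 0L)
  # brute-force oracle on compact clusters
  set.seed(46)
  for (r in 1:10) {
    n <- 60
    X <- matrix(rnorm(n * 3) * 6, n, 3)
    got <- nonlocal_contact_counts(X)
    bf <- integer(n)
    for (i in 1:n) for (j in 1:n) {
      if (abs(i - j) > 20 && sqrt(sum((X[i, ] - X[j, ])^2)) < 12)
        bf[i] <- bf[i] + 1L
    }
    expect_identical(got, bf)
    # symmetry: total count is even
    expect_equal(sum(got) %% 2, 0)
  }
})

test_that("stratified metrics partition residues and match per-subset runs", {
  set.seed(47)
  n <- 200
  y <- rbinom(n, 1, 0.25)
  s <- runif(n)
  counts <- sample(0:30, n, replace = TRUE)
  st <- stratified_metrics(y, s, counts, threshold = 0.5)
  expect_equal(sum(st$n), n)
  for (b in 1:3) {
    idx <- switch(b, counts <= 9, counts >= 10 & counts <= 19, counts >= 20)
    m <- confusion_and_metrics(y[idx], s[idx], 0.5)
    expect_equal(st$MCC[b], m$MCC, tolerance = 1e-12)
  }
  # all counts zero: upper bins flagged empty
  st0 <- stratified_metrics(y, s, rep(0L, n), threshold = 0.5)
  expect_equal(st0$flag, c("", "empty", "empty"))
  expect_equal(st0$n, c(n, 0L, 0L))
  expect_error(stratified_metrics(y, s, counts, 0.5,
                                  bins = data.frame(lo = c(0, 12), hi = c(9, Inf))),
               "partition")
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(48)
  y <- rbinom(120, 1, 0.3)
  s <- runif(120)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})
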