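# dysglycemia labelling, paired change tests, predictor comparison, ROC/AUC

test_that("dysglycemia labels use strict thresholds", {
  expect_false(label_dysglycemia(95, 120))
  expect_false(label_dysglycemia(100, 140))   # exactly at threshold: not dysglycemic
  expect_true(label_dysglycemia(101, 120))
  expect_true(label_dysglycemia(95, 141))
  expect_equal(label_dysglycemia(c(95, 100, 101, 95), c(120, 140, 120, 141)),
               c(FALSE, FALSE, TRUE, TRUE))
  expect_true(is.na(label_dysglycemia(NA, 120)))
})

test_that("paired tests handle the no-change degenerate case", {
  b <- data.frame(fpg = c(83, 85, 90, 88), hba1c = c(5.1, 5.2, 5.3, 5.4))
  out <- paired_change_tests(b, b)
  expect_equal(out$statistic, c(0, 0))
  expect_equal(out$p, c(1, 1))
})

test_that("a constant +1 shift in FPG is detected by the signed-rank test", {
  set.seed(4)
  b <- data.frame(fpg = rnorm(50, 85, 6))
  f <- data.frame(fpg = b$fpg + 1)
  out <- paired_change_tests(b, f)
  expect_lt(out$p, 0.001)
})

test_that("McNemar on balanced discordance gives p = 1 exactly", {
  # 10 newly dysglycemic vs 10 reverted
  before <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 4), rep(FALSE, 150))
  after <- c(rep(FALSE, 10), rep(TRUE, 10), rep(TRUE, 4), rep(FALSE, 150))
  out <- paired_change_tests(data.frame(x = rnorm(174)),
                             data.frame(x = rnorm(174)),
                             dysglycemia = data.frame(b = before, f = after))
  expect_equal(out$p[out$variable == "dysglycemia"], 1)
  # asymmetric discordance is detected
  b2 <- rep(c(TRUE, FALSE), c(2, 38)); f2 <- rep(c(TRUE, FALSE), c(22, 18))
  f2[1:2] <- TRUE
  out2 <- paired_change_tests(data.frame(x = rnorm(40)), data.frame(x = rnorm(40)),
                              dysglycemia = data.frame(b = b2, f = f2))
  expect_lt(out2$p[out2$variable == "dysglycemia"], 0.001)
})

test_that("AUC equals the all-pairs concordance oracle with ties counted 1/2", {
  concordance_oracle <- function(s, y) {
    pos <- s[y]; neg <- s[!y]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(14)
  for (r in 1:20) {
    n <- sample(10:200, 1)
    y <- runif(n) < 0.3
    if (!any(y) || all(y)) next
    s <- sample(round(rnorm(n), sample(0:2, 1)))   # coarse rounding forces ties
    expect_equal(roc_auc(s, y)$auc, concordance_oracle(s, y), tolerance = 1e-12)
  }
  # enumerated toy case: 3 of 4 pos/neg pairs concordant
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auc, 0.75)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  s <- rnorm(150); y <- runif(150) < 0.4
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0, tolerance = 1e-12)
  expect_equal(roc_auc(qnorm(pnorm(s))^3 + 2 * s, y)$auc, a0, tolerance = 1e-12)
})

test_that("degenerate scores: perfect separation gives 1, all-ties give exactly 0.5", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(c(FALSE, TRUE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both outcome classes")
})

test_that("the ROC staircase is monotone from (0,0) to (1,1)", {
  set.seed(19)
  r <- roc_auc(rnorm(80), runif(80) < 0.25)$roc
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[nrow(r)], r$tpr[nrow(r)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
})

test_that("labels independent of all features give null AUCs near 0.5", {
  set.seed(23)
  n <- 2000
  d <- data.frame(fpg = rnorm(n, 85, 6), pg2h = rnorm(n, 100, 15),
                  hba1c = rnorm(n, 5.2, 0.3),
                  shape = sample(c("biphasic", "monophasic",
                                   "monotonically_increasing"), n, TRUE),
                  matrix(rnorm(n * 6), n,
                         dimnames = list(NULL, c(paste0("g_z", 1:3, "_std"),
                                                 paste0("i_z", 1:3, "_std")))),
                  outcome = runif(n) < 0.5)
  fits <- fit_predictor_models(d)
  expect_equal(nrow(fits$summary), 7L)
  # single-variable fits carry no multi-dimensional optimism
  single <- fits$summary$predictor %in% c("FPG", "2hrPG", "HbA1c")
  expect_true(all(abs(fits$summary$auc[single] - 0.5) < 0.03))
  # multi-variable in-sample fits are optimistic by a known amount under the
  # null: E[AUC] ~ pnorm(sqrt(k (1/n1 + 1/n0)) / sqrt(2)) for k predictors
  k <- c(FPG = 1, `2hrPG` = 1, HbA1c = 1, shape = 2, `glucose FPCs` = 3,
         `insulin FPCs` = 3, `glucose+insulin FPCs` = 6)
  n1 <- sum(d$outcome); n0 <- n - n1
  expected <- pnorm(sqrt(k[fits$summary$predictor] * (1 / n1 + 1 / n0)) / sqrt(2))
  expect_true(all(abs(fits$summary$auc - expected) < 0.03))
})

test_that("a feature equal to the true log-odds approaches the generator Bayes AUC", {
  set.seed(27)
  n <- 4000
  eta <- -2.5 + 1.2 * rnorm(n)
  y <- runif(n) < plogis(eta)
  stopifnot(any(y), !all(y))
  auc_fit <- fit_predictor_models(
    data.frame(fpg = eta, pg2h = rnorm(n), hba1c = rnorm(n),
               shape = "monophasic",
               matrix(rnorm(n * 6), n,
                      dimnames = list(NULL, c(paste0("g_z", 1:3, "_std"),
                                              paste0("i_z", 1:3, "_std")))),
               outcome = y))$summary
  auc_eta <- auc_fit$auc[auc_fit$predictor == "FPG"]
  # numerically integrated true AUC: P(eta_pos > eta_neg) under the model
  M <- 200000
  eta2 <- -2.5 + 1.2 * rnorm(M)
  p <- plogis(eta2)
  w_pos <- p / sum(p); w_neg <- (1 - p) / sum(1 - p)
  ord <- order(eta2)
  bayes <- sum(w_pos[ord] * cumsum(w_neg[ord])) # P(pos>neg), ties negligible
  expect_lt(abs(auc_eta - bayes), 0.03)
})

test_that("complete separation is flagged but the AUC is still reported", {
  set.seed(31)
  n <- 60
  y <- rep(c(FALSE, TRUE), c(45, 15))
  d <- data.frame(fpg = ifelse(y, 110, 90) + rnorm(n, 0, 1),
                  pg2h = rnorm(n, 100, 10), hba1c = rnorm(n, 5.2, 0.2),
                  shape = "monophasic",
                  matrix(rnorm(n * 6), n,
                         dimnames = list(NULL, c(paste0("g_z", 1:3, "_std"),
                                                 paste0("i_z", 1:3, "_std")))),
                  outcome = y)
  fits <- fit_predictor_models(d)
  expect_true(fits$fits$FPG$separation)
  expect_equal(fits$fits$FPG$auc, 1)
})
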