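test_that("regression metrics match identity, anti-identity and a hand oracle", {
  y <- c(-2, -1, 0, 1, 2)
  r <- regression_metrics(y, y)
  expect_equal(r$pearson, 1)
  expect_equal(r$mse, 0)
  expect_equal(r$kendall_tau, 1)
  expect_equal(r$spearman_rho, 1)
  expect_equal(regression_metrics(y, -y)$pearson, -1)

  # 6-point fixture, expected values computed from the textbook formulas
  yt <- c(1, 2, 3, 4, 5, 6)
  yp <- c(2, 1, 4, 3, 6, 5)
  r2 <- regression_metrics(yt, yp)
  expect_equal(r2$pearson, 29 / 35)
  expect_equal(r2$mse, 1)
  expect_equal(r2$kendall_tau, 0.6)
  expect_equal(r2$spearman_rho, 29 / 35)

  expect_error(regression_metrics(rep(1, 5), y), class = "gs_degenerate_error")
  expect_error(regression_metrics(1:2, 1:2), class = "gs_config_error")
})

test_that("neutral-band classification treats boundaries as neutral", {
  expect_equal(as.character(classify_by_regression(0.35, -0.35, 0.35)), "neutral")
  expect_equal(as.character(classify_by_regression(0.351, -0.35, 0.35)), "stabilizing")
  expect_equal(as.character(classify_by_regression(-5, -4.9, 4.9)), "destabilizing")
  # degenerate band = sign classification with 0 neutral
  v <- c(-1, 0, 2)
  expect_equal(as.character(classify_by_regression(v, 0, 0)),
               c("destabilizing", "neutral", "stabilizing"))
})

test_that("binary rule maps negatives and zero to 0, positives to 1", {
  expect_equal(binary_stabilizing(c(-0.1, 0.2, 3)), c(0L, 1L, 1L))
  expect_equal(binary_stabilizing(c(0)), 0L)
  expect_true(all(binary_stabilizing(runif(20, 0.1, 5)) == 1L))
  labels <- c(rep(1, 38), rep(0, 12))
  expect_equal(mean(labels), 0.76)
})

test_that("band (0,0) agrees with the binary rule on all nonzero values", {
  set.seed(4)
  v <- rnorm(200)
  v <- v[v != 0]
  three <- classify_by_regression(v, 0, 0)
  expect_identical(as.integer(three == "stabilizing"), binary_stabilizing(v))
})

test_that("classification metrics match hand computations", {
  expect_equal(classification_metrics(c("a", "b", "c"), c("a", "b", "c")),
               c(accuracy = 1, mcc = 1, weighted_f1 = 1))
  # binary contingency TP=3 FP=1 FN=2 TN=4, MCC by the closed formula
  truth <- c(rep("pos", 5), rep("neg", 5))
  pred <- c("pos", "pos", "pos", "neg", "neg", "pos", "neg", "neg", "neg", "neg")
  m <- classification_metrics(truth, pred)
  expect_equal(unname(m["accuracy"]), 0.7)
  expect_equal(unname(m["mcc"]), (3 * 4 - 1 * 2) / sqrt(4 * 5 * 5 * 6))
  f1_pos <- 2 * 3 / (2 * 3 + 1 + 2)
  f1_neg <- 2 * 4 / (2 * 4 + 2 + 1)
  expect_equal(unname(m["weighted_f1"]), 0.5 * f1_pos + 0.5 * f1_neg)

  # uniform random labels over 3 balanced classes: accuracy near 1/3
  set.seed(9)
  t3 <- sample(c("a", "b", "c"), 3000, replace = TRUE)
  p3 <- sample(c("a", "b", "c"), 3000, replace = TRUE)
  expect_lt(abs(classification_metrics(t3, p3)["accuracy"] - 1 / 3), 0.03)

  expect_warning(m1 <- classification_metrics(rep("a", 5), rep("a", 5)),
                 class = "gs_degenerate_warning")
  expect_equal(unname(m1["mcc"]), 0)
})

test_that("threshold scan enumerates the full band grid", {
  set.seed(2)
  yt <- rnorm(40, 0, 2)
  sc <- threshold_scan(yt, yt)
  expect_equal(nrow(sc$table), 59L)
  expect_true(all(sc$table$accuracy == 1))           # perfect predictions
  expect_equal(sc$table$band_hi, seq(0.1, 3.0, 0.05))

  # 12-point fixture: confusion at band (-1, 1) tallied by hand
  yt2 <- c(-3, -2, -1.5, -0.5, 0, 0.4, 0.9, 1.2, 2, 2.5, -1.2, 1.05)
  yp2 <- c(-2, 1.5, -0.2, -1.4, 0.3, 2, -3, 1.4, 0.6, 2.2, 0, -0.9)
  t_lab <- classify_by_regression(yt2, -1, 1)
  p_lab <- classify_by_regression(yp2, -1, 1)
  hand <- 0
  for (i in seq_along(yt2)) {
    tl <- if (yt2[i] < -1) "d" else if (yt2[i] > 1) "s" else "n"
    pl <- if (yp2[i] < -1) "d" else if (yp2[i] > 1) "s" else "n"
    hand <- hand + (tl == pl)
  }
  m <- suppressWarnings(classification_metrics(t_lab, p_lab))
  expect_equal(unname(m["accuracy"]), hand / 12)
  row <- threshold_scan(yt2, yp2, start = 1, step = 0.5, max = 1)$table
  expect_equal(row$accuracy, hand / 12)
})

test_that("metrics are permutation equivariant and bands act monotonically", {
  set.seed(5)
  yt <- rnorm(60); yp <- yt + rnorm(60, 0, 0.5)
  perm <- sample(60)
  r1 <- regression_metrics(yt, yp)
  r2 <- regression_metrics(yt[perm], yp[perm])
  expect_equal(unclass(r1), unclass(r2))
  m1 <- suppressWarnings(classification_metrics(
    classify_by_regression(yt, -0.5, 0.5), classify_by_regression(yp, -0.5, 0.5)))
  m2 <- suppressWarnings(classification_metrics(
    classify_by_regression(yt[perm], -0.5, 0.5),
    classify_by_regression(yp[perm], -0.5, 0.5)))
  expect_equal(m1, m2)
  # widening the band never increases non-neutral labels
  bands <- seq(0.1, 3, 0.3)
  nonneutral <- vapply(bands, function(t) {
    sum(classify_by_regression(yt, -t, t) != "neutral")
  }, numeric(1))
  expect_true(all(diff(nonneutral) <= 0))
})

test_that("benchmarking applies per-method bands", {
  truth <- data.frame(key = paste0("m", 1:6), dTm = c(-2, -1, 0.05, 0.5, 1, 3))
  good <- data.frame(key = truth$key, value = truth$dTm)
  coarse <- data.frame(key = truth$key, value = truth$dTm * 0.1)
  tab <- benchmark_predictors(
    truth,
    list(exact = list(predictions = good, band = c(-0.1, 0.1)),
         shrunk = list(predictions = coarse, band = c(-0.01, 0.01))),
    truth_band = c(-0.1, 0.1))
  expect_equal(tab$accuracy[tab$method == "exact"], 1)
  expect_equal(nrow(tab), 2L)
})
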