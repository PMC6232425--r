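test_that("an exact linear response attributes 100% to its predictor", {
  x <- 1:10
  vp <- variance_partition(2 * x, list(x = x))
  expect_equal(vp$percent[vp$term == "x"], 100, tolerance = 1e-9)
  expect_equal(vp$percent[vp$term == "residual"], 0, tolerance = 1e-9)
  expect_equal(vp$mean_sq[vp$term == "residual"], 0, tolerance = 1e-12)
  expect_true(is.infinite(vp$F[vp$term == "x"]))
})

test_that("percentages sum to 100 and SS decomposition is exact", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    p <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- rnorm(n, mean = 0.5 * p$a - 0.3 * p$c)
    vp <- variance_partition(y, p)
    expect_equal(sum(vp$percent), 100, tolerance = 0.01)
    ss_total <- sum((y - mean(y))^2)
    expect_equal(sum(vp$sum_sq), ss_total, tolerance = 1e-9 * ss_total)
    expect_equal(vp$term, c("a", "b", "c", "residual"))
  }
})

test_that("an orthogonal null design explains essentially nothing", {
  # predictors orthogonal to the response by construction
  y <- rep(c(-1, 1), 8)
  p <- data.frame(x1 = rep(c(1, 1, -1, -1), 4), x2 = rep(c(1, -1), each = 8))
  vp <- variance_partition(y, p)
  expect_equal(vp$percent[vp$term == "x1"], 0, tolerance = 1e-9)
  expect_equal(vp$percent[vp$term == "x2"], 0, tolerance = 1e-9)
})

test_that("term order changes the sequential attribution of correlated predictors", {
  set.seed(92)
  x1 <- rnorm(20)
  x2 <- x1 + rnorm(20, sd = 0.1)
  y <- x1 + rnorm(20, sd = 0.2)
  v12 <- variance_partition(y, list(first = x1, second = x2))
  v21 <- variance_partition(y, list(first = x2, second = x1))
  expect_gt(v12$sum_sq[1], v12$sum_sq[2])
  expect_gt(v21$sum_sq[1], v21$sum_sq[2])
  expect_equal(sum(v12$sum_sq), sum(v21$sum_sq), tolerance = 1e-9)
})

test_that("collinear predictors carry zero SS with a warning; stars follow p", {
  set.seed(93)
  x <- rnorm(15)
  expect_warning(vp <- variance_partition(2 * x + rnorm(15, sd = 0.05),
                                          list(a = x, b = 2 * x)),
                 "collinear")
  expect_equal(vp$sum_sq[vp$term == "b"], 0)
  expect_equal(vp$stars[vp$term == "a"], "***")
  expect_error(variance_partition(1:5, list(a = 1:4)), "length")
  expect_error(variance_partition(1:4, list(a = 1:4, b = 4:1, c = c(2, 4, 1, 3))),
               "observations")
})

test_that("eai_predictors builds |g| and mean-distance columns per cell", {
  est <- data.frame(treatment = rep(c("X", "Y"), each = 2),
                    timepoint = "T1",
                    variable = rep(c("v1", "v2"), 2),
                    g = c(-1.5, 0.5, 2, 1), var_g = 0.6)
  eai_tab <- eai_table(est, letters = FALSE)
  md <- data.frame(sample_id = c("c1", "c2", "x1", "x2", "y1", "y2"),
                   treatment = rep(c("control", "X", "Y"), each = 2),
                   timepoint = "T1")
  dm <- matrix(1, 6, 6, dimnames = list(md$sample_id, md$sample_id))
  diag(dm) <- 0
  dm[c("x1", "x2"), c("c1", "c2")] <- 3
  dm[c("c1", "c2"), c("x1", "x2")] <- 3
  out <- eai_predictors(eai_tab, est, dm = dm, metadata = md, control = "control",
                        predictors = c("weighted_unifrac", "v1"))
  expect_equal(out$response, eai_tab$eai)
  expect_equal(out$predictors$weighted_unifrac,
               c(3, 1)[match(eai_tab$treatment, c("X", "Y"))])
  expect_equal(out$predictors$v1, abs(est$g[est$variable == "v1"]))
  expect_error(eai_predictors(eai_tab, est, predictors = "weighted_unifrac"),
               "needs dm")
})
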