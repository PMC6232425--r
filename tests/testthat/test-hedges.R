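test_that("hedges_g reproduces the hand-worked 4-vs-4 example", {
  est <- hedges_g(control = c(10, 12, 11, 13), treated = c(14, 16, 15, 17))
  # by hand: s_p = sqrt(5/3), d = 4/s_p, J = 1 - 3/23
  expect_equal(est$g, 2.6943, tolerance = 1e-4)
  expect_equal(est$var_g, 0.9537, tolerance = 1e-4)
  expect_equal(est$ci_low, est$g - 1.96 * sqrt(est$var_g), tolerance = 1e-12)
  expect_equal(est$ci_high, est$g + 1.96 * sqrt(est$var_g), tolerance = 1e-12)

  orc <- oracle_hedges_g(c(10, 12, 11, 13), c(14, 16, 15, 17))
  expect_equal(est$g, orc$g, tolerance = 1e-12)
  expect_equal(est$var_g, orc$var_g, tolerance = 1e-12)
})

test_that("hedges_g agrees with a meta-analysis reference up to its bias-correction variant", {
  skip_if_not_installed("metafor")
  ctrl <- c(10, 12, 11, 13); trt <- c(14, 16, 15, 17)
  ref <- metafor::escalc(measure = "SMD", m1i = mean(trt), sd1i = sd(trt), n1i = 4,
                         m2i = mean(ctrl), sd2i = sd(ctrl), n2i = 4)
  est <- hedges_g(ctrl, trt)
  # metafor uses the exact-gamma correction; ours the 1 - 3/(4m-1) form
  expect_equal(est$g, as.numeric(ref$yi), tolerance = 0.01)
  expect_equal(est$var_g, as.numeric(ref$vi), tolerance = 0.01)
})

test_that("identical groups give a zero effect with a symmetric CI", {
  est <- hedges_g(c(5, 5, 5, 7), c(5, 5, 5, 7))
  expect_equal(est$g, 0)
  expect_equal(est$ci_low, -est$ci_high)
})

test_that("swapping groups negates g and preserves var_g; scale and location invariance", {
  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(sample(2:8, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    e1 <- hedges_g(a, b)
    e2 <- hedges_g(b, a)
    expect_equal(e1$g, -e2$g, tolerance = 1e-12)
    expect_equal(e1$var_g, e2$var_g, tolerance = 1e-12)
    k <- runif(1, 0.1, 50); c0 <- runif(1, -100, 100)
    e3 <- hedges_g(a * k, b * k)
    e4 <- hedges_g(a + c0, b + c0)
    expect_equal(e3$g, e1$g, tolerance = 1e-12)
    expect_equal(e4$g, e1$g, tolerance = 1e-12)
  }
})

test_that("degenerate inputs are rejected or handled as specified", {
  expect_error(hedges_g(c(1), c(1, 2)), "insufficient replicates")
  expect_error(hedges_g(c(1, 2), c(3)), "insufficient replicates")
  expect_error(hedges_g(c(1, 1, 1), c(2, 2, 2)), "zero pooled variance")
  expect_error(hedges_g(c(1, NA, 2), c(1, 2)), "non-finite")
  # zero spread, equal means: g = 0 with the n-dependent variance term only
  est <- hedges_g(c(3, 3, 3, 3), c(3, 3, 3, 3))
  expect_equal(est$g, 0)
  expect_equal(est$var_g, 0.5)
})

make_measurements <- function(values_by_cell) {
  # values_by_cell: named list "treatment|timepoint|variable" -> numeric
  do.call(rbind, lapply(names(values_by_cell), function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    v <- values_by_cell[[k]]
    data.frame(sample_id = paste(p[1], p[2], seq_along(v), sep = "_"),
               treatment = p[1], timepoint = p[2], replicate = seq_along(v),
               variable = p[3], value = v)
  }))
}

test_that("effect_size_table keys, ordering and the all-equal null", {
  m <- make_measurements(list(
    "control|T1|v1" = c(1, 2, 3, 4), "trt|T1|v1" = c(1, 2, 3, 4),
    "control|T1|v2" = c(5, 6, 7, 8), "trt|T1|v2" = c(5, 6, 7, 8),
    "control|T1|v3" = c(2, 4, 6, 8), "trt|T1|v3" = c(2, 4, 6, 8)))
  es <- effect_size_table(m, control = "control")
  expect_equal(nrow(es), 3)
  expect_equal(es$variable, c("v1", "v2", "v3"))
  expect_equal(es$treatment, rep("trt", 3))
  expect_true(all(es$g == 0))
})

test_that("log10 transform matches direct evaluation on transformed lists", {
  ctrl <- c(10, 13, 11, 12)
  trt <- 10 * ctrl
  m <- make_measurements(list("control|T1|v" = ctrl, "trt|T1|v" = trt))
  es <- effect_size_table(m, control = "control", transforms = c(v = "log10"))
  direct <- hedges_g(log10(ctrl), log10(trt))
  expect_equal(es$g, direct$g, tolerance = 1e-12)
  expect_equal(es$transform, "log10")
  # log-scale means differ by exactly 1, same spread pattern
  expect_equal(mean(log10(trt)) - mean(log10(ctrl)), 1)
})

test_that("effect_size_table validates its inputs", {
  m <- make_measurements(list("control|T1|v" = 1:4, "trt|T1|v" = 2:5,
                              "trt|T2|v" = 2:5))
  expect_error(effect_size_table(m, control = "control"), "T2")
  m2 <- make_measurements(list("control|T1|v" = 1:4, "control|T1|w" = 1:4,
                               "trt|T1|v" = 2:5))
  expect_error(effect_size_table(m2, control = "control"), "w")
  m3 <- make_measurements(list("control|T1|v" = c(-1, 1, 2, 3), "trt|T1|v" = 2:5))
  expect_error(effect_size_table(m3, control = "control",
                                 transforms = c(v = "log10")),
               "non-positive.*control_T1_1")
  expect_error(effect_size_table(m, control = "nope"), "not present")
})
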