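test_that("standardization is exact, idempotent and back-mappable", {
  df <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  z <- standardize(df, c("a", "b"))
  expect_equal(z$a, c(-1, 0, 1))                 # sample SD = 1
  expect_equal(mean(z$b), 0)
  expect_equal(sd(z$b), 1)
  z2 <- standardize(z, c("a", "b"))
  expect_equal(z2$a, z$a, tolerance = 1e-12)

  # a slope fitted on the z scale maps back exactly
  set.seed(3)
  big <- data.frame(x = rnorm(100, 5, 2))
  big$y <- 1.5 * big$x + rnorm(100, 0, 0.1)
  zb <- standardize(big, "x")
  slope_z <- coef(lm(y ~ x, zb))[["x"]]
  sc <- attr(zb, "standardization")
  expect_equal(slope_z / sc$scale, coef(lm(y ~ x, big))[["x"]],
               tolerance = 1e-10)

  expect_error(standardize(data.frame(k = rep(2, 5)), "k"), "zero-variance")
})

test_that("collinearity screen flags exactly the dependent pairs", {
  set.seed(5)
  df <- data.frame(x = rnorm(1e4))
  df$x2 <- 2 * df$x
  df$z <- rnorm(1e4)
  scr <- collinearity_screen(df, c("x", "x2", "z"))
  expect_equal(nrow(scr$flagged), 1)
  expect_setequal(as.character(scr$flagged[1, ]), c("x", "x2"))

  indep <- data.frame(a = rnorm(1e4), b = rnorm(1e4), c = rnorm(1e4))
  expect_equal(nrow(collinearity_screen(indep, c("a", "b", "c"))$flagged), 0)
})

test_that("ML mixed fits agree with OLS in the degenerate limit and recover
           the published-scale coefficient presets", {
  # no among-group variance: ML fixed effects equal ordinary least squares
  set.seed(7)
  df <- data.frame(individual = rep(1:20, each = 5), x = rnorm(100))
  df$y <- 2 + 0.8 * df$x + rnorm(100, 0, 1)
  m <- fit_lmm_ml(df, "y", "x")
  ols <- coef(lm(y ~ x, df))
  expect_lt(max(abs(m$coef - ols)), 1e-6)
  expect_true(m$singular)

  # preset simulation: log(HR) = 0.54 z(max_disp) + 0.34 z(rIIV) + noise
  set.seed(8)
  n_ind <- 64
  d2 <- data.frame(individual = rep(seq_len(n_ind), each = 2),
                   max_disp = rnorm(128), riiv = rnorm(128))
  b_i <- rnorm(n_ind, 0, 0.2)
  d2$log_hr <- 0.54 * d2$max_disp + 0.34 * d2$riiv + b_i[d2$individual] +
    rnorm(128, 0, 0.3)
  m2 <- fit_lmm_ml(d2, "log_hr", c("max_disp", "riiv"))
  expect_lt(abs(m2$coef[["max_disp"]] - 0.54), 0.1)
  expect_lt(abs(m2$coef[["riiv"]] - 0.34), 0.1)
  expect_equal(m2$k, 5L)  # 3 fixed effects + 2 variances
})

test_that("AICc follows its closed form and limits", {
  expect_equal(aicc(-10, 3, 20), 27.5)
  expect_equal(aicc(-10, 3, 1e9), -2 * -10 + 6, tolerance = 1e-6)
  for (n in c(6, 10, 50)) expect_gt(aicc(-5, 3, n), -2 * -5 + 6)
  expect_error(aicc(-5, 3, 4), "exceed")
})

test_that("enumeration counts, constraints and weights behave exactly", {
  set.seed(9)
  df <- data.frame(individual = rep(1:30, each = 4),
                   p1 = rnorm(120), p2 = rnorm(120), p3 = rnorm(120))
  df$y <- 0.5 * df$p1 + rnorm(30, 0, 0.3)[df$individual] + rnorm(120, 0, 0.5)

  tab <- enumerate_and_rank(df, "y", c("p1", "p2", "p3"))
  expect_equal(nrow(tab), 8)                       # 2^3
  expect_equal(sum(tab$weight), 1)
  expect_equal(min(tab$delta), 0)

  tab_f <- enumerate_and_rank(df, "y", c("p1", "p2", "p3"), forced = "p1")
  expect_equal(nrow(tab_f), 4)
  expect_true(all(grepl("p1", tab_f$formula)))

  # flagged pairs never co-occur
  tab_x <- enumerate_and_rank(df, "y", c("p1", "p2", "p3"),
                              excluded_pairs = cbind("p1", "p2"))
  expect_equal(nrow(tab_x), 6)
  expect_false(any(grepl("p1", tab_x$formula) & grepl("p2", tab_x$formula)))

  # ranking invariant to enumeration order of predictors
  tab_r <- enumerate_and_rank(df, "y", c("p3", "p2", "p1"))
  expect_equal(tab_r$formula, tab$formula)
  expect_equal(tab_r$AICc, tab$AICc)

  expect_error(enumerate_and_rank(df, "y", paste0("p", 1:3), max_models = 4),
               "raise max_models")
})

test_that("full model averaging shrinks absent predictors toward zero", {
  set.seed(10)
  df <- data.frame(individual = rep(1:40, each = 3),
                   a = rnorm(120), b = rnorm(120))
  df$y <- 1 + 0.9 * df$a + rnorm(40, 0, 0.3)[df$individual] +
    rnorm(120, 0, 0.4)
  tab <- enumerate_and_rank(df, "y", c("a", "b"))
  avg <- model_average(tab, delta_max = 4)
  arow <- avg[avg$term == "a", ]
  expect_lt(abs(arow$estimate - 0.9), 0.15)

  # single model in scope: averaged estimates equal that model's
  avg1 <- model_average(tab, delta_max = 1e-9)
  top <- attr(tab, "models")[[1]]
  for (tm in avg1$term) {
    expect_equal(avg1$estimate[avg1$term == tm], unname(top$coef[tm]))
    expect_equal(avg1$se_unconditional[avg1$term == tm], unname(top$se[tm]))
  }

  # the full average lies in the convex hull of {model estimate, 0}
  models <- attr(tab, "models")
  for (tm in avg$term) {
    bs <- vapply(models, function(m)
      if (tm %in% names(m$coef)) unname(m$coef[tm]) else 0, 0)
    expect_lte(avg$estimate[avg$term == tm], max(bs) + 1e-12)
    expect_gte(avg$estimate[avg$term == tm], min(bs) - 1e-12)
  }

  # weights invariant to a constant shift of every AICc
  tab2 <- tab
  tab2$AICc <- tab2$AICc + 100
  tab2$delta <- tab2$AICc - min(tab2$AICc)
  w2 <- exp(-0.5 * tab2$delta); w2 <- w2 / sum(w2)
  expect_equal(w2, tab$weight, tolerance = 1e-12)
})
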