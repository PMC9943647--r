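test_that("noiseless hyperbolas invert exactly", {
  x <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  fit <- fit_hyperbola(x, 0.9 * x / (1.1 + x))
  expect_equal(unname(coef(fit)), c(1.1, 0.9), tolerance = 1e-6)
  # half-saturation identity
  expect_equal(predict(fit, newdata = fit$Kd), fit$Bmax / 2)
  expect_lt(fit$rss, 1e-12)
})

test_that("hyperbola preconditions are enforced", {
  expect_error(fit_hyperbola(c(1, 2), c(0.1, 0.2)),
               class = "bindpoly_invalid_input")
  expect_error(fit_hyperbola(c(1, 1, 1, 2), c(0.1, 0.1, 0.1, 0.2)),
               class = "bindpoly_invalid_input")   # only 2 distinct x
  expect_error(fit_hyperbola(c(1, 2, 4), c(0, 0, 0)),
               class = "bindpoly_invalid_input")   # no signal
})

test_that("fits are scale-equivariant in concentration", {
  x <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  y <- 0.85 * x / (1.7 + x)
  f1 <- fit_hyperbola(x, y)
  for (c_ in c(0.1, 3, 50)) {
    f2 <- fit_hyperbola(c_ * x, y)
    expect_equal(f2$Kd, c_ * f1$Kd, tolerance = 1e-9)
    expect_equal(f2$Bmax, f1$Bmax, tolerance = 1e-9)
  }
})

test_that("EMSA and SPR fitting share one hyperbolic core", {
  conc <- c(0.1, 0.25, 0.5, 0.75, 1)
  Req <- 100 * conc / (0.22 + conc)
  spr <- fit_spr_steady_state(conc, Req)
  expect_equal(unname(coef(spr)), c(0.22, 100), tolerance = 1e-6)
  # Req at Kd is half the maximal response
  expect_equal(predict(spr, newdata = 0.22), 50, tolerance = 1e-4)
  emsa_core <- fit_hyperbola(conc, Req)
  expect_equal(coef(spr), coef(emsa_core))
  expect_error(fit_spr_steady_state(c(0.5, 0.5, 0.5), c(10, 11, 12)),
               class = "bindpoly_invalid_input")
})

test_that("Kd is recovered under measurement noise and with fixed Bmax", {
  kds <- vapply(1:20, function(i) {
    d <- simulate_binding_curve(Kd = 1.1, Bmax = 0.9, sigma = 0.03,
                                seed = 100 + i)
    fit_hyperbola(d$x_uM, d$y)$Kd
  }, numeric(1))
  expect_lt(abs(mean(kds) - 1.1) / 1.1, 0.10)

  x <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
  fitf <- fit_hyperbola(x, 1 * x / (2 + x), fix_bmax = 1)
  expect_equal(fitf$Kd, 2, tolerance = 1e-6)
  expect_identical(fitf$Bmax, 1)
})

test_that("a Kd outside the probed range is flagged as poorly constrained", {
  x <- c(1, 2, 4, 8)
  expect_warning(fit <- fit_hyperbola(x, 1e-4 * x / (1e4 + x) + 1e-5),
                 "poorly constrained")
  expect_true(fit$poorly_constrained)
})

test_that("active fraction is the bound-to-total ratio with clipping", {
  expect_equal(as.numeric(active_fraction(0, 1)), 0)
  f <- active_fraction(0.93, 1)
  expect_equal(as.numeric(f), 0.93)
  expect_false(attr(f, "over_unity"))
  expect_warning(g <- active_fraction(1.2, 1), "clipped")
  expect_equal(as.numeric(g), 1)
  expect_true(attr(g, "over_unity"))
  expect_error(active_fraction(0.5, 0), class = "bindpoly_invalid_input")
})

test_that("group comparisons match their sampling distributions", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  res <- compare_affinity_groups(same, mode = "anova")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  g1 <- c(1.0, 1.1, 1.2); g2 <- c(5.0, 5.5, 6.0)
  tt <- compare_affinity_groups(list(g1, g2), mode = "ttest")
  expect_lt(tt$p_value, 0.01)

  # permutation oracle: the observed |t| is the most extreme of all
  # choose(6,3) = 20 label assignments
  pool <- c(g1, g2)
  combs <- utils::combn(6, 3)
  tstats <- apply(combs, 2, function(idx)
    abs(stats::t.test(pool[idx], pool[-idx], var.equal = TRUE)$statistic))
  expect_equal(sum(tstats >= abs(tt$statistic) - 1e-12), 2)  # the split + mirror

  # Welch variant differs in degrees of freedom
  tw <- compare_affinity_groups(list(g1, g2), mode = "ttest", welch = TRUE)
  expect_lt(tw$df, tt$df)

  expect_error(compare_affinity_groups(list(g1), mode = "anova"),
               class = "bindpoly_invalid_input")
  expect_error(compare_affinity_groups(list(g1, c(1)), mode = "anova"),
               class = "bindpoly_invalid_input")
  expect_error(compare_affinity_groups(list(g1, g2, g2), mode = "ttest"),
               class = "bindpoly_invalid_input")
})

test_that("the ANOVA holds its nominal type-I error rate", {
  set.seed(77)
  p <- vapply(1:1000, function(i) {
    groups <- list(stats::rnorm(5, 1, 0.2), stats::rnorm(5, 1, 0.2),
                   stats::rnorm(5, 1, 0.2))
    compare_affinity_groups(groups, mode = "anova")$p_value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})
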