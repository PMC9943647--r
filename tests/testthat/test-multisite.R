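test_that("noiseless titrations invert to the generating constants", {
  grid <- seq(0.05, 5, length.out = 12)
  for (K in list(c(3, 3, 3), c(4, 5, 6))) {
    fit <- fit_macroscopic(theory_titration(K, grid))
    expect_s3_class(fit, "macrofit")
    expect_true(fit$converged)
    expect_equal(unname(coef(fit)), K, tolerance = 1e-6)
  }
})

test_that("recovery holds across four decades of each constant", {
  grid <- log_grid(0.01, 10, 15)
  cases <- list(c(0.01, 0.01, 0.01), c(100, 100, 100), c(0.01, 1, 100),
                c(100, 1, 0.01), c(0.5, 20, 0.05))
  for (K in cases) {
    fit <- fit_macroscopic(theory_titration(K, grid))
    expect_equal(unname(coef(fit)), K, tolerance = 1e-6)
  }
})

test_that("flat free-DNA data raises an identifiability error", {
  d <- data.frame(replicate = "r1", protein_uM = c(0.1, 0.5, 1, 2),
                  dna_uM = 0.02, f0 = 1, f1 = 0, f2 = 0, f3 = 0)
  expect_error(fit_macroscopic(d), class = "bindpoly_identifiability_error")
})

test_that("titration validation enforces the fraction simplex and grid size", {
  d <- theory_titration(c(3, 3, 3), seq(0.1, 1.3, length.out = 6))
  d2 <- d; d2$f0 <- d2$f0 + 0.015          # within 2% slack: renormalised
  fit <- fit_macroscopic(d2)
  expect_true(all(abs(rowSums(fit$data[, c("f0", "f1", "f2", "f3")]) - 1) <
                  1e-12))
  d3 <- d; d3$f0 <- d3$f0 + 0.2            # beyond slack: rejected
  expect_error(fit_macroscopic(d3), class = "bindpoly_invalid_input")
  d4 <- d[1:3, ]                           # < 4 distinct concentrations
  expect_error(fit_macroscopic(d4), class = "bindpoly_invalid_input")
  d5 <- rbind(d, transform(d, replicate = "r2"))
  expect_error(fit_macroscopic(d5), class = "bindpoly_invalid_input")
})

test_that("exact ligand conservation recovers constants under depletion", {
  # forward-generate with the mass balance solved independently by uniroot
  K <- c(3.6, 4.32, 5.184)
  P <- seq(0.1, 1.3, length.out = 10)
  dna <- 0.02
  L <- vapply(P, function(p) {
    stats::uniroot(function(l) {
      Z <- 1 + K[1] * l + K[2] * l^2 + K[3] * l^3
      l + dna * (K[1] * l + 2 * K[2] * l^2 + 3 * K[3] * l^3) / Z - p
    }, c(0, p), tol = 1e-14)$root
  }, numeric(1))
  th <- species_fractions(L, K)
  d <- data.frame(replicate = "r1", protein_uM = P, dna_uM = dna,
                  f0 = th$theta0, f1 = th$theta1, f2 = th$theta2,
                  f3 = th$theta3)
  fit <- fit_macroscopic(d, ligand_conservation = "exact")
  expect_equal(unname(coef(fit)), K, tolerance = 1e-6)
  # the total-protein approximation is biased, but only slightly at 20 nM DNA
  fit_tot <- fit_macroscopic(d, ligand_conservation = "total")
  expect_false(isTRUE(all.equal(unname(coef(fit_tot)), K, tolerance = 1e-6)))
  expect_equal(unname(coef(fit_tot)), K, tolerance = 0.3)
})

test_that("macrofit methods are coherent", {
  grid <- seq(0.05, 5, length.out = 12)
  fit <- fit_macroscopic(theory_titration(c(4, 5, 6), grid))
  expect_equal(dim(residuals(fit)), c(12L, 4L))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  pr <- predict(fit, newdata = c(0.5, 1))
  expect_equal(pr$theta1, species_fractions(c(0.5, 1), c(4, 5, 6))$theta1)
  expect_output(print(fit), "K1")
  expect_output(print(summary(fit)), "cooperativity ratios")
})

test_that("bootstrap is seed-deterministic and degenerate on exact data", {
  d <- theory_titration(c(3, 3, 3), seq(0.05, 5, length.out = 12))
  b1 <- bootstrap_uncertainty(d, n_boot = 100, seed = 5)
  b2 <- bootstrap_uncertainty(d, n_boot = 100, seed = 5)
  expect_identical(b1$draws, b2$draws)
  b3 <- bootstrap_uncertainty(d, n_boot = 100, seed = 6)
  expect_false(identical(b1$draws, b3$draws))
  # resampling exact model points: every refit lands on the same constants
  expect_lt(max(vapply(b1$draws[c("K1", "K2", "K3")], stats::sd, 1)), 1e-6)
  expect_equal(b1$n_failed, 0)
  expect_error(bootstrap_uncertainty(d, n_boot = 50, seed = 1),
               class = "bindpoly_invalid_input")
  expect_error(bootstrap_uncertainty(d, n_boot = 100),
               class = "bindpoly_invalid_input")
})

test_that("bootstrap intervals cover the generating constants", {
  # three independent gels per dataset, as in the published EMSA design
  trials <- 20
  covered <- matrix(FALSE, trials, 3)
  K_true <- c(3, 3, 3)
  for (i in seq_len(trials)) {
    sim <- simulate_titration(K = K_true,
                              grid = seq(0.05, 5, length.out = 12),
                              reps = 3, noise = 300, seed = 1000 + i)
    boot <- bootstrap_uncertainty(sim, n_boot = 500, seed = 2000 + i)
    for (j in 1:3) {
      ci <- stats::quantile(boot$draws[[j]], c(0.025, 0.975), names = FALSE)
      covered[i, j] <- K_true[j] >= ci[1] && K_true[j] <= ci[2]
    }
  }
  # each constant inside its central 95% interval in at least 90% of trials
  expect_true(all(colMeans(covered) >= 0.9))
})

test_that("independent data yield unit ratios, no verdict, and the true Ka", {
  grid <- seq(0.05, 5, length.out = 12)
  for (Ka in c(0.3, 1.2, 5)) {
    d <- theory_titration(macro_from_ka(Ka), grid)
    fit <- fit_macroscopic(d)
    boot <- bootstrap_uncertainty(d, n_boot = 100, seed = 9)
    rep <- assess_cooperativity(fit, boot)
    expect_equal(rep$r2_mean, 1, tolerance = 1e-6)
    expect_equal(rep$r3_mean, 1, tolerance = 1e-6)
    expect_identical(c(rep$verdict2, rep$verdict3),
                     c("not-inferred", "not-inferred"))
    expect_equal(rep$Ka_mean, Ka, tolerance = 1e-6)
    # single noiseless replicate: zero spread, Kd exactly reciprocal
    expect_identical(rep$r2_sd, 0)
    expect_identical(rep$Ka_sd, 0)
    expect_equal(rep$Kd, 1 / rep$Ka_mean)
  }
})

test_that("pairwise-coupled sites are called cooperative and refuse the reduction", {
  # micro constants k = 1, all couplings 10 -> K = (3, 30, 30), r2 = 10
  K <- macro_from_micro(micro_constants(1, 1, 1, 10, 10, 10))
  expect_equal(unclass(K), c(K1 = 3, K2 = 30, K3 = 30))
  expect_equal(unname(cooperativity_ratios(K)["r2"]), 10)
  d <- simulate_titration(K = K, grid = seq(0.05, 5, length.out = 12),
                          noise = 500, seed = 21)
  fit <- fit_macroscopic(d)
  boot <- bootstrap_uncertainty(d, n_boot = 200, seed = 22)
  rep <- assess_cooperativity(fit, boot)
  expect_identical(rep$verdict2, "cooperative")
  expect_true(is.na(rep$Ka_mean))
  expect_true(is.na(rep$Kd))
  expect_output(print(rep), "reduction refused")
})

test_that("the cooperative verdict is rare under a true independent generator", {
  n_sets <- 50
  verdicts <- matrix(FALSE, n_sets, 2)
  for (i in seq_len(n_sets)) {
    sim <- simulate_titration(Ka = 1.2, noise = 300, seed = 5000 + i)
    fit <- fit_macroscopic(sim)
    boot <- bootstrap_uncertainty(sim, n_boot = 100, seed = 6000 + i)
    rep <- assess_cooperativity(fit, boot)
    verdicts[i, ] <- c(rep$verdict2, rep$verdict3) == "cooperative"
  }
  expect_lte(mean(verdicts[, 1]), 0.10)
  expect_lte(mean(verdicts[, 2]), 0.10)
})

test_that("full pipeline reciprocity: Kd = 1/Ka_true on noiseless data", {
  for (Ka in c(0.5, 1.2, 3)) {
    d <- theory_titration(macro_from_ka(Ka),
                          seq(0.1, 1.3, length.out = 12))
    fit <- fit_macroscopic(d)
    kd <- ka_from_macro(fit$K)$Kd
    expect_equal(kd, 1 / Ka, tolerance = 0.02)
  }
})
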