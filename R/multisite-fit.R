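## Multisite inference: estimate (K1, K2, K3) from EMSA titration fractions,
## bootstrap the uncertainty, and issue cooperativity verdicts plus the
## identical-site Ka/Kd reduction.

TITRATION_COLS <- c("replicate", "protein_uM", "dna_uM", "f0", "f1", "f2", "f3")

# Validate a titration data frame and renormalise fraction rows.
# Per-row fraction sums may deviate from 1 by up to `slack` (gel-quantification
# tolerance); within slack rows are rescaled to sum exactly to 1, beyond it the
# row is rejected with its index.
validate_titration <- function(data, slack = 0.02, renormalize = TRUE) {
  if (!is.data.frame(data))
    stop_bindpoly("titration data must be a data frame", "bindpoly_invalid_input")
  missing <- setdiff(setdiff(TITRATION_COLS, c("replicate", "dna_uM")),
                     names(data))
  if (length(missing))
    stop_bindpoly(paste0("titration data is missing column(s): ",
                         paste(missing, collapse = ", ")),
                  "bindpoly_invalid_input")
  if (is.null(data$replicate)) data$replicate <- "r1"
  if (is.null(data$dna_uM)) data$dna_uM <- NA_real_
  fr <- as.matrix(data[, c("f0", "f1", "f2", "f3")])
  if (anyNA(fr) || any(fr < -1e-12) || any(fr > 1 + 1e-12))
    stop_bindpoly("fractions f0..f3 must lie in [0, 1]", "bindpoly_invalid_input")
  if (anyNA(data$protein_uM) || any(data$protein_uM < 0))
    stop_bindpoly("protein_uM must be non-negative", "bindpoly_invalid_input")
  sums <- rowSums(fr)
  bad <- which(abs(sums - 1) > slack)
  if (length(bad))
    stop_bindpoly(paste0("fraction rows must sum to 1 within ", slack,
                         "; offending row(s): ", paste(bad, collapse = ", ")),
                  "bindpoly_invalid_input")
  if (renormalize) {
    data[, c("f0", "f1", "f2", "f3")] <- fr / sums
  }
  for (rep_id in unique(data$replicate)) {
    if (length(unique(data$protein_uM[data$replicate == rep_id])) < 4)
      stop_bindpoly(paste0("replicate '", rep_id,
                           "' has fewer than 4 distinct protein concentrations"),
                    "bindpoly_invalid_input")
  }
  data
}

# Free ligand concentration per titration point. "total" approximates free
# protein by total protein (DNA is in the tens of nM against >= 100 nM
# protein, so depletion is at most a few percent); "exact" solves the scalar
# mass balance L + D * (theta1 + 2*theta2 + 3*theta3) = P by bracketed
# root-finding at each point.
free_ligand <- function(P, D, K, conservation = c("total", "exact")) {
  conservation <- match.arg(conservation)
  if (conservation == "total") return(P)
  if (any(is.na(D)))
    stop_bindpoly("exact ligand conservation requires dna_uM",
                  "bindpoly_invalid_input")
  vapply(seq_along(P), function(i) {
    p <- P[i]; d <- D[i]
    if (p == 0) return(0)
    g <- function(l) {
      Z <- 1 + K[1] * l + K[2] * l^2 + K[3] * l^3
      bound <- (K[1] * l + 2 * K[2] * l^2 + 3 * K[3] * l^3) / Z
      l + d * bound - p
    }
    stats::uniroot(g, c(0, p), tol = 1e-12)$root
  }, numeric(1))
}

# residual vector on the log10-K scale; inlined binding polynomial (this is
# the hot path of the fit and of every bootstrap refit)
macrofit_residuals <- function(logK, P, D, obs, sw, conservation) {
  K <- 10^logK
  L <- if (conservation == "total") P else free_ligand(P, D, K, conservation)
  Z <- 1 + K[1] * L + K[2] * L^2 + K[3] * L^3
  pred <- cbind(K[1] * L, K[2] * L^2, K[3] * L^3) / Z
  as.vector(sw * (obs - pred))
}

#' Fit macroscopic binding constants to an EMSA titration
#'
#' Estimates the binding-polynomial coefficients `(K1, K2, K3)` of a
#' three-site DNA from the observed ligation-state fractions of one titration
#' replicate, by weighted nonlinear least squares on `(f1, f2, f3)` against
#' the model fractions `(theta1, theta2, theta3)` (the free-DNA fraction is
#' determined by normalisation and excluded). Positivity is enforced by
#' fitting `log10(Ki)`; Levenberg-Marquardt is restarted from `n_starts`
#' points of a log-uniform grid and the lowest residual sum of squares wins,
#' ties (RSS within 1e-9) going to the smallest `||log10 K||`.
#'
#' @param data Data frame with columns `protein_uM`, `f0`..`f3` and
#'   optionally `dna_uM` and `replicate` (a single replicate). Fraction rows
#'   are renormalised to sum to 1 (up to 2% slack; beyond that the row is
#'   rejected).
#' @param ligand_conservation `"total"` (default) approximates free ligand by
#'   total protein; `"exact"` solves the mass balance
#'   `L + dna_uM * (theta1 + 2 theta2 + 3 theta3) = protein_uM` per point.
#' @param weights Optional per-row weights (e.g. inverse replicate variances);
#'   default unit weights.
#' @param n_starts Number of multistart initialisations (default 8, the
#'   corners of a log10 grid spanning 1e-2 to 1e2).
#' @param start Optional numeric vector `log10(c(K1, K2, K3))` used as the
#'   only start (used internally by the bootstrap for speed).
#' @return An object of class `"macrofit"` with components `K`
#'   ([macro_constants()]), `se` (delta-method standard errors of the Ki),
#'   `rss`, `converged`, `n_starts_used`, `data`, and the fitted fractions.
#' @examples
#' sim <- simulate_titration(Ka = 1.2, noise = 0, seed = 1)
#' fit <- fit_macroscopic(sim)
#' coef(fit)
#' @export
fit_macroscopic <- function(data,
                            ligand_conservation = c("total", "exact"),
                            weights = NULL,
                            n_starts = 8,
                            start = NULL) {
  ligand_conservation <- match.arg(ligand_conservation)
  data <- validate_titration(data)
  if (length(unique(data$replicate)) > 1)
    stop_bindpoly("fit_macroscopic fits one replicate at a time; split by replicate",
                  "bindpoly_invalid_input")
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (length(weights) != nrow(data) || any(weights <= 0))
    stop_bindpoly("weights must be positive, one per row", "bindpoly_invalid_input")

  # identifiability: there must be a binding signal somewhere on the grid
  if (max(data$f1 + data$f2 + data$f3) < 0.02)
    stop_bindpoly("no binding signal: all rows are essentially free DNA",
                  "bindpoly_identifiability_error")

  starts <- if (!is.null(start)) {
    matrix(start, nrow = 1)
  } else {
    as.matrix(expand.grid(c(-2, 2), c(-2, 2), c(-2, 2)))[seq_len(n_starts), ,
                                                         drop = FALSE]
  }

  P <- data$protein_uM
  D <- data$dna_uM
  obs <- as.matrix(data[, c("f1", "f2", "f3")])
  sw <- sqrt(weights)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = macrofit_residuals,
                         P = P, D = D, obs = obs, sw = sw,
                         conservation = ligand_conservation, control = ctrl),
      error = function(e) NULL)
  }
  ok <- vapply(fits, function(f)
    !is.null(f) && length(f$info) == 1 && f$info %in% 1:4, logical(1))
  if (!any(ok))
    stop_bindpoly("no multistart initialisation converged",
                  "bindpoly_convergence_error")
  fits <- fits[ok]
  rss <- vapply(fits, function(f) sum(f$fvec^2), numeric(1))
  best_rss <- min(rss)
  cand <- which(rss - best_rss < 1e-9)
  norms <- vapply(fits[cand], function(f) sqrt(sum(f$par^2)), numeric(1))
  fit <- fits[[cand[which.min(norms)]]]

  logK <- fit$par
  K <- 10^logK

  # delta-method SEs: J'J on the log10 scale by central differences
  se <- rep(NA_real_, 3)
  nobs <- 3 * nrow(data)
  if (nobs > 3) {
    J <- matrix(NA_real_, nobs, 3)
    h <- 1e-6
    for (j in 1:3) {
      up <- logK; up[j] <- up[j] + h
      dn <- logK; dn[j] <- dn[j] - h
      J[, j] <- (macrofit_residuals(up, P, D, obs, sw, ligand_conservation) -
                 macrofit_residuals(dn, P, D, obs, sw, ligand_conservation)) / (2 * h)
    }
    sigma2 <- sum(fit$fvec^2) / (nobs - 3)
    covlog <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(covlog) && all(diag(covlog) >= 0))
      se <- K * log(10) * sqrt(diag(covlog))
  }
  names(se) <- c("K1", "K2", "K3")

  L <- free_ligand(data$protein_uM, data$dna_uM, K, ligand_conservation)
  structure(list(
    K = macro_constants(K[1], K[2], K[3]),
    logK = stats::setNames(logK, c("K1", "K2", "K3")),
    se = se,
    rss = sum(fit$fvec^2),
    converged = TRUE,
    n_starts_used = nrow(starts),
    ligand_conservation = ligand_conservation,
    weights = weights,
    data = data,
    fitted = species_fractions(L, K)
  ), class = "macrofit")
}

#' @export
coef.macrofit <- function(object, ...) unclass(object$K)

#' @export
print.macrofit <- function(x, ...) {
  cat("Three-site binding-polynomial fit\n")
  cat(sprintf("  K1 = %.4g uM^-1 (SE %.3g)\n", x$K[1], x$se[1]))
  cat(sprintf("  K2 = %.4g uM^-2 (SE %.3g)\n", x$K[2], x$se[2]))
  cat(sprintf("  K3 = %.4g uM^-3 (SE %.3g)\n", x$K[3], x$se[3]))
  cat(sprintf("  RSS = %.4g on %d titration points (%s free-ligand rule)\n",
              x$rss, nrow(x$data), x$ligand_conservation))
  invisible(x)
}

#' @export
summary.macrofit <- function(object, ...) {
  r <- cooperativity_ratios(object$K)
  ka <- tryCatch(ka_from_macro(object$K), error = function(e) NULL)
  out <- list(fit = object, ratios = r, ka = ka)
  class(out) <- "summary.macrofit"
  out
}

#' @export
print.summary.macrofit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  cooperativity ratios: r2 = %.4g, r3 = %.4g (1 = independent)\n",
              x$ratios["r2"], x$ratios["r3"]))
  if (!is.null(x$ka))
    cat(sprintf("  identical-site reduction: Ka = %.4g uM^-1, Kd = %.4g uM\n",
                x$ka$Ka, x$ka$Kd))
  invisible(x)
}

#' @export
predict.macrofit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  L <- if (is.data.frame(newdata)) newdata$protein_uM else as.numeric(newdata)
  species_fractions(L, object$K)
}

#' @export
fitted.macrofit <- function(object, ...) object$fitted

#' @export
residuals.macrofit <- function(object, ...) {
  obs <- as.matrix(object$data[, c("f0", "f1", "f2", "f3")])
  pred <- as.matrix(object$fitted[, c("theta0", "theta1", "theta2", "theta3")])
  res <- obs - pred
  colnames(res) <- c("f0", "f1", "f2", "f3")
  res
}

#' @export
plot.macrofit <- function(x, n_grid = 200, ...) {
  d <- x$data
  Lg <- seq(min(d$protein_uM), max(d$protein_uM), length.out = n_grid)
  th <- species_fractions(free_ligand(Lg, rep(mean(d$dna_uM), n_grid), coef(x),
                                      x$ligand_conservation), coef(x))
  cols <- c("black", "#1b9e77", "#d95f02", "#7570b3")
  graphics::matplot(d$protein_uM, d[, c("f0", "f1", "f2", "f3")],
                    pch = 19, col = cols, xlab = "protein (uM)",
                    ylab = "fraction of DNA", ylim = c(0, 1), ...)
  graphics::matlines(Lg, th[, c("theta0", "theta1", "theta2", "theta3")],
                     lty = 1, col = cols)
  graphics::legend("right", legend = c("free", "C1", "C2", "C3"),
                   col = cols, pch = 19, bty = "n")
  invisible(x)
}

#' Simulate titrations from a fitted three-site model
#'
#' Draws new Dirichlet-noised titration datasets at the fitted constants and
#' the observed concentration grid.
#'
#' @param object A `"macrofit"` object.
#' @param nsim Number of simulated datasets.
#' @param seed Integer seed (mandatory: all randomness in the package is
#'   explicitly seeded).
#' @param noise Dirichlet concentration parameter (0 = noiseless).
#' @param ... Unused.
#' @return A list of `nsim` titration data frames.
#' @export
simulate.macrofit <- function(object, nsim = 1, seed, noise = 300, ...) {
  grid <- sort(unique(object$data$protein_uM))
  dna <- mean(object$data$dna_uM)
  lapply(seq_len(nsim), function(i)
    simulate_titration(K = coef(object), grid = grid, dna_uM = dna,
                       reps = 1, noise = noise, seed = seed + i - 1))
}

#' Bootstrap uncertainty for macroscopic constants and derived statistics
#'
#' Case-resampling bootstrap over concentration points within each replicate:
#' every resample redraws the rows of each replicate with replacement, refits
#' the three-site model (started from the full-data estimate), and records
#' `(K1, K2, K3)`, the cooperativity ratios and the identical-site `Ka`
#' (averaged across replicates within a resample). Resamples that fail to
#' converge are dropped and counted. Deterministic given `seed`.
#'
#' @param data Titration data frame (one or more replicates).
#' @param n_boot Number of bootstrap resamples, `>= 100` (default 1000).
#' @param seed Integer seed (mandatory).
#' @param ... Passed to [fit_macroscopic()] (e.g. `ligand_conservation`).
#' @return An object of class `"bindpoly_boot"`: list with `draws` (data frame
#'   of `K1, K2, K3, r2, r3, Ka` per successful resample), `n_boot`,
#'   `n_failed` and `seed`.
#' @export
bootstrap_uncertainty <- function(data, n_boot = 1000, seed, ...) {
  if (missing(seed)) stop_bindpoly("seed is mandatory", "bindpoly_invalid_input")
  if (n_boot < 100)
    stop_bindpoly("n_boot must be >= 100", "bindpoly_invalid_input")
  data <- validate_titration(data)
  reps <- split(data, data$replicate)
  full <- lapply(reps, fit_macroscopic, ...)

  one_draw <- function() {
    per_rep <- lapply(seq_along(reps), function(j) {
      d <- reps[[j]]
      idx <- sample.int(nrow(d), nrow(d), replace = TRUE)
      fit <- tryCatch(
        fit_macroscopic(d[idx, , drop = FALSE], start = full[[j]]$logK, ...),
        error = function(e) NULL)
      if (is.null(fit))
        fit <- tryCatch(fit_macroscopic(d[idx, , drop = FALSE], ...),
                        error = function(e) NULL)
      fit
    })
    if (any(vapply(per_rep, is.null, logical(1)))) return(NULL)
    Ks <- t(vapply(per_rep, coef, numeric(3)))
    rs <- t(vapply(per_rep, function(f)
      suppressWarnings(cooperativity_ratios(f$K)), numeric(2)))
    kas <- vapply(per_rep, function(f)
      tryCatch(ka_from_macro(f$K)$Ka, error = function(e) NA_real_), numeric(1))
    c(colMeans(Ks), colMeans(rs), Ka = mean(kas))
  }

  draws <- with_seed(seed, {
    out <- vector("list", n_boot)
    for (b in seq_len(n_boot)) out[[b]] <- one_draw()
    out
  })
  failed <- vapply(draws, is.null, logical(1))
  draws <- do.call(rbind, draws[!failed])
  draws <- as.data.frame(draws)
  names(draws) <- c("K1", "K2", "K3", "r2", "r3", "Ka")
  structure(list(draws = draws, n_boot = n_boot, n_failed = sum(failed),
                 seed = seed),
            class = "bindpoly_boot")
}

#' @export
print.bindpoly_boot <- function(x, ...) {
  cat(sprintf("Bootstrap of the three-site fit: %d resamples (%d failed), seed %d\n",
              x$n_boot, x$n_failed, x$seed))
  print(vapply(x$draws, stats::quantile,
               probs = c(0.025, 0.5, 0.975), FUN.VALUE = numeric(3)))
  invisible(x)
}

#' Cooperativity verdicts and identical-site Ka/Kd reduction
#'
#' Summarises per-replicate three-site fits into the cooperativity report:
#' ratio statistics `r2`, `r3` as mean +/- SD across replicates, a verdict per
#' binding event, and — when no event is judged cooperative — the per-site
#' association constant `Ka` (mean +/- SD across replicates via
#' [ka_from_macro()]) and `Kd = 1/Ka_mean`.
#'
#' The verdict rule is conservative: event j is called `"cooperative"` only if
#' the bootstrap lower 2.5% bound of `rj` exceeds 1; otherwise
#' `"not-inferred"`. If a cooperative verdict is issued the identical-site
#' reduction is refused (the reduction assumes independence), and `Ka`/`Kd`
#' are reported as `NA`.
#'
#' @param fits A `"macrofit"` object or list of them (one per replicate).
#' @param boot A `"bindpoly_boot"` object from [bootstrap_uncertainty()]
#'   computed on the same data.
#' @return An object of class `"coop_report"`.
#' @export
assess_cooperativity <- function(fits, boot) {
  if (inherits(fits, "macrofit")) fits <- list(fits)
  if (!length(fits) || !all(vapply(fits, inherits, logical(1), "macrofit")))
    stop_bindpoly("fits must be one or more macrofit objects",
                  "bindpoly_invalid_input")
  if (!inherits(boot, "bindpoly_boot"))
    stop_bindpoly("boot must come from bootstrap_uncertainty()",
                  "bindpoly_invalid_input")

  rs <- t(vapply(fits, function(f)
    suppressWarnings(cooperativity_ratios(f$K)), numeric(2)))
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  r2_mean <- mean(rs[, "r2"]); r2_sd <- sd0(rs[, "r2"])
  r3_mean <- mean(rs[, "r3"]); r3_sd <- sd0(rs[, "r3"])

  lb <- function(v) stats::quantile(v, 0.025, na.rm = TRUE, names = FALSE)
  verdict2 <- if (lb(boot$draws$r2) > 1) "cooperative" else "not-inferred"
  verdict3 <- if (lb(boot$draws$r3) > 1) "cooperative" else "not-inferred"
  cooperative <- verdict2 == "cooperative" || verdict3 == "cooperative"

  if (cooperative) {
    Ka_mean <- NA_real_; Ka_sd <- NA_real_; Kd <- NA_real_
  } else {
    kas <- vapply(fits, function(f) ka_from_macro(f$K)$Ka, numeric(1))
    Ka_mean <- mean(kas); Ka_sd <- sd0(kas); Kd <- 1 / Ka_mean
  }

  structure(list(
    r2_mean = r2_mean, r2_sd = r2_sd,
    r3_mean = r3_mean, r3_sd = r3_sd,
    r2_boot_sd = stats::sd(boot$draws$r2, na.rm = TRUE),
    r3_boot_sd = stats::sd(boot$draws$r3, na.rm = TRUE),
    Ka_boot_sd = stats::sd(boot$draws$Ka, na.rm = TRUE),
    verdict2 = verdict2, verdict3 = verdict3,
    Ka_mean = Ka_mean, Ka_sd = Ka_sd, Kd = Kd,
    K_mean = colMeans(t(vapply(fits, coef, numeric(3)))),
    n_replicates = length(fits),
    n_bootstrap = nrow(boot$draws),
    seed = boot$seed
  ), class = "coop_report")
}

#' @export
print.coop_report <- function(x, ...) {
  cat("Cooperativity report (three identical DNA repeats)\n")
  cat(sprintf("  r2 = %.3g +/- %.2g (bootstrap SD %.2g): %s\n",
              x$r2_mean, x$r2_sd, x$r2_boot_sd, x$verdict2))
  cat(sprintf("  r3 = %.3g +/- %.2g (bootstrap SD %.2g): %s\n",
              x$r3_mean, x$r3_sd, x$r3_boot_sd, x$verdict3))
  cat(sprintf("  verdict rule: bootstrap lower 2.5%% bound of rj > 1 (%d resamples)\n",
              x$n_bootstrap))
  if (is.na(x$Ka_mean)) {
    cat("  identical-site Ka reduction refused: a cooperative verdict was issued\n")
  } else {
    cat(sprintf("  per-site Ka = %.3g +/- %.2g uM^-1;  Kd = 1/Ka = %.3g uM\n",
                x$Ka_mean, x$Ka_sd, x$Kd))
  }
  cat(sprintf("  replicates: %d\n", x$n_replicates))
  invisible(x)
}
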