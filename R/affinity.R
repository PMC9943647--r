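## Single-site affinity: hyperbolic saturation fits shared between EMSA
## fraction-bound curves and SPR steady-state responses, the active-fraction
## determination, and group comparison of replicate Kd values.

#' Fit a one-site saturation hyperbola
#'
#' Weighted least-squares fit of `y = Bmax * x / (Kd + x)` to a binding
#' curve, the model for fraction of complexed DNA versus protein
#' concentration. The same core serves EMSA fraction-bound data and SPR
#' steady-state responses (see [fit_spr_steady_state()]), where `Bmax` is the
#' maximal response `Rmax` in response units.
#'
#' @param x Ligand concentrations (uM), at least 3 distinct values.
#' @param y Response at each `x` (fraction bound, or RU for SPR).
#' @param weights Optional positive weights, one per point.
#' @param fix_bmax If non-`NULL`, `Bmax` is fixed at this value and only `Kd`
#'   is estimated.
#' @param response_unit Label used by the print method (`"fraction"` or
#'   `"RU"`).
#' @return An object of class `"hyperfit"`: list with `Kd`, `Bmax`, `se`
#'   (standard errors), `rss`, `converged`, `poorly_constrained` (`TRUE` when
#'   the fitted `Kd` falls outside `(min(x>0)/100, 100*max(x))`), and the
#'   data.
#' @examples
#' x <- c(0.25, 0.5, 1, 2, 4, 8, 16, 32)
#' fit <- fit_hyperbola(x, 0.9 * x / (1.1 + x))
#' coef(fit)                       # Kd = 1.1 uM, Bmax = 0.9
#' predict(fit, newdata = 1.1)     # half-saturation: Bmax / 2
#' @export
fit_hyperbola <- function(x, y, weights = NULL, fix_bmax = NULL,
                          response_unit = "fraction") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop_bindpoly("x and y must have equal length", "bindpoly_invalid_input")
  if (anyNA(x) || anyNA(y) || any(x < 0))
    stop_bindpoly("x must be non-negative and x, y free of NAs",
                  "bindpoly_invalid_input")
  if (length(unique(x)) < 3)
    stop_bindpoly("at least 3 distinct concentrations are required",
                  "bindpoly_invalid_input")
  if (max(y) <= 0)
    stop_bindpoly("no binding signal: max(y) must be > 0",
                  "bindpoly_invalid_input")
  if (is.null(weights)) weights <- rep(1, length(x))
  if (length(weights) != length(x) || any(weights <= 0))
    stop_bindpoly("weights must be positive, one per point",
                  "bindpoly_invalid_input")

  bmax0 <- max(y)
  xpos <- x[x > 0]
  kd0 <- xpos[which.min(abs(y[x > 0] - bmax0 / 2))]
  if (!length(kd0) || kd0 <= 0) kd0 <- stats::median(xpos)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15, ptol = 1e-15)

  # Levenberg-Marquardt on the log scale: positivity for free, and robust to
  # nearly flat curves that defeat the nls() gradient check
  sw <- sqrt(weights)
  resid_fn <- function(p) {
    Kd <- 10^p[1]
    Bmax <- if (is.null(fix_bmax)) 10^p[2] else fix_bmax
    sw * (y - Bmax * x / (Kd + x))
  }
  p0 <- if (is.null(fix_bmax)) log10(c(kd0, bmax0)) else log10(kd0)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid_fn, control = ctrl)
  if (!(length(fit$info) == 1 && fit$info %in% 1:4))
    stop_bindpoly("hyperbolic fit did not converge",
                  "bindpoly_convergence_error")
  Kd <- 10^fit$par[1]
  Bmax <- if (is.null(fix_bmax)) 10^fit$par[2] else fix_bmax

  # delta-method SEs from a finite-difference Jacobian on the log scale
  npar <- length(fit$par)
  se <- c(Kd = NA_real_, Bmax = if (is.null(fix_bmax)) NA_real_ else 0)
  if (length(x) > npar) {
    J <- matrix(NA_real_, length(x), npar)
    h <- 1e-6
    for (j in seq_len(npar)) {
      up <- fit$par; up[j] <- up[j] + h
      dn <- fit$par; dn[j] <- dn[j] - h
      J[, j] <- (resid_fn(up) - resid_fn(dn)) / (2 * h)
    }
    sigma2 <- sum(fit$fvec^2) / (length(x) - npar)
    covlog <- tryCatch(sigma2 * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(covlog) && all(diag(covlog) >= 0)) {
      se["Kd"] <- Kd * log(10) * sqrt(covlog[1, 1])
      if (is.null(fix_bmax))
        se["Bmax"] <- Bmax * log(10) * sqrt(covlog[2, 2])
    }
  }
  poorly <- Kd < min(xpos) / 100 || Kd > 100 * max(x)
  if (poorly)
    warning("fitted Kd lies outside (min(x)/100, 100*max(x)): poorly constrained",
            call. = FALSE)
  structure(list(
    Kd = Kd, Bmax = Bmax, se = se,
    rss = sum(fit$fvec^2),
    converged = TRUE,
    poorly_constrained = poorly,
    bmax_fixed = !is.null(fix_bmax),
    response_unit = response_unit,
    data = df, weights = weights
  ), class = "hyperfit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit an SPR steady-state one-site saturation model
#'
#' Fits `Req = Rmax * conc / (Kd + conc)` to steady-state SPR responses —
#' the same hyperbolic core as [fit_hyperbola()], with the plateau
#' interpreted as the maximal response `Rmax` in response units.
#'
#' @param conc Analyte concentrations (uM), at least 3 distinct values.
#' @param Req Steady-state responses (RU).
#' @inheritParams fit_hyperbola
#' @return A `"hyperfit"` object; `Bmax` holds `Rmax` (RU).
#' @examples
#' conc <- c(0.1, 0.25, 0.5, 0.75, 1)
#' fit <- fit_spr_steady_state(conc, 100 * conc / (0.22 + conc))
#' coef(fit)    # Kd = 0.22 uM, Rmax = 100 RU
#' @export
fit_spr_steady_state <- function(conc, Req, weights = NULL, fix_bmax = NULL) {
  fit_hyperbola(conc, Req, weights = weights, fix_bmax = fix_bmax,
                response_unit = "RU")
}

#' @export
coef.hyperfit <- function(object, ...)
  c(Kd = object$Kd, Bmax = object$Bmax)

#' @export
print.hyperfit <- function(x, ...) {
  lab <- if (x$response_unit == "RU") "Rmax" else "Bmax"
  cat("One-site saturation fit: y = Bmax * x / (Kd + x)\n")
  cat(sprintf("  Kd   = %.4g uM (SE %.3g)\n", x$Kd, x$se["Kd"]))
  cat(sprintf("  %s = %.4g %s%s (SE %.3g)\n", lab, x$Bmax,
              x$response_unit, if (x$bmax_fixed) " [fixed]" else "",
              x$se["Bmax"]))
  cat(sprintf("  RSS = %.4g on %d points\n", x$rss, nrow(x$data)))
  if (x$poorly_constrained)
    cat("  warning: Kd poorly constrained by the concentration range\n")
  invisible(x)
}

#' @export
summary.hyperfit <- function(object, ...) object

#' @export
predict.hyperfit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x
       else if (is.data.frame(newdata)) newdata$x
       else as.numeric(newdata)
  object$Bmax * x / (object$Kd + x)
}

#' @export
residuals.hyperfit <- function(object, ...)
  object$data$y - predict(object)

#' @export
plot.hyperfit <- function(x, n_grid = 200, ...) {
  d <- x$data
  xg <- seq(0, max(d$x), length.out = n_grid)
  graphics::plot(d$x, d$y, pch = 19, xlab = "concentration (uM)",
                 ylab = paste0("response (", x$response_unit, ")"), ...)
  graphics::lines(xg, predict(x, xg))
  graphics::abline(v = x$Kd, lty = 3)
  invisible(x)
}

#' Active fraction of a protein preparation
#'
#' Under stoichiometric binding conditions (DNA in molar excess, 1:1
#' complex), the concentration of protein-DNA complex measures the
#' binding-competent protein: `active = bound_complex / protein_total`.
#' Values above 1 (quantification error) are clipped to 1 with a warning and
#' flagged.
#'
#' @param bound_complex Complex concentration (uM).
#' @param protein_total Total protein concentration (uM), `> 0`.
#' @return The active fraction (numeric in `[0, 1]`) with attribute
#'   `over_unity` indicating whether clipping occurred.
#' @examples
#' active_fraction(0.93, 1.0)   # 93% active preparation
#' @export
active_fraction <- function(bound_complex, protein_total) {
  if (!is.numeric(protein_total) || length(protein_total) != 1 ||
      is.na(protein_total) || protein_total <= 0)
    stop_bindpoly("protein_total must be a single positive concentration",
                  "bindpoly_invalid_input")
  if (!is.numeric(bound_complex) || length(bound_complex) != 1 ||
      is.na(bound_complex) || bound_complex < 0)
    stop_bindpoly("bound_complex must be a single non-negative concentration",
                  "bindpoly_invalid_input")
  f <- bound_complex / protein_total
  over <- f > 1
  if (over) {
    warning(sprintf("active fraction %.3g exceeds 1; clipped (check stoichiometry)",
                    f), call. = FALSE)
    f <- 1
  }
  structure(f, over_unity = over)
}

#' Compare dissociation constants between groups
#'
#' One-way fixed-effects ANOVA across two or more groups of replicate Kd
#' values, or a two-sample t test (equal-variance by default, Welch by flag)
#' for exactly two groups. Raw p-values are reported; no multiple-testing
#' correction is applied.
#'
#' @param groups A list of numeric vectors of replicate Kd values (uM); for
#'   ANOVA at least 2 groups of at least 2 values each, for the t test
#'   exactly 2 groups.
#' @param mode `"anova"` or `"ttest"`.
#' @param welch For `mode = "ttest"`, use the Welch (unequal-variance)
#'   variant. Default `FALSE` (Student's equal-variance t).
#' @return A list with `statistic`, `p_value`, `df` and `method`.
#' @examples
#' compare_affinity_groups(list(wt = c(1.0, 1.2, 1.1), mut = c(5.0, 5.5, 6.0)),
#'                         mode = "ttest")
#' @export
compare_affinity_groups <- function(groups, mode = c("anova", "ttest"),
                                    welch = FALSE) {
  mode <- match.arg(mode)
  if (!is.list(groups) || length(groups) < 2)
    stop_bindpoly("groups must be a list of >= 2 numeric vectors",
                  "bindpoly_invalid_input")
  sizes <- lengths(groups)
  if (any(sizes < 2))
    stop_bindpoly("each group needs >= 2 replicate values",
                  "bindpoly_invalid_input")
  if (mode == "ttest") {
    if (length(groups) != 2)
      stop_bindpoly("t-test mode requires exactly 2 groups",
                    "bindpoly_invalid_input")
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = !welch)
    return(list(statistic = unname(tt$statistic),
                p_value = tt$p.value,
                df = unname(tt$parameter),
                method = if (welch) "Welch two-sample t test"
                         else "Student's equal-variance t test"))
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), sizes))
  tab <- stats::anova(stats::aov(values ~ labels))
  list(statistic = tab[["F value"]][1],
       p_value = tab[["Pr(>F)"]][1],
       df = c(between = tab[["Df"]][1], within = tab[["Df"]][2]),
       method = "one-way fixed-effects ANOVA")
}
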