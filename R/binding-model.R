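#' @keywords internal
"_PACKAGE"

## Package-wide unit convention: concentrations in uM, so K1, K2, K3 carry
## uM^-1, uM^-2, uM^-3 and every product Ki * L^i is dimensionless. Values are
## never auto-converted.

stop_bindpoly <- function(msg, class) {
  stop(structure(
    class = c(class, "bindpoly_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Microscopic binding constants for a three-site DNA
#'
#' Container for the intrinsic per-site association constants `k1`, `k2`, `k3`
#' (uM^-1) and the pairwise cooperativity factors `k12`, `k13`, `k23`
#' (dimensionless). Setting all couplings to 1 and `k1 = k2 = k3` encodes the
#' identical-independent-site case.
#'
#' @param k1,k2,k3 Intrinsic site association constants (uM^-1), `>= 0`.
#' @param k12,k13,k23 Pairwise cooperativity factors (dimensionless), `>= 0`;
#'   1 means no coupling.
#' @return A named numeric vector of class `"micro_constants"`.
#' @examples
#' micro_constants(1, 1, 1)             # identical independent sites
#' micro_constants(1, 1, 1, k12 = 10)   # coupling between sites 1 and 2
#' @export
micro_constants <- function(k1, k2, k3, k12 = 1, k13 = 1, k23 = 1) {
  m <- c(k1 = k1, k2 = k2, k3 = k3, k12 = k12, k13 = k13, k23 = k23)
  m <- vapply(m, as.numeric, numeric(1))
  if (anyNA(m) || any(m < 0))
    stop_bindpoly("all microscopic constants must be finite and >= 0",
                  "bindpoly_invalid_input")
  structure(m, class = "micro_constants")
}

#' Macroscopic binding constants (binding-polynomial coefficients)
#'
#' The coefficients of the binding polynomial
#' `Z = 1 + K1*L + K2*L^2 + K3*L^3`, with `K1` in uM^-1, `K2` in uM^-2 and
#' `K3` in uM^-3 so that each `Ki * L^i` is dimensionless for `L` in uM.
#'
#' @param K1,K2,K3 Macroscopic association constants, `>= 0`.
#' @return A named numeric vector of class `"macro_constants"`.
#' @export
macro_constants <- function(K1, K2, K3) {
  K <- c(K1 = as.numeric(K1), K2 = as.numeric(K2), K3 = as.numeric(K3))
  if (anyNA(K) || any(K < 0))
    stop_bindpoly("all macroscopic constants must be finite and >= 0",
                  "bindpoly_invalid_input")
  structure(K, class = "macro_constants")
}

as_macro <- function(K) {
  if (inherits(K, "macro_constants")) return(unclass(K))
  K <- as.numeric(K)
  if (length(K) != 3 || anyNA(K) || any(K < 0))
    stop_bindpoly("K must be three non-negative numbers (K1, K2, K3)",
                  "bindpoly_invalid_input")
  names(K) <- c("K1", "K2", "K3")
  K
}

as_micro <- function(m) {
  if (inherits(m, "micro_constants")) return(unclass(m))
  m <- as.numeric(m)
  if (length(m) != 6 || anyNA(m) || any(m < 0))
    stop_bindpoly("m must be six non-negative numbers (k1, k2, k3, k12, k13, k23)",
                  "bindpoly_invalid_input")
  names(m) <- c("k1", "k2", "k3", "k12", "k13", "k23")
  m
}

#' Ligation-state fractions from the three-site binding polynomial
#'
#' Evaluates the fractions of DNA molecules carrying exactly 0, 1, 2 or 3
#' bound ligands at free ligand concentration `L`:
#' `theta_i = Ki * L^i / Z` with `Z = 1 + K1*L + K2*L^2 + K3*L^3` (and
#' `K0 = 1`). The fractions sum to one by construction.
#'
#' @param L Free ligand concentration(s) in uM, `>= 0`; vectorised.
#' @param K Macroscopic constants: a [macro_constants()] object or a numeric
#'   vector `c(K1, K2, K3)`.
#' @return A data frame with columns `L`, `theta0`..`theta3` and `Z`, one row
#'   per element of `L`.
#' @examples
#' species_fractions(1, c(3, 3, 3))        # Z = 10, fractions .1/.3/.3/.3
#' species_fractions(c(0, 0.5, 2), macro_constants(3.6, 4.32, 5.184))
#' @export
species_fractions <- function(L, K) {
  K <- as_macro(K)
  L <- as.numeric(L)
  if (length(L) < 1 || anyNA(L) || any(L < 0))
    stop_bindpoly("L must be non-negative ligand concentration(s) in uM",
                  "bindpoly_invalid_input")
  Z <- 1 + K[1] * L + K[2] * L^2 + K[3] * L^3
  data.frame(
    L = L,
    theta0 = 1 / Z,
    theta1 = K[1] * L / Z,
    theta2 = K[2] * L^2 / Z,
    theta3 = K[3] * L^3 / Z,
    Z = Z,
    row.names = NULL
  )
}

#' Macroscopic constants from microscopic constants
#'
#' Combines intrinsic site constants and pairwise couplings into the
#' coefficients of the binding polynomial:
#' `K1 = k1 + k2 + k3`,
#' `K2 = k1*k2*k12 + k1*k3*k13 + k2*k3*k23`, and (default convention)
#' `K3 = k1*k2*k3 * (k12 + k13 + k23)`.
#'
#' The triply liganded coefficient is the pairwise-additive sum form. Under
#' it the identical-independent limit (`ki = Ka`, couplings 1) gives
#' `K = (3*Ka, 3*Ka^2, 3*Ka^3)` rather than the binomial `(3*Ka, 3*Ka^2,
#' Ka^3)`; `triple_term = "product"` selects the alternative
#' `K3 = k1*k2*k3*k12*k13*k23` for comparison.
#'
#' @param m Microscopic constants: a [micro_constants()] object or a numeric
#'   vector `c(k1, k2, k3, k12, k13, k23)`.
#' @param triple_term Convention for the triply liganded statistical weight:
#'   `"sum"` (default) or `"product"`.
#' @return A [macro_constants()] object.
#' @examples
#' macro_from_micro(micro_constants(1, 1, 1))        # (3, 3, 3)
#' macro_from_micro(micro_constants(2, 1, 1))        # (4, 5, 6)
#' @export
macro_from_micro <- function(m, triple_term = c("sum", "product")) {
  m <- as_micro(m)
  triple_term <- match.arg(triple_term)
  K1 <- m["k1"] + m["k2"] + m["k3"]
  K2 <- m["k1"] * m["k2"] * m["k12"] +
        m["k1"] * m["k3"] * m["k13"] +
        m["k2"] * m["k3"] * m["k23"]
  K3 <- if (triple_term == "sum") {
    m["k1"] * m["k2"] * m["k3"] * (m["k12"] + m["k13"] + m["k23"])
  } else {
    m["k1"] * m["k2"] * m["k3"] * m["k12"] * m["k13"] * m["k23"]
  }
  macro_constants(unname(K1), unname(K2), unname(K3))
}

#' Ligation-state fractions by direct microstate enumeration
#'
#' Independent check on [species_fractions()]: enumerates the statistical
#' weight of every ligation configuration of the three sites — unliganded 1;
#' singly liganded at site i, `ki*L`; doubly liganded at sites i,j,
#' `ki*kj*kij*L^2`; triply liganded, `k1*k2*k3*(k12+k13+k23)*L^3` under the
#' default sum convention — sums them into the partition function and returns
#' the per-occupancy fractions. Agrees with
#' `species_fractions(L, macro_from_micro(m))` to machine precision.
#'
#' @inheritParams macro_from_micro
#' @param L Free ligand concentration(s) in uM, `>= 0`.
#' @return A data frame in the same layout as [species_fractions()].
#' @export
microstate_oracle <- function(m, L, triple_term = c("sum", "product")) {
  m <- as_micro(m)
  triple_term <- match.arg(triple_term)
  L <- as.numeric(L)
  if (length(L) < 1 || anyNA(L) || any(L < 0))
    stop_bindpoly("L must be non-negative ligand concentration(s) in uM",
                  "bindpoly_invalid_input")
  k1 <- unname(m["k1"]); k2 <- unname(m["k2"]); k3 <- unname(m["k3"])
  k12 <- unname(m["k12"]); k13 <- unname(m["k13"]); k23 <- unname(m["k23"])
  out <- lapply(L, function(l) {
    w0 <- 1
    w1 <- c(k1, k2, k3) * l                       # {1}, {2}, {3}
    w2 <- c(k1 * k2 * k12, k1 * k3 * k13, k2 * k3 * k23) * l^2  # {12},{13},{23}
    w3 <- if (triple_term == "sum") {
      k1 * k2 * k3 * (k12 + k13 + k23) * l^3
    } else {
      k1 * k2 * k3 * k12 * k13 * k23 * l^3
    }
    Z <- w0 + sum(w1) + sum(w2) + w3
    c(theta0 = w0 / Z, theta1 = sum(w1) / Z, theta2 = sum(w2) / Z,
      theta3 = w3 / Z, Z = Z)
  })
  out <- do.call(rbind, out)
  data.frame(L = L, theta0 = out[, "theta0"], theta1 = out[, "theta1"],
             theta2 = out[, "theta2"], theta3 = out[, "theta3"],
             Z = out[, "Z"], row.names = NULL)
}

#' Cooperativity ratio statistics
#'
#' For a three-site system the second and third binding events are cooperative
#' when `K2 > K1^2 / 3` and `K3 > K2*K1 / 3` respectively. This returns the
#' corresponding ratio statistics `r2 = 3*K2 / K1^2` and
#' `r3 = 3*K3 / (K1*K2)`; a value above 1 signals cooperativity for that
#' event, and identical independent sites give exactly `(1, 1)`.
#'
#' If `K1 = 0` neither ratio is defined and an error is raised. If only
#' `K1*K2 = 0`, `r3` is returned as `NA` with a warning naming it.
#'
#' @inheritParams species_fractions
#' @return A named numeric vector `c(r2 = , r3 = )`.
#' @examples
#' cooperativity_ratios(c(3, 3, 3))   # (1, 1): no cooperativity signal
#' cooperativity_ratios(c(4, 5, 6))   # (0.9375, 0.9)
#' @export
cooperativity_ratios <- function(K) {
  K <- as_macro(K)
  if (K[1] <= 0)
    stop_bindpoly("r2 undefined: K1 is zero", "bindpoly_undefined_ratio")
  r2 <- 3 * K[2] / K[1]^2
  if (K[1] * K[2] <= 0) {
    warning("r3 undefined: K1*K2 is zero; returning NA for r3",
            call. = FALSE)
    r3 <- NA_real_
  } else {
    r3 <- 3 * K[3] / (K[1] * K[2])
  }
  c(r2 = unname(r2), r3 = unname(r3))
}

#' Per-site association constant under identical independent sites
#'
#' When the three sites are identical and independent the macroscopic
#' constants reduce to `K1 = 3*Ka`, `K2 = 3*Ka^2`, `K3 = 3*Ka^3`, so each
#' order gives an estimate of the per-site association constant:
#' `K1/3`, `sqrt(K2/3)` and `(K3/3)^(1/3)`. The combined `Ka` is the
#' arithmetic mean of the three estimates and `Kd = 1/Ka`.
#'
#' @inheritParams species_fractions
#' @return A list with `estimates` (the three per-order Ka values, uM^-1),
#'   `Ka` (their mean, uM^-1) and `Kd` (uM).
#' @examples
#' ka_from_macro(c(3.6, 4.32, 5.184))   # Ka = 1.2, Kd ~ 0.83 uM
#' @export
ka_from_macro <- function(K) {
  K <- as_macro(K)
  if (any(K <= 0))
    stop_bindpoly("Ka reduction requires K1, K2, K3 > 0",
                  "bindpoly_invalid_input")
  est <- c(K1 = unname(K[1] / 3),
           K2 = unname(sqrt(K[2] / 3)),
           K3 = unname((K[3] / 3)^(1 / 3)))
  Ka <- mean(est)
  list(estimates = est, Ka = Ka, Kd = 1 / Ka)
}

#' Macroscopic constants implied by a per-site Ka
#'
#' Inverse of [ka_from_macro()] for identical independent sites:
#' `K = (3*Ka, 3*Ka^2, 3*Ka^3)`.
#'
#' @param Ka Per-site association constant (uM^-1), `> 0`.
#' @return A [macro_constants()] object.
#' @export
macro_from_ka <- function(Ka) {
  Ka <- as.numeric(Ka)
  if (length(Ka) != 1 || is.na(Ka) || Ka <= 0)
    stop_bindpoly("Ka must be a single positive number (uM^-1)",
                  "bindpoly_invalid_input")
  macro_constants(3 * Ka, 3 * Ka^2, 3 * Ka^3)
}
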