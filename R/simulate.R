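## Seeded generators emulating each experimental input at desk scale. The
## defaults reproduce the published experimental designs: a 0.1-1.3 uM
## protein grid with 20 nM three-repeat DNA for the cooperativity EMSA, a
## 0.5-50 uM range for single-repeat EMSAs, the five-concentration SPR
## injection series, and a chase sampled from 10 s. Noiseless mode
## (noise/sigma = 0) reproduces the forward model exactly; the same seed
## gives bit-identical output.

#' Simulate a three-site EMSA titration
#'
#' Generates ligation-state fractions on a protein-concentration grid from
#' the three-site binding polynomial, with compositional noise: each row's
#' fractions are drawn from a Dirichlet with mean equal to the model
#' `(theta0..theta3)` and concentration parameter `noise` (larger = tighter;
#' 0 = exact model values). The grid concentration is used as the free-ligand
#' value, matching the total-protein approximation used by default in
#' [fit_macroscopic()] (DNA at tens of nM depletes at most a few percent of
#' the protein).
#'
#' @param Ka Per-site association constant (uM^-1) for identical independent
#'   sites; used when `K` is not given, via `K = (3Ka, 3Ka^2, 3Ka^3)`.
#' @param K Macroscopic constants `c(K1, K2, K3)`; overrides `Ka`.
#' @param grid Protein concentrations (uM). Default: 12 points over the
#'   0.1-1.3 uM range of the published cooperativity EMSA.
#' @param dna_uM Labelled DNA concentration (uM). Default 0.02 (20 nM).
#' @param reps Number of replicates.
#' @param noise Dirichlet concentration parameter (0 = noiseless).
#' @param seed Integer seed (mandatory).
#' @return A titration data frame with columns `replicate`, `protein_uM`,
#'   `dna_uM`, `f0`..`f3`.
#' @examples
#' simulate_titration(Ka = 1.2, noise = 300, seed = 42)
#' @export
simulate_titration <- function(Ka = NULL, K = NULL,
                               grid = seq(0.1, 1.3, length.out = 12),
                               dna_uM = 0.02, reps = 1, noise = 300, seed) {
  if (is.null(K)) {
    if (is.null(Ka))
      stop_bindpoly("supply either Ka or K", "bindpoly_invalid_input")
    K <- macro_from_ka(Ka)
  }
  K <- as_macro(K)
  grid <- as.numeric(grid)
  if (!length(grid) || anyNA(grid) || any(grid < 0))
    stop_bindpoly("grid must be non-negative concentrations (uM)",
                  "bindpoly_invalid_input")
  if (noise < 0)
    stop_bindpoly("noise must be >= 0", "bindpoly_invalid_input")
  th <- as.matrix(species_fractions(grid, K)[, c("theta0", "theta1",
                                                 "theta2", "theta3")])
  with_seed(seed, {
    out <- lapply(seq_len(reps), function(r) {
      fr <- t(apply(th, 1, rdirichlet_mean, alpha = noise))
      data.frame(replicate = sprintf("r%d", r), protein_uM = grid,
                 dna_uM = dna_uM, f0 = fr[, 1], f1 = fr[, 2],
                 f2 = fr[, 3], f3 = fr[, 4])
    })
    do.call(rbind, out)
  })
}

#' Simulate a single-site binding curve
#'
#' `y = Bmax * x / (Kd + x)` plus Gaussian noise, clipped to `[0, 1]`
#' (fraction-bound data).
#'
#' @param Kd Dissociation constant (uM).
#' @param Bmax Maximal bound fraction.
#' @param x Protein concentrations (uM). Default: the nonzero points of the
#'   published 0.5-50 uM single-repeat EMSA series.
#' @param sigma Gaussian noise SD (0 = noiseless).
#' @param seed Integer seed (mandatory).
#' @return A data frame with columns `replicate`, `x_uM`, `y`.
#' @export
simulate_binding_curve <- function(Kd, Bmax = 1,
                                   x = c(0.6, 0.9, 1.2, 2.4, 3.5, 5.0,
                                         6.5, 26.1, 39.1, 49.9),
                                   sigma = 0, seed) {
  if (Kd <= 0 || Bmax <= 0 || sigma < 0)
    stop_bindpoly("Kd and Bmax must be > 0 and sigma >= 0",
                  "bindpoly_invalid_input")
  y0 <- Bmax * x / (Kd + x)
  y <- with_seed(seed, {
    if (sigma == 0) y0 else pmin(pmax(y0 + stats::rnorm(length(x), 0, sigma),
                                      0), 1)
  })
  data.frame(replicate = "r1", x_uM = x, y = y)
}

#' Simulate a dissociation chase
#'
#' `f(t) = (f0 - background) * exp(-koff * t) + background` plus Gaussian
#' noise, clipped to `[0, 1]`.
#'
#' @param koff Dissociation rate constant (s^-1).
#' @param f0 Complexed fraction at `t = 0`.
#' @param background Background complexed fraction (default 0.05, the
#'   competition-control level).
#' @param t Sampling times (s), first sample at 10 s by default.
#' @param sigma Gaussian noise SD (0 = noiseless).
#' @param seed Integer seed (mandatory).
#' @return A data frame with columns `time_s`, `fraction_complex`.
#' @export
simulate_decay <- function(koff, f0 = 0.5, background = 0.05,
                           t = c(10, 30, 60, 120, 240, 480),
                           sigma = 0, seed) {
  if (koff <= 0 || f0 < 0 || f0 > 1 || background < 0 || background >= 1 ||
      sigma < 0)
    stop_bindpoly("invalid decay parameters", "bindpoly_invalid_input")
  f <- (f0 - background) * exp(-koff * t) + background
  f <- with_seed(seed, {
    if (sigma == 0) f else pmin(pmax(f + stats::rnorm(length(t), 0, sigma),
                                     0), 1)
  })
  data.frame(time_s = t, fraction_complex = f)
}

#' Simulate SPR steady-state responses
#'
#' `Req = Rmax * conc / (Kd + conc)` plus Gaussian noise (RU), floored at 0.
#'
#' @param Kd Dissociation constant (uM).
#' @param Rmax Maximal response (RU).
#' @param conc Analyte concentrations (uM). Default: the published
#'   five-concentration injection series.
#' @param sigma Gaussian noise SD in RU (0 = noiseless).
#' @param seed Integer seed (mandatory).
#' @return A data frame with columns `conc_uM`, `Req_RU`.
#' @export
simulate_spr <- function(Kd, Rmax = 100,
                         conc = c(0.1, 0.25, 0.5, 0.75, 1),
                         sigma = 0, seed) {
  if (Kd <= 0 || Rmax <= 0 || sigma < 0)
    stop_bindpoly("Kd and Rmax must be > 0 and sigma >= 0",
                  "bindpoly_invalid_input")
  r0 <- Rmax * conc / (Kd + conc)
  r <- with_seed(seed, {
    if (sigma == 0) r0 else pmax(r0 + stats::rnorm(length(conc), 0, sigma), 0)
  })
  data.frame(conc_uM = conc, Req_RU = r)
}

#' Simulate paired footprint lane profiles
#'
#' Free-lane per-base intensities are drawn log-normal around a common
#' baseline; the complexed lane multiplies each base by its protection
#' factor `p` (1 = unchanged, 0.5 = 50% protected, 1.3 = 30% hyperexposed)
#' with multiplicative Gaussian noise.
#'
#' @param protection Per-base protection factors, `> 0`.
#' @param sequence Optional nucleotide letters, same length as `protection`.
#' @param strand `"top"` or `"bottom"`.
#' @param baseline Mean free-lane intensity (arbitrary densitometry units).
#' @param sdlog Log-normal spread of free-lane intensities.
#' @param sigma Multiplicative noise SD on the complexed lane
#'   (0 = noiseless).
#' @param seed Integer seed (mandatory).
#' @return A list with [lane_profile()] elements `free` and `complexed`, and
#'   the generating `protection`.
#' @export
simulate_footprint <- function(protection, sequence = NULL,
                               strand = c("top", "bottom"),
                               baseline = 1000, sdlog = 0.3, sigma = 0,
                               seed) {
  strand <- match.arg(strand)
  protection <- as.numeric(protection)
  if (!length(protection) || anyNA(protection) || any(protection <= 0))
    stop_bindpoly("protection factors must be positive",
                  "bindpoly_invalid_input")
  if (sigma < 0 || sdlog < 0 || baseline <= 0)
    stop_bindpoly("baseline must be > 0 and sdlog, sigma >= 0",
                  "bindpoly_invalid_input")
  n <- length(protection)
  base <- if (is.null(sequence)) NA_character_ else as.character(sequence)
  with_seed(seed, {
    free_int <- if (sdlog == 0) rep(baseline, n)
                else stats::rlnorm(n, log(baseline), sdlog)
    mult <- if (sigma == 0) rep(1, n)
            else pmax(1 + stats::rnorm(n, 0, sigma), 0)
    cplx_int <- free_int * protection * mult
    list(free = lane_profile(seq_len(n), free_int, base, strand),
         complexed = lane_profile(seq_len(n), cplx_int, base, strand),
         protection = protection)
  })
}
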