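# shared fixtures built in code

log_grid <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

# noiseless titration straight from the forward model (bypasses the
# generator so fitter tests have an oracle independent of simulate_titration)
theory_titration <- function(K, grid, dna_uM = 0.02) {
  th <- species_fractions(grid, K)
  data.frame(replicate = "r1", protein_uM = grid, dna_uM = dna_uM,
             f0 = th$theta0, f1 = th$theta1, f2 = th$theta2, f3 = th$theta3)
}

random_micro <- function() {
  micro_constants(stats::runif(1, 0.01, 10), stats::runif(1, 0.01, 10),
                  stats::runif(1, 0.01, 10), stats::runif(1, 0.01, 5),
                  stats::runif(1, 0.01, 5), stats::runif(1, 0.01, 5))
}
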