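make_pair <- function(free_int, cplx_int, strand = "top") {
  list(free = lane_profile(seq_along(free_int), free_int, strand = strand),
       complexed = lane_profile(seq_along(cplx_int), cplx_int,
                                strand = strand))
}

test_that("lane normalisation matches total intensities", {
  p <- make_pair(c(10, 20, 30), c(10, 20, 30))
  nm <- normalize_profiles(p$free, p$complexed)
  expect_equal(nm$scale, 1)

  # a global 2x exposure difference rescales away entirely
  p2 <- make_pair(c(10, 20, 30), 2 * c(10, 20, 30))
  nm2 <- normalize_profiles(p2$free, p2$complexed)
  expect_equal(nm2$scale, 0.5)
  expect_equal(nm2$complexed$intensity, nm2$free$intensity)

  # one halved base: scale is the hand-computed total ratio 60/50
  p3 <- make_pair(c(10, 20, 30), c(10, 10, 30))
  nm3 <- normalize_profiles(p3$free, p3$complexed)
  expect_equal(nm3$scale, 60 / 50)
  # with the unaffected bases as reference the halved base stays halved
  nm3r <- normalize_profiles(p3$free, p3$complexed, reference = c(1, 3))
  expect_equal(nm3r$scale, 1)
  expect_equal(nm3r$complexed$intensity[2], 10)

  mism <- lane_profile(2:4, c(1, 2, 3))
  expect_error(normalize_profiles(p$free, mism),
               class = "bindpoly_alignment_error")
  bottom <- lane_profile(1:3, c(1, 2, 3), strand = "bottom")
  expect_error(normalize_profiles(p$free, bottom),
               class = "bindpoly_alignment_error")
})

test_that("percent change classifies protection and hyperexposure", {
  free <- lane_profile(1:4, c(100, 100, 100, 100))
  cplx <- lane_profile(1:4, c(100, 50, 130, 100))
  rep <- percent_change(free, cplx)   # already on a common scale
  expect_equal(rep$percent_change, c(0, -50, 30, 0))
  expect_equal(rep$classification,
               c("unchanged", "protected", "hyperexposed", "unchanged"))
  expect_equal(attr(rep, "threshold"), 20)

  # identical lanes: all zero, all unchanged
  rep0 <- percent_change(free, lane_profile(1:4, rep(100, 4)))
  expect_true(all(rep0$percent_change == 0))
  expect_true(all(rep0$classification == "unchanged"))

  # a zero free-lane base is flagged, not dropped
  f0 <- lane_profile(1:3, c(100, 0, 100))
  c0 <- lane_profile(1:3, c(100, 10, 100))
  repz <- percent_change(f0, c0)
  expect_equal(nrow(repz), 3)
  expect_identical(repz$classification[2], "unquantifiable")
  expect_true(is.na(repz$percent_change[2]))
})

test_that("replicate reports average per base and reclassify on the mean", {
  free <- lane_profile(1:2, c(100, 100))
  r1 <- percent_change(free, lane_profile(1:2, c(60, 130)))   # -40, +30
  r2 <- percent_change(free, lane_profile(1:2, c(40, 90)))    # -60, -10
  avg <- average_replicates(list(r1, r2))
  expect_equal(avg$percent_change, c(-50, 10))
  expect_equal(avg$classification, c("protected", "unchanged"))

  same <- average_replicates(list(r1, r1))
  expect_equal(same$percent_change, r1$percent_change)
  expect_equal(same$classification, r1$classification)

  expect_error(average_replicates(list(r1)),
               class = "bindpoly_invalid_input")
})

test_that("reports are invariant to lane rescaling", {
  set.seed(8)
  free_int <- stats::rlnorm(20, log(1000), 0.4)
  cplx_int <- free_int * stats::runif(20, 0.4, 1.5)
  base_rep <- function(fi, ci) {
    p <- make_pair(fi, ci)
    nm <- normalize_profiles(p$free, p$complexed)
    percent_change(nm$free, nm$complexed)
  }
  ref <- base_rep(free_int, cplx_int)
  for (c_ in c(0.01, 7, 1000)) {
    expect_equal(base_rep(c_ * free_int, cplx_int)$percent_change,
                 ref$percent_change, tolerance = 1e-12)
    expect_equal(base_rep(free_int, c_ * cplx_int)$percent_change,
                 ref$percent_change, tolerance = 1e-12)
  }
})

test_that("simulated protection factors are recovered", {
  prot <- rep(1, 20); prot[5] <- 0.5; prot[12] <- 1.4
  sim <- simulate_footprint(prot, sigma = 0, seed = 13)
  # reference = the untouched bases: recovery is exact in noiseless mode
  nm <- normalize_profiles(sim$free, sim$complexed,
                           reference = which(prot == 1))
  rep <- percent_change(nm$free, nm$complexed)
  expect_equal(rep$percent_change, 100 * (prot - 1), tolerance = 1e-9)
  expect_identical(rep$classification[5], "protected")
  expect_identical(rep$classification[12], "hyperexposed")
  # total-intensity normalisation distorts by only the few-percent mass shift
  nm2 <- normalize_profiles(sim$free, sim$complexed)
  rep2 <- percent_change(nm2$free, nm2$complexed)
  expect_equal(rep2$percent_change[5], -50, tolerance = 0.1)

  # all-unchanged profile: nothing beyond threshold
  sim1 <- simulate_footprint(rep(1, 10), sigma = 0, seed = 14)
  nm1 <- normalize_profiles(sim1$free, sim1$complexed)
  rep1 <- percent_change(nm1$free, nm1$complexed)
  expect_true(all(rep1$classification == "unchanged"))
})
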