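test_that("the CBF scale factor matches an independent evaluation", {
  # frozen from an independent evaluation of the closed form with the
  # standard constants (lambda 0.9 ml/g, T1b 1.65 s, alpha 0.85, tau 1.5 s,
  # PLD 2.025 s)
  expect_equal(cbf_scale_factor(asl_parameters()), 11000.3007,
               tolerance = 1e-6)

  # single voxel with difference ratio 0.005 quantifies to ~55 ml/100 g/min
  g <- function(v) volume_grid(array(v, c(1, 1, 1)), c(1, 1, 1))
  cbf <- compute_cbf(g(1005), g(1000), g(1000))
  expect_equal(cbf$data[1, 1, 1], 55.0, tolerance = 0.1)
})

test_that("quantification is linear in the difference signal and scale free", {
  set.seed(4)
  d <- c(5, 5, 5)
  pd <- volume_grid(array(runif(125, 800, 1200), d), c(2, 2, 2))
  label <- volume_grid(array(runif(125, 40, 60), d), c(2, 2, 2))
  diff <- array(runif(125, 0, 10), d)
  ctrl1 <- volume_grid(label$data + diff, c(2, 2, 2))
  ctrl2 <- volume_grid(label$data + 2 * diff, c(2, 2, 2))

  cbf1 <- compute_cbf(ctrl1, label, pd)
  cbf2 <- compute_cbf(ctrl2, label, pd)
  expect_equal(cbf2$data, 2 * cbf1$data, tolerance = 1e-12)

  # control = label -> zero CBF everywhere
  cbf0 <- compute_cbf(label, label, pd)
  expect_true(all(cbf0$data == 0))

  # multiplying all three images by one constant leaves CBF unchanged
  s <- 3.7
  cbf_s <- compute_cbf(volume_grid(s * ctrl1$data, c(2, 2, 2)),
                       volume_grid(s * label$data, c(2, 2, 2)),
                       volume_grid(s * pd$data, c(2, 2, 2)))
  expect_equal(cbf_s$data, cbf1$data, tolerance = 1e-12)
})

test_that("time units convert and implausible T1 values are rejected", {
  ms <- asl_parameters(t1_blood = 1650, tau = 1500, pld = 2025,
                       time_unit = "ms")
  s <- asl_parameters()
  expect_equal(ms$t1_blood, s$t1_blood)
  expect_equal(cbf_scale_factor(ms), cbf_scale_factor(s))
  # milliseconds passed as seconds fail the plausibility guard
  expect_error(asl_parameters(t1_blood = 1650), "plausible")
  expect_error(asl_parameters(t1_blood = 0.3), "plausible")
  expect_error(asl_parameters(alpha = 1.2), "alpha")
})

test_that("non-positive and degenerate PD voxels are handled explicitly", {
  d <- c(3, 3, 3)
  g <- function(v) volume_grid(array(v, d), c(2, 2, 2))
  pd_bad <- g(1000)
  pd_bad$data[1, 1, 1] <- 0
  expect_error(compute_cbf(g(1005), g(1000), pd_bad), "1 non-positive")
  # geometry mismatch
  expect_error(compute_cbf(g(1005), g(1000),
                           volume_grid(array(1000, d), c(1, 1, 1))),
               "geometry")
})

test_that("relative CBF normalizes by the reference mean", {
  d <- c(4, 4, 4)
  cbf <- volume_grid(array(60, d), c(2, 2, 2))
  cbf$data[2, 2, 2] <- 90
  ref <- structure_mask("ref", array(TRUE, d), c(2, 2, 2))
  ref$data[2, 2, 2] <- FALSE  # reference excludes the hot voxel
  rc <- relative_cbf(cbf, ref)
  expect_equal(rc$data[2, 2, 2], 1.5)
  expect_equal(rc$data[1, 1, 1], 1.0)

  # constant map self-normalizes to 1 everywhere
  rc2 <- relative_cbf(volume_grid(array(42, d), c(2, 2, 2)),
                      structure_mask("all", array(TRUE, d), c(2, 2, 2)))
  expect_true(all(abs(rc2$data - 1) < 1e-12))

  empty <- structure_mask("e", array(FALSE, d), c(2, 2, 2))
  expect_error(relative_cbf(cbf, empty), "empty")
})

test_that("the mirrored gray-matter reference lies contralateral to the lesion", {
  ph <- small_phantom(noise = FALSE)
  gtv <- ph$structure_masks$gtv
  ref <- mirror_reference(gtv, ph$tissue_masks$gray)
  expect_gt(sum(ref$data), 0)
  # lesion is in the left hemisphere (low x); reference entirely in the right
  nx <- dim(gtv$data)[1]
  ref_x <- which(ref$data, arr.ind = TRUE)[, 1]
  expect_true(all(ref_x > nx / 2))
  # reflection alone preserves the voxel count
  expect_equal(sum(reflect_mask(gtv)$data), sum(gtv$data))

  # on the noiseless phantom the reference is pure gray matter: rCBF there is 1
  cbf <- compute_cbf(ph$asl_control, ph$asl_label, ph$asl_pd)
  rc <- relative_cbf(cbf, ref)
  expect_lt(max(abs(rc$data[ref$data] - 1)), 1e-6)

  # midline scenario returns the configured insula-analog reference
  ins <- ph$structure_masks$insula_ref
  ref_mid <- mirror_reference(gtv, ph$tissue_masks$gray,
                              scenario = "midline", insula = ins)
  expect_equal(ref_mid$data, ins$data)
  expect_error(mirror_reference(gtv, ph$tissue_masks$gray,
                                scenario = "midline"), "insula")
})

test_that("region-mean CBF error shrinks as 1/sqrt(n) with noise", {
  ph <- small_phantom(noise = TRUE)
  cbf <- compute_cbf(ph$asl_control, ph$asl_label, ph$asl_pd)
  err <- cbf$data - ph$truth_cbf$data
  white <- ph$tissue_masks$white$data
  # RMS of block means over disjoint cubic blocks of two sizes
  block_rms <- function(w) {
    d <- dim(err)
    starts <- expand.grid(i = seq(1, d[1] - w + 1, by = w),
                          j = seq(1, d[2] - w + 1, by = w),
                          k = seq(1, d[3] - w + 1, by = w))
    ms <- apply(starts, 1, function(s) {
      blk_w <- white[s[1]:(s[1] + w - 1), s[2]:(s[2] + w - 1),
                     s[3]:(s[3] + w - 1)]
      if (!all(blk_w)) return(NA_real_)
      mean(err[s[1]:(s[1] + w - 1), s[2]:(s[2] + w - 1),
               s[3]:(s[3] + w - 1)])
    })
    sqrt(mean(ms^2, na.rm = TRUE))
  }
  r5 <- block_rms(5)    # n = 125 voxels
  r10 <- block_rms(10)  # n = 1000 voxels
  expect_gt(r5, r10)
  # expected ratio sqrt(8) ~ 2.83; allow generous sampling slack
  expect_gt(r5 / r10, 1.6)
  expect_lt(r5 / r10, 5)
})
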