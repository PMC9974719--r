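test_that("hyper-perfusion thresholding is strict and brute-force exact", {
  # 3x3x1 toy: enumerated by hand against the strict > 1.4 rule
  vals <- c(1.2, 1.39, 1.4, 1.41, 2.0, 0.9, 1.5, 1.0, 1.45)
  rc <- volume_grid(array(vals, c(3, 3, 1)), c(2, 2, 2))
  gtv <- structure_mask("gtv", array(TRUE, c(3, 3, 1)), c(2, 2, 2))
  sel <- segment_hyperperfusion(rc, gtv)
  expect_equal(sum(sel$data), 4)           # 1.41, 2.0, 1.5, 1.45
  expect_false(sel$data[3, 1, 1])          # 1.4 itself excluded
  expect_false(attr(sel, "empty"))
  # >= variant picks up the boundary voxel too
  sel_ge <- segment_hyperperfusion(rc, gtv, strict = FALSE)
  expect_equal(sum(sel_ge$data), 5)
  # result is always contained in the GTV
  gtv2 <- gtv; gtv2$data[1, , ] <- FALSE
  expect_true(all(gtv2$data[segment_hyperperfusion(rc, gtv2)$data]))
})

test_that("an all-below-threshold map yields an empty GTV-ASL with a warning", {
  rc <- volume_grid(array(1.0, c(3, 3, 3)), c(2, 2, 2))
  gtv <- structure_mask("gtv", array(TRUE, c(3, 3, 3)), c(2, 2, 2))
  expect_warning(sel <- segment_hyperperfusion(rc, gtv), "empty")
  expect_true(attr(sel, "empty"))
  expect_equal(sum(sel$data), 0)
})

test_that("raising the threshold never grows the segmented volume", {
  set.seed(5)
  rc <- volume_grid(array(runif(343, 0.5, 2.5), c(7, 7, 7)), c(2, 2, 2))
  gtv <- structure_mask("gtv", array(TRUE, c(7, 7, 7)), c(2, 2, 2))
  prev <- NULL
  for (thr in c(0.8, 1.2, 1.4, 1.8, 2.2)) {
    cur <- suppressWarnings(segment_hyperperfusion(rc, gtv, threshold = thr))
    if (!is.null(prev)) expect_true(all(prev$data[cur$data]))
    prev <- cur
  }
})

test_that("on the noiseless phantom the GTV-ASL equals the true core", {
  ph <- small_phantom(noise = FALSE)
  cbf <- compute_cbf(ph$asl_control, ph$asl_label, ph$asl_pd)
  ref <- mirror_reference(ph$structure_masks$gtv, ph$tissue_masks$gray)
  rc <- relative_cbf(cbf, ref)
  sel <- segment_hyperperfusion(rc, ph$structure_masks$gtv)
  expect_identical(sel$data, ph$structure_masks$core$data)
})

test_that("margin expansion matches physical-distance oracles", {
  # zero margin is the identity
  set.seed(6)
  m <- structure_mask("m", array(runif(4 * 5 * 6) > 0.8, c(4, 5, 6)),
                      c(2, 2, 2))
  expect_equal(expand_margin(m, 0)$data, m$data)

  # single voxel on a 2 mm grid, 3 mm margin: 19 voxels (offsets with
  # 2*sqrt(i^2+j^2+k^2) <= 3)
  s <- structure_mask("pt", array(FALSE, c(7, 7, 7)), c(2, 2, 2))
  s$data[4, 4, 4] <- TRUE
  expect_equal(sum(expand_margin(s, 3)$data), 19)

  # sphere r = 10 mm expanded by 10 mm on a 1 mm grid: volume ratio ~ 8
  g <- volume_grid(array(0, c(45, 45, 45)), c(1, 1, 1))
  ctr <- g$origin + (dim(g$data) - 1) * g$spacing / 2
  sph <- structure_mask("sph",
                        aslboost:::rasterize_sphere(g, ctr, 10), c(1, 1, 1))
  grown <- expand_margin(sph, 10)
  expect_equal(sum(grown$data) / sum(sph$data), 8, tolerance = 0.03)
  # superset property
  expect_true(all(grown$data[sph$data]))
})

test_that("expansion equals the brute-force all-pairs oracle on small grids", {
  set.seed(7)
  for (case in 1:3) {
    d <- sample(8:14, 3, replace = TRUE)
    spacing <- if (case == 3) c(2, 2, 3) else c(1.5, 1.5, 1.5)  # anisotropic too
    m <- structure_mask("m", array(runif(prod(d)) > 0.92, d), spacing)
    if (!any(m$data)) m$data[1, 1, 1] <- TRUE
    for (margin in c(2, 4.5)) {
      expect_identical(expand_margin(m, margin)$data,
                       brute_force_expand(m, margin)$data,
                       label = sprintf("case %d margin %g", case, margin))
    }
  }
})

test_that("expansion is monotone in the margin", {
  set.seed(8)
  m <- structure_mask("m", array(runif(1000) > 0.95, c(10, 10, 10)),
                      c(2, 2, 2))
  m$data[5, 5, 5] <- TRUE
  prev <- expand_margin(m, 1)
  for (margin in c(2, 4, 7)) {
    cur <- expand_margin(m, margin)
    expect_true(all(cur$data[prev$data]))
    prev <- cur
  }
  expect_error(expand_margin(structure_mask("e", array(FALSE, c(3, 3, 3)),
                                            c(1, 1, 1)), 2), "empty")
})

test_that("the target cascade nests and reproduces analytic volume ratios", {
  # nested spheres on a 1 mm grid: GTV r = 25, core r = 12;
  # PTV-ASL/PTV ratio ~ ((12+3)/(25+10+5))^3 = 5.27% before clipping
  g <- volume_grid(array(0, c(96, 96, 96)), c(1, 1, 1))
  ctr <- g$origin + (dim(g$data) - 1) * g$spacing / 2
  gtv <- structure_mask("gtv", aslboost:::rasterize_sphere(g, ctr, 25),
                        c(1, 1, 1))
  core <- structure_mask("gtv_asl", aslboost:::rasterize_sphere(g, ctr, 12),
                         c(1, 1, 1))
  casc <- build_structure_cascade(gtv, core)
  expect_equal(attr(casc, "ptv_asl_ratio"), (15 / 40)^3, tolerance = 0.05)

  # nesting: GTV in CTV in PTV; PTV-ASL in PTV
  expect_true(all(casc$ctv$data[casc$gtv$data]))
  expect_true(all(casc$ptv$data[casc$ctv$data]))
  expect_true(all(casc$ptv$data[casc$ptv_asl$data]))
  # subtraction identities
  expect_equal(sum(casc$ptv_sub$data),
               sum(casc$ptv$data) - sum(casc$ptv_asl$data))
  expect_equal(sum(casc$gtv_sub$data),
               sum(casc$gtv$data) - sum(casc$gtv_asl$data))
})

test_that("an empty GTV-ASL degenerates the cascade gracefully", {
  g <- volume_grid(array(0, c(40, 40, 40)), c(2, 2, 2))
  ctr <- g$origin + (dim(g$data) - 1) * g$spacing / 2
  gtv <- structure_mask("gtv", aslboost:::rasterize_sphere(g, ctr, 12),
                        c(2, 2, 2))
  empty <- structure_mask("gtv_asl", array(FALSE, c(40, 40, 40)), c(2, 2, 2))
  casc <- build_structure_cascade(gtv, empty)
  expect_equal(casc$ptv_sub$data, casc$ptv$data)
  expect_equal(attr(casc, "ptv_asl_ratio"), 0)
  # containment precondition enforced
  outside <- structure_mask("gtv_asl", !gtv$data, c(2, 2, 2))
  expect_error(build_structure_cascade(gtv, outside), "contained")
})

test_that("clipping restricts the cascade to the body", {
  g <- volume_grid(array(0, c(30, 30, 30)), c(2, 2, 2))
  ctr <- g$origin + (dim(g$data) - 1) * g$spacing / 2
  gtv <- structure_mask("gtv", aslboost:::rasterize_sphere(g, ctr, 10),
                        c(2, 2, 2))
  sub <- structure_mask("gtv_asl", aslboost:::rasterize_sphere(g, ctr, 4),
                        c(2, 2, 2))
  body <- structure_mask("body", aslboost:::rasterize_sphere(g, ctr, 20),
                         c(2, 2, 2))
  casc <- build_structure_cascade(gtv, sub, clip = body)
  expect_true(all(body$data[casc$ptv$data]))
  casc_unclipped <- build_structure_cascade(gtv, sub)
  expect_gt(sum(casc_unclipped$ptv$data), sum(casc$ptv$data))
})
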