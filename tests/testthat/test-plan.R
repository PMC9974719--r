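# compact planning geometry: nested spheres on a 64^3 grid at 2 mm
plan_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- volume_grid(array(0, c(64, 64, 64)), c(2, 2, 2))
    ctr <- g$origin + (dim(g$data) - 1) * g$spacing / 2
    gtv <- structure_mask("gtv", aslboost:::rasterize_sphere(g, ctr, 12),
                          c(2, 2, 2))
    core <- structure_mask("gtv_asl",
                           aslboost:::rasterize_sphere(g, ctr + c(-4, 0, 0), 5),
                           c(2, 2, 2))
    cache <<- build_structure_cascade(gtv, core)
    cache
  }
})

test_that("prescription arithmetic and validation", {
  rx <- plan_prescription(baseline_dose_gy = 60, escalation_fraction = 0.20)
  expect_equal(rx$boost_dose_gy, 72)
  rx2 <- plan_prescription(baseline_dose_gy = 45, escalation_fraction = 0.10)
  expect_equal(rx2$boost_dose_gy, 49.5)
  expect_error(plan_prescription(cap_fraction = 0.9), "cap_fraction")
  expect_error(plan_prescription(coverage_goal = 0), "coverage_goal")
})

test_that("the degenerate zero-penumbra limit is a perfect box dose", {
  st <- plan_fixture()
  rx <- plan_prescription()
  dose <- simulate_plan(st, rx, dose_model_config(penumbra_sigma_mm = 0),
                        "plan1")
  expect_true(all(dose$data[st$ptv$data] == 60))
  expect_true(all(dose$data[!st$ptv$data] == 0))
  dvh <- compute_dvh(dose, st$ptv)
  expect_equal(dose_at_volume(dvh, 0.02), 60)
  expect_equal(dose_at_volume(dvh, 0.98), 60)
  expect_equal(mean(dose$data[st$ptv$data]), 60)
})

test_that("normalization, boost and coverage contracts hold for all variants", {
  st <- plan_fixture()
  rx <- plan_prescription()
  doses <- lapply(c(plan1 = "plan1", plan2 = "plan2", plan3 = "plan3"),
                  function(v) simulate_plan(st, rx, variant = v))
  for (v in names(doses)) {
    norm <- attr(doses[[v]], "normalization")
    expect_lt(norm$residual, 0.005, label = paste(v, "normalization"))
    expect_gte(coverage(doses[[v]], st$ptv, rx$baseline_dose_gy), 0.95)
    expect_true(all(doses[[v]]$data >= 0))
  }
  expect_equal(attr(doses$plan1, "normalization")$structure, "ptv")
  expect_equal(attr(doses$plan2, "normalization")$structure, "ptv_asl")

  # mean PTV-ASL dose escalates by the escalation fraction (within 1%)
  ratio <- mean(doses$plan2$data[st$ptv_asl$data]) /
    mean(doses$plan1$data[st$ptv_asl$data])
  expect_equal(ratio, 1.2, tolerance = 0.01)

  # dose vanishes far from the target (beyond ~5 sigma of the aperture)
  far <- !expand_margin(st$ptv, 45)$data
  expect_lt(max(doses$plan1$data[far]), 0.01 * rx$baseline_dose_gy)
})

test_that("the 110% cap binds plans 1-2 and its removal only adds dose", {
  st <- plan_fixture()
  rx <- plan_prescription()
  p2 <- simulate_plan(st, rx, variant = "plan2")
  p3 <- simulate_plan(st, rx, variant = "plan3")

  cap_map <- 1.10 * local_prescription(st, rx, "plan2")$data
  expect_lt(max(p2$data - cap_map), 1e-6)
  p1 <- simulate_plan(st, rx, variant = "plan1")
  expect_lt(max(p1$data) , 1.10 * rx$baseline_dose_gy + 1e-6)

  # plan 3 is the uncapped version: nowhere colder, hotter at the top
  expect_true(all(p3$data - p2$data > -1e-9))
  expect_gte(max(p3$data), max(p2$data))
  # the cap removal only reshapes the hot tail: D98% moves by < 1 Gy
  for (s in c("ptv", "ptv_asl", "ptv_sub")) {
    d98_2 <- dose_at_volume(compute_dvh(p2, st[[s]]), 0.98)
    d98_3 <- dose_at_volume(compute_dvh(p3, st[[s]]), 0.98)
    expect_lt(abs(d98_3 - d98_2), 1, label = paste("D98", s))
  }

  # the global-baseline cap reading caps the boost region too; it is only
  # consistent with escalations below cap_fraction - 1 (an 8% boost here --
  # a 20% boost above a 110% global cap is infeasible by construction)
  rx_gb <- plan_prescription(escalation_fraction = 0.08,
                             cap_reference = "baseline")
  p2_gb <- simulate_plan(st, rx_gb, variant = "plan2")
  expect_lt(max(p2_gb$data), 1.10 * rx_gb$baseline_dose_gy + 1e-6)
  # and the infeasible combination fails loudly with the conflict named
  expect_error(simulate_plan(st, plan_prescription(cap_reference = "baseline"),
                             variant = "plan2"), "cannot both be satisfied")
})

test_that("mean boost dose is monotone in the escalation fraction", {
  st <- plan_fixture()
  means <- vapply(c(0.10, 0.15, 0.20), function(esc) {
    d <- simulate_plan(st, plan_prescription(escalation_fraction = esc),
                       variant = "plan2")
    mean(d$data[st$ptv_asl$data])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("an empty PTV-ASL falls back to the conventional plan", {
  st <- plan_fixture()
  st$ptv_asl <- structure_mask("ptv_asl", array(FALSE, dim(st$ptv$data)),
                               st$ptv$spacing)
  rx <- plan_prescription()
  expect_warning(p2 <- simulate_plan(st, rx, variant = "plan2"), "fall")
  p1 <- simulate_plan(st, rx, variant = "plan1")
  expect_equal(p2$data, p1$data)
  expect_true(attr(p2, "fallback"))
})

test_that("constraint checking reports observed values and verdicts", {
  n <- c(20, 10, 10)
  stem <- structure_mask("brainstem", array(FALSE, n), c(2, 2, 2))
  stem$data[1:5, 1:5, 1:5] <- TRUE  # 1 cc
  structures <- list(brainstem = stem)
  tab <- oar_constraint_table(data.frame(
    structure = "brainstem", metric = "D0.1cc", limit_gy = 54,
    comparator = "<=", stringsAsFactors = FALSE))

  res_ok <- check_constraints(uniform_dose(50, n), structures, tab)
  expect_true(res_ok$pass)
  expect_equal(res_ok$observed_gy, 50)
  expect_true(attr(res_ok, "overall_pass"))

  res_bad <- check_constraints(uniform_dose(55, n), structures, tab)
  expect_false(res_bad$pass)
  expect_equal(res_bad$observed_gy, 55)
  expect_equal(res_bad$limit_gy, 54)

  expect_error(check_constraints(uniform_dose(50, n),
                                 list(), tab), "brainstem")
  # default table covers every cranial OAR once per metric
  expect_error(oar_constraint_table(data.frame(
    structure = c("a", "a"), metric = c("Dmax", "Dmax"),
    limit_gy = c(10, 20), comparator = c("<", "<"))), "once per metric")
})
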