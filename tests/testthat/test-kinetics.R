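test_that("calibration inverse-maps exactly on a perfect line and flags", {
  std <- tibble::tibble(conc_uM = seq(50, 400, by = 50))
  std$absorbance <- 0.05 + 0.002 * std$conc_uM
  abs_in <- 0.05 + 0.002 * c(200, 10, 450, -10)
  q <- calibrate_and_quantify(abs_in, std)
  expect_equal(q$conc_uM, c(200, 10, 450, 0), tolerance = 1e-9)
  expect_equal(q$flag, c("ok", "below_range", "above_range", "floored"))
})

test_that("calibration guards standards count and fit quality", {
  expect_error(
    calibrate_and_quantify(0.1, tibble::tibble(conc_uM = c(0, 100),
                                               absorbance = c(0, 0.2))),
    "3 calibration standards")
  set.seed(1)
  bad <- tibble::tibble(conc_uM = seq(0, 400, by = 50),
                        absorbance = runif(9))
  expect_error(calibrate_and_quantify(0.1, bad), "R-squared")
})

test_that("background correction floors negatives and checks the grid", {
  s <- tibble::tibble(time_h = c(0, 2, 4), amine_uM = c(1, 10, 30))
  b <- tibble::tibble(time_h = c(0, 2, 4), amine_uM = c(2, 4, 6))
  expect_warning(cc <- background_correct(s, b), "floored")
  expect_equal(cc$amine_uM, c(0, 6, 24))
  expect_equal(attr(cc, "n_floored"), 1L)
  b2 <- tibble::tibble(time_h = c(0, 2, 5), amine_uM = c(2, 4, 6))
  expect_error(background_correct(s, b2), "time grid")
})

test_that("specific activity matches the hand calculation", {
  rec <- tibble::tibble(amine_uM = 300, time_h = 2, enzyme_mg_per_L = 1.9)
  expect_message(specific_activity(rec), "replica")
  sa <- suppressMessages(specific_activity(rec))
  expect_equal(sa$mean, 300 / (2 * 1.9), tolerance = 1e-12)

  # replicate-wise means feed the aggregate
  rec2 <- tibble::tibble(amine_uM = c(300, 310, 280, 320),
                         time_h = 2, enzyme_mg_per_L = 1.9,
                         replicate = c(1, 1, 2, 2))
  sa2 <- specific_activity(rec2)
  per_rep <- c(mean(c(300, 310)), mean(c(280, 320))) / (2 * 1.9)
  expect_equal(sa2$mean, mean(per_rep), tolerance = 1e-12)
  expect_equal(sa2$n, 2L)
})

test_that("molar and mass enzyme concentrations are cross-checked", {
  expect_equal(enzyme_mg_per_L(50), 1.9, tolerance = 1e-12)
  rec <- tibble::tibble(amine_uM = 300, time_h = 2,
                        enzyme_mg_per_L = 1.9, enzyme_nM = 50)
  expect_silent(suppressMessages(specific_activity(rec)))
  rec$enzyme_mg_per_L <- 2.5
  expect_error(specific_activity(rec), "2%")
  expect_error(specific_activity(tibble::tibble(amine_uM = 1, time_h = 2)),
               "enzyme_mg_per_L")
})

test_that("fold change propagates error and rounds half-up", {
  fc <- fold_change(c(462, 15), c(77, 5))
  expect_equal(fc$fold, 6, tolerance = 1e-12)
  expect_equal(fc$sem, 6 * sqrt((15 / 462)^2 + (5 / 77)^2), tolerance = 1e-12)
  expect_equal(fold_change(c(0.25, 0.01), c(1, 0))$fold_rounded, 0.3)
  expect_equal(fold_change(c(3.45, 0.01), c(1, 0))$fold_rounded, 3.5)
  expect_equal(fold_change(list(mean = 10, sem = 1),
                           list(mean = 2, sem = 0.1))$fold, 5)
  expect_error(fold_change(c(2, 0.1), c(0, 0.1)), "positive")
})

test_that("noiseless Michaelis-Menten data are recovered exactly", {
  d <- make_mm_data(vmax = 10, km = 100, noise_cv = 0)
  f <- fit_mm(d, model = "convMM")
  g <- glance(f)
  expect_equal(g$vmax, 10, tolerance = 1e-6)
  expect_equal(g$km, 100, tolerance = 1e-6)
  expect_equal(g$model, "convMM")
  expect_gt(g$r_squared, 1 - 1e-10)
  td <- tidy(f)
  expect_equal(td$term, c("Vmax", "Km"))
  f2 <- fit_mm(d, model = "invMM")
  expect_equal(f2$model, "invMM")
  expect_error(fit_mm(tibble::tibble(x = c(1, 1, 2, 2), rate = 1:4)),
               "distinct x")
})

test_that("degree of depolymerization matches the hand oracle", {
  pr <- tibble::tibble(amount_umol = c(10, 5), repeat_units = c(1, 2))
  d <- degree_of_depolymerization(pr, loading_g_per_L = 0.5)
  # 20 umol repeat units * 113.16 g/mol = 2.2632 mg over 500 mg loading
  expect_equal(d$released_mg, 20 * 113.16 * 1e-3, tolerance = 1e-12)
  expect_equal(d$dod_pct, 100 * (20 * 113.16 * 1e-6) / 0.5, tolerance = 1e-12)
  expect_equal(d$monomer_fraction_pct, 50, tolerance = 1e-12)

  # free-monomer basis adds hydrolysis water back
  d2 <- degree_of_depolymerization(pr, 0.5, basis = "free-monomer")
  expect_equal(d2$released_mg,
               (10 * 131.17 + 5 * (2 * 131.17 - 18.015)) * 1e-3,
               tolerance = 1e-12)
})

test_that("depolymerization series warn when decreasing and reject negatives", {
  pr <- tibble::tibble(amount_umol = c(10, 5), repeat_units = 1,
                       time_h = c(2, 4))
  expect_warning(degree_of_depolymerization(pr, 0.5), "decreases")
  expect_error(degree_of_depolymerization(
    tibble::tibble(amount_umol = -1, repeat_units = 1), 0.5), "non-negative")
  expect_error(degree_of_depolymerization(
    tibble::tibble(amount_umol = 1, repeat_units = 1), 0), "positive")
})

test_that("melting temperatures are recovered and shift-equivariant", {
  tm1 <- extract_tm(make_melt_curve(tm = 85.7, noise = 0, seed = 1))
  expect_equal(tm1$tm, 85.7, tolerance = 1e-3)
  expect_equal(tm1$method, "boltzmann")
  tm2 <- extract_tm(make_melt_curve(tm = 88.7, noise = 0, seed = 1))
  expect_equal(tm2$tm - tm1$tm, 3, tolerance = 1e-6)
  noisy <- extract_tm(make_melt_curve(tm = 85.7, noise = 0.01, seed = 7))
  expect_equal(noisy$tm, 85.7, tolerance = 0.2)
})

test_that("melt curves without a transition in range raise an error", {
  expect_error(extract_tm(make_melt_curve(tm = 120, noise = 0)), "boundary")
  expect_error(
    extract_tm(tibble::tibble(temperature_C = 1:4, signal = 1:4)), "short")
  expect_error(
    extract_tm(tibble::tibble(temperature_C = c(1, 2, 2, 3, 4, 5),
                              signal = rnorm(6))), "increasing")
})

test_that("epistasis classification covers all three classes", {
  singles <- tibble::tibble(fold = c(2.8, 3.0), sem = c(0.1, 0.1))
  neg <- classify_epistasis(singles, c(5.3, 0.3))
  expect_equal(neg$class, "negative")
  expect_equal(neg$expected, 8.4, tolerance = 1e-12)
  expect_equal(neg$sigma_expected,
               8.4 * sqrt((0.1 / 2.8)^2 + (0.1 / 3.0)^2), tolerance = 1e-12)
  expect_equal(classify_epistasis(singles, c(12, 0.3))$class, "positive")
  expect_equal(classify_epistasis(singles, c(8.5, 0.3))$class, "additive")
  # widening the band reclassifies a borderline combo as additive
  expect_equal(classify_epistasis(singles, c(5.3, 0.3), k_sigma = 100)$class,
               "additive")
  expect_error(classify_epistasis(singles[1, ], c(5, 0.1)), "two single")
  expect_error(classify_epistasis(singles, c(-1, 0.1)), "positive")
})

test_that("unit conversions are exact", {
  expect_equal(activity_mg_to_umol(131.17), 1000, tolerance = 1e-12)
  expect_equal(enzyme_mg_per_L(100, mw = 20000), 2, tolerance = 1e-12)
})
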