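noiseless_table <- function(areas = c(1, 3, 10, 30, 100),
                            f = function(x) 2 - 1 * x, res = 0) {
  data.frame(area_ha = areas, ses = f(log(areas)), res = res)
}

test_that("noiseless linear SES is interpolated exactly", {
  fit <- suppressMessages(fit_mslip_area(noiseless_table(), center = 0))
  expect_equal(fit$beta0, 2, tolerance = 1e-10)
  expect_equal(fit$beta1, -1, tolerance = 1e-10)
  expect_equal(fit$beta2, 0)
  au <- estimate_ausr(fit)
  expect_equal(au$ausr_ha, exp(2), tolerance = 1e-9)
  expect_true(au$within_range)
  expect_identical(au$slope_sign, "negative")
})

test_that("undefined SES rows are dropped and counted; too few rows error", {
  tab <- noiseless_table()
  tab$ses[2] <- NA
  expect_message(fit <- fit_mslip_area(tab, center = 0), "1 fragment")
  expect_equal(fit$n_used, 4L)
  expect_equal(fit$n_dropped, 1L)
  tab$ses[3] <- NA
  expect_error(suppressMessages(fit_mslip_area(tab)), "at least 4")
  expect_error(suppressMessages(fit_mslip_area(noiseless_table(),
                                               quadratic = TRUE,
                                               center = 0)[
    "never reached"]), NA)  # 5 rows suffice for the quadratic
})

test_that("res covariate is estimated when informative", {
  set.seed(31)
  areas <- exp(runif(60, -1, 6))
  res <- rnorm(60, 0, 0.3)
  tab <- data.frame(area_ha = areas,
                    ses = 1.5 - 0.8 * log(areas) - 2 * res, res = res)
  fit <- fit_mslip_area(tab, center = 0)
  expect_equal(fit$beta1, -0.8, tolerance = 1e-9)
  expect_equal(fit$beta2, -2, tolerance = 1e-9)
})

test_that("collinear non-constant designs error", {
  tab <- noiseless_table(areas = c(1, 3, 10, 30, 100))
  tab$res <- log(tab$area_ha)  # res duplicates the ln-area predictor
  expect_error(suppressMessages(fit_mslip_area(tab, center = 0)),
               "collinear")
})

test_that("A_USR is invariant to the centering constant", {
  ds <- suppressMessages(simulate_landscape(
    synthetic_config(n_fragments = 80, n_species = 100, seed = 61)))
  tbl <- compute_mslip_ses(ds, n_draws = 300, seed = 62)
  isar <- fit_isar(tbl$area_ha, tbl$richness)
  tbl$res <- residual_richness(isar, tbl$area_ha, tbl$richness)$res
  f0 <- fit_mslip_area(tbl, center = 0)
  fm <- fit_mslip_area(tbl)  # centered at mean ln-area
  expect_false(isTRUE(all.equal(f0$beta0, fm$beta0)))
  a0 <- estimate_ausr(f0)$ausr_ha
  am <- estimate_ausr(fm)$ausr_ha
  expect_equal(a0, am, tolerance = 1e-9)
  expect_equal(predict(f0$lm), predict(fm$lm), tolerance = 1e-9)
})

test_that("horizontal relation yields an undefined, near-zero estimate", {
  set.seed(77)
  tab <- data.frame(area_ha = exp(runif(40, 0, 5)),
                    ses = rnorm(40, 0, 1), res = 0)
  fit <- suppressMessages(fit_mslip_area(tab))
  fit$beta1 <- 0  # exact horizontal line
  au <- estimate_ausr(fit)
  expect_true(is.na(au$ausr_ha))
  expect_length(au$crossings, 0)
  expect_identical(classify_fragments(tab$area_ha, au),
                   rep("unclassified", 40))
})

test_that("slope_sign reflects the beta1 confidence interval", {
  set.seed(78)
  tab <- data.frame(area_ha = exp(runif(40, 0, 5)),
                    ses = rnorm(40, 0, 1), res = 0)
  fit <- suppressMessages(fit_mslip_area(tab))
  expect_identical(estimate_ausr(fit)$slope_sign, "near_zero")
  tab$ses <- 2 - 1.2 * log(tab$area_ha) + rnorm(40, 0, 0.3)
  fit2 <- suppressMessages(fit_mslip_area(tab))
  expect_identical(estimate_ausr(fit2)$slope_sign, "negative")
})

test_that("quadratic model reports both analytic crossings", {
  # SES = -(x - 1)(x - 3) = -3 + 4x - x^2: roots at ln(area) = 1 and 3
  areas <- exp(seq(-1, 5, length.out = 12))
  x <- log(areas)
  tab <- data.frame(area_ha = areas, ses = -(x - 1) * (x - 3), res = 0)
  fit <- suppressMessages(fit_mslip_area(tab, quadratic = TRUE, center = 0))
  expect_equal(fit$beta3, -1, tolerance = 1e-9)
  au <- estimate_ausr(fit)
  expect_equal(sort(au$crossings), c(exp(1), exp(3)), tolerance = 1e-8)
  # the descending crossing (large-fragment threshold) is the primary one
  expect_equal(au$ausr_ha, exp(3), tolerance = 1e-8)
})

test_that("quadratic path with a vanishing quadratic term equals linear", {
  tab <- noiseless_table()
  fl <- suppressMessages(fit_mslip_area(tab, center = 0))
  fq <- suppressMessages(fit_mslip_area(tab, quadratic = TRUE, center = 0))
  fq$beta3 <- 0
  expect_equal(estimate_ausr(fq)$ausr_ha, estimate_ausr(fl)$ausr_ha,
               tolerance = 1e-8)
})

test_that("classification threshold and boundary convention", {
  expect_identical(classify_fragments(c(1, 10), 7.39), c("small", "large"))
  expect_identical(classify_fragments(7.39, 7.39), "large")
  expect_identical(classify_fragments(c(2, 3), NA_real_),
                   c("unclassified", "unclassified"))
})

test_that("bootstrap interval brackets the point estimate and is seeded", {
  set.seed(90)
  areas <- exp(runif(60, 0, 5))
  tab <- data.frame(area_ha = areas,
                    ses = 2.5 - 1 * (log(areas) - 2.5) * 1 + rnorm(60, 0, 0.8))
  tab$ses <- 2.5 - 1 * log(areas) + rnorm(60, 0, 0.8)
  fit <- suppressMessages(fit_mslip_area(tab))
  au1 <- estimate_ausr(fit, bootstrap = 199, seed = 5)
  au2 <- estimate_ausr(fit, bootstrap = 199, seed = 5)
  expect_identical(au1$ci, au2$ci)
  expect_gt(au1$boot_prop_defined, 0.9)
  expect_lt(au1$ci[1], au1$ausr_ha)
  expect_gt(au1$ci[2], au1$ausr_ha)
  expect_error(estimate_ausr(fit, bootstrap = 10), "seed")
})
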