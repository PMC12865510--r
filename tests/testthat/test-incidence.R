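test_that("incidence equals presence count over fragment count", {
  ds <- demo_dataset()
  prof <- compute_incidence(ds)
  expect_equal(unname(prof["b"]), 0.8)   # 4 of 5 fragments
  expect_equal(unname(prof["a"]), 1.0)   # ubiquitous
  expect_equal(unname(prof["h"]), 0.2)
  expect_identical(attr(prof, "n_fragments"), 5L)

  m3 <- matrix(c(1, 0, 0, 1, 1, 0), nrow = 3,
               dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  ds3 <- occurrence_dataset(m3, data.frame(fragment_id = paste0("f", 1:3),
                                           area_ha = 1:3))
  expect_equal(unname(compute_incidence(ds3)["s1"]), 1 / 3)
})

test_that("observed MSLIP is the geometric mean of resident incidences", {
  expect_equal(mslip_observed(0.8), 0.8)
  expect_equal(mslip_observed(c(1.0, 0.8, 0.6)), 0.48^(1 / 3))
  expect_equal(round(mslip_observed(c(1.0, 0.8, 0.6)), 4), 0.783)
  expect_equal(mslip_observed(c(0.5, 0.5)), 0.5)
  expect_true(is.na(mslip_observed(numeric(0))))
  expect_error(mslip_observed(c(0.5, 0)), "in \\(0, 1\\]")

  # oracle property: agrees with direct product-root on random inputs
  set.seed(401)
  for (i in 1:25) {
    x <- runif(sample(1:12, 1), min = 0.05, max = 1)
    expect_equal(mslip_observed(x), geomean_oracle(x), tolerance = 1e-12)
  }
})

test_that("SES arithmetic matches the worked example and handles degeneracy", {
  expect_equal(ses_from_summary(0.78, 0.54, 0.16), 1.5)
  expect_equal(ses_from_summary(0.6, 0.6, 0.1), 0)
  expect_true(is.na(ses_from_summary(0.7, 0.5, 0)))
  expect_true(is.na(ses_from_summary(NA_real_, 0.5, 0.1)))
  expect_error(ses_from_summary(0.7, 0.5, -0.1), ">= 0")
})

test_that("null distribution matches exhaustive enumeration on tiny pools", {
  # degenerate pool: no spread whatever the richness
  nd <- null_distribution(3, c(1, 1), n_draws = 500, seed = 7)
  expect_equal(nd$null_mean, 1)
  expect_equal(nd$null_sd, 0)

  cases <- list(list(pool = c(0.5, 1.0), k = 1),
                list(pool = c(0.2, 0.6, 1.0), k = 2),
                list(pool = c(0.25, 0.5, 0.75, 1.0), k = 3))
  n_draws <- 20000
  for (cs in cases) {
    ex <- enum_null(cs$pool, cs$k)
    nd <- null_distribution(cs$k, cs$pool, n_draws = n_draws, seed = 11)
    se_mean <- ex$sd / sqrt(n_draws)
    se_sd <- ex$sd / sqrt(2 * n_draws)
    expect_lt(abs(nd$null_mean - ex$mean), 3 * se_mean)
    expect_lt(abs(nd$null_sd - ex$sd), 3 * se_sd)
  }
  # the k = 1 exhaustive case has closed form mean 0.75, sd 0.25
  ex1 <- enum_null(c(0.5, 1.0), 1)
  expect_equal(ex1$mean, 0.75)
  expect_equal(ex1$sd, 0.25)

  expect_error(null_distribution(0, c(0.5, 1), seed = 1), "richness")
  expect_error(null_distribution(2, c(0.5, 1), n_draws = 0, seed = 1),
               "n_draws")
})

test_that("Monte-Carlo null converges toward enumeration as draws grow", {
  pool <- c(0.3, 0.6, 0.9)
  ex <- enum_null(pool, 2)
  errs <- vapply(c(200, 2000, 50000), function(nd) {
    x <- null_distribution(2, pool, n_draws = nd, seed = 5)
    abs(x$null_mean - ex$mean)
  }, numeric(1))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3], 3 * ex$sd / sqrt(50000))
})

test_that("per-fragment table reproduces, respects seed, flags empties", {
  ds <- demo_dataset()
  t1 <- compute_mslip_ses(ds, n_draws = 400, seed = 42)
  t2 <- compute_mslip_ses(ds, n_draws = 400, seed = 42)
  expect_identical(t1, t2)
  t3 <- compute_mslip_ses(ds, n_draws = 400, seed = 43)
  expect_false(identical(t1$ses, t3$ses))

  expect_equal(t1$richness, c(2, 3, 5, 6, 6))
  expect_equal(t1$mslip_obs[2], 0.48^(1 / 3))
  # equal-richness fragments share the same null
  expect_equal(t1$null_mean[4], t1$null_mean[5])

  # empty fragment: undefined MSLIP and SES, others unaffected
  m <- demo_matrix()
  m["f1", ] <- 0L
  dse <- occurrence_dataset(m, demo_meta())
  expect_message(te <- compute_mslip_ses(dse, n_draws = 200, seed = 1),
                 "undefined SES")
  expect_true(is.na(te$mslip_obs[1]) && is.na(te$ses[1]))
  expect_true(all(is.finite(te$ses[-1])))
})

test_that("SES is invariant to fragment relabelling and species reordering", {
  ds <- demo_dataset()
  t1 <- compute_mslip_ses(ds, n_draws = 300, seed = 9)

  perm_sp <- c(5, 3, 8, 1, 2, 7, 4, 6)
  ds_sp <- occurrence_dataset(demo_matrix()[, perm_sp], demo_meta())
  t2 <- compute_mslip_ses(ds_sp, n_draws = 300, seed = 9)
  expect_equal(t2$ses, t1$ses)

  perm_fr <- c(4, 2, 5, 1, 3)
  ds_fr <- occurrence_dataset(demo_matrix()[perm_fr, ],
                              demo_meta()[perm_fr, ])
  t3 <- compute_mslip_ses(ds_fr, n_draws = 300, seed = 9)
  expect_equal(t3$ses[match(t1$fragment_id, t3$fragment_id)], t1$ses)
})

test_that("identical species sets give degenerate nulls, undefined SES", {
  m <- matrix(1L, 4, 3, dimnames = list(paste0("f", 1:4), paste0("s", 1:3)))
  ds <- occurrence_dataset(m, data.frame(fragment_id = paste0("f", 1:4),
                                         area_ha = c(1, 4, 9, 16)))
  tb <- suppressMessages(compute_mslip_ses(ds, n_draws = 200, seed = 3))
  expect_true(all(tb$null_sd == 0))
  expect_true(all(is.na(tb$ses)))
})

test_that("a fragment holding only widespread species scores positive SES", {
  # 4 x 4 toy: s1 nearly ubiquitous, f1 holds s1 alone
  m <- matrix(c(1, 0, 0, 0,
                1, 1, 0, 0,
                1, 0, 1, 0,
                0, 1, 1, 1), nrow = 4, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), paste0("s", 1:4)))
  ds <- occurrence_dataset(m, data.frame(fragment_id = paste0("f", 1:4),
                                         area_ha = c(1, 2, 4, 8)))
  prof <- compute_incidence(ds)
  ex <- enum_null(as.numeric(prof), 1)
  ses_exact <- (unname(prof["s1"]) - ex$mean) / ex$sd
  expect_gt(ses_exact, 0)
  tb <- compute_mslip_ses(ds, n_draws = 5000, seed = 21)
  expect_gt(tb$ses[1], 0)
})
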