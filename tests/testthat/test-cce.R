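test_that("lognormal calibration reproduces its defining bounds", {
  # butadiene BMD bounds from the packaged potency table
  spec <- lognormal_from_bounds(bounded_quantity(30.3, 56))
  expect_equal(spec$mu, 3.71825, tolerance = 1e-5)
  expect_equal(spec$sigma, 0.18670, tolerance = 1e-4)
  z <- qnorm(0.95)
  expect_equal(exp(spec$mu - z * spec$sigma), 30.3, tolerance = 1e-10)
  expect_equal(exp(spec$mu + z * spec$sigma), 56, tolerance = 1e-10)
  # degenerate bounds give a point mass
  pm <- lognormal_from_bounds(bounded_quantity(10, 10))
  expect_equal(pm$sigma, 0)
  expect_error(bounded_quantity(20, 10), ">= lb")
  # non-90% bounds need an explicit z
  b80 <- bounded_quantity(2, 8, confidence = 0.80)
  expect_error(lognormal_from_bounds(b80), "not 90%")
  expect_silent(lognormal_from_bounds(b80, z = qnorm(0.90)))
})

test_that("point-mass inputs collapse the CCE to the emission ratio", {
  # one compound: the RPF cancels; any value gives CCE = E_cig / E_alt
  for (r in c(0.2, 1, 37)) {
    res <- sample_cce(list(x = point_bq(50)), list(x = point_bq(5)),
                      list(x = point_bq(r)), n = 100, seed = 1)
    expect_true(all(res$samples == 10))
  }
  # identical products: CCE identically 1 even with sampled RPFs
  e <- list(a = point_bq(3), b = point_bq(11))
  rpf <- list(a = bounded_quantity(0.5, 8), b = point_bq(1))
  res <- sample_cce(e, e, rpf, n = 1000, seed = 2)
  expect_equal(max(abs(res$samples - 1)), 0)
})

test_that("CCE sampling is seed-deterministic and validates compound sets", {
  rpfs <- case_study_rpfs()
  em <- case_study_emissions()
  r1 <- sample_cce(em$cigarette, em$htp, rpfs, n = 5000, seed = 7)
  r2 <- sample_cce(em$cigarette, em$htp, rpfs, n = 5000, seed = 7)
  expect_identical(r1$samples, r2$samples)
  r3 <- sample_cce(em$cigarette, em$htp, rpfs, n = 5000, seed = 8)
  expect_false(identical(r1$samples, r3$samples))
  expect_error(
    sample_cce(em$cigarette[-1], em$htp, rpfs, n = 10, seed = 1),
    "compound sets differ.*Butadiene")
})

test_that("sampling does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(sample_cce(list(x = bounded_quantity(1, 2)),
                       list(x = bounded_quantity(1, 2)),
                       list(x = point_bq(1)), n = 100, seed = 42))
  expect_identical(runif(1), before)
})

test_that("lower alternative emissions never lower the CCE percentiles", {
  rpfs <- case_study_rpfs()
  em <- case_study_emissions()
  base <- sample_cce(em$cigarette, em$htp, rpfs, n = 2e4, seed = 3)
  smaller <- em$htp
  smaller[["Formaldehyde"]] <- bounded_quantity(
    smaller[["Formaldehyde"]]$lb / 3, smaller[["Formaldehyde"]]$ub / 3)
  shifted <- sample_cce(em$cigarette, smaller, rpfs, n = 2e4, seed = 3)
  expect_gte(shifted$p05, base$p05)
  expect_gte(shifted$p50, base$p50)
  expect_gte(shifted$p95, base$p95)
})

test_that("rescaling all RPFs by a point factor leaves CCE draws unchanged", {
  e_cig <- list(a = point_bq(50), b = point_bq(10))
  e_alt <- list(a = point_bq(5), b = point_bq(1))
  rpf <- list(a = point_bq(2), b = point_bq(40))
  r1 <- sample_cce(e_cig, e_alt, rpf, n = 1000, seed = 5)
  resc <- reference_rescale(rpf, "b")
  expect_equal(resc$b$lb, 1)
  r2 <- sample_cce(e_cig, e_alt, resc, n = 1000, seed = 5)
  expect_identical(r1$samples, r2$samples)
  expect_error(reference_rescale(rpf, "zz"), "unknown reference")
  # rescaling by the reference itself (point RPF 1) is the identity
  self <- reference_rescale(list(a = point_bq(1), b = rpf$b), "a")
  expect_equal(self$b$ub, rpf$b$ub)
})

test_that("health translation counts effect-size halvings and applies the rubric", {
  h0 <- health_translation(1, 1)
  expect_equal(h0$h_lower, 0)
  expect_match(h0$verdict, "no ")
  h1 <- health_translation(2, 2, halving_factor = 2)
  expect_equal(h1$h_lower, 1)
  h <- health_translation(10, 25, halving_factor = 2)
  expect_equal(h$h_lower, 3.3219, tolerance = 1e-4)
  expect_equal(h$h_upper, 4.6439, tolerance = 1e-4)
  expect_match(h$verdict, "substantial reduction")
  expect_match(health_translation(0.2, 0.8)$verdict, "increase in harm")
  expect_match(health_translation(0.8, 3)$verdict, "spans")
})

test_that("contribution shares sum to one and flag the dominant compound", {
  res <- sample_cce(list(a = point_bq(30), b = point_bq(10)),
                    list(a = point_bq(1), b = point_bq(3)),
                    list(a = point_bq(1), b = point_bq(1)),
                    n = 500, seed = 1)
  tab <- contribution_report(res)
  expect_equal(sum(tab$share_cig), 1, tolerance = 1e-12)
  expect_equal(sum(tab$share_alt), 1, tolerance = 1e-12)
  expect_equal(tab$compound[tab$dominant_cig], "a")
  expect_equal(tab$compound[tab$dominant_alt], "b")
  # single compound: share exactly 1
  one <- sample_cce(list(x = point_bq(2)), list(x = point_bq(1)),
                    list(x = point_bq(1)), n = 10, seed = 1)
  expect_equal(contribution_report(one)$share_cig, 1)
})
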