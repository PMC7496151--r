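test_that("a pure dose rescaling is recovered as the exact RPF", {
  # compound B's doses are A's divided by 4 with identical counts: the
  # curves are shifted by log 4, so RPF(B vs A) = 4 at the MLE
  set.seed(11)
  a <- draw_dataset("A", n = 50)
  b <- make_dataset("B", dose = a$dose / 4, x = a$n_affected, n = 50)
  cov <- fit_covariate(list(a, b), "A")
  rpf_b <- cov$rpf$rpf[cov$rpf$compound_id == "B"]
  expect_equal(rpf_b, 4, tolerance = 1e-4)
  expect_true(cov$rpf$lb[2] < 4 && cov$rpf$ub[2] > 4)
  # reference against itself: exactly 1 with degenerate interval
  ref_row <- cov$rpf[cov$rpf$compound_id == "A", ]
  expect_identical(ref_row$rpf, 1)
  expect_identical(c(ref_row$lb, ref_row$ub), c(1, 1))
})

test_that("RPFs and their intervals do not depend on the BMR", {
  set.seed(21)
  ds <- list(draw_dataset("A", n = 50), draw_dataset("B", beta = 25, n = 50),
             draw_dataset("C", beta = 400, n = 50))
  f10 <- fit_covariate(ds, "A", bmr = 0.10)
  f05 <- fit_covariate(ds, "A", bmr = 0.05)
  expect_equal(f05$rpf$rpf, f10$rpf$rpf, tolerance = 1e-6)
  expect_equal(f05$rpf$lb, f10$rpf$lb, tolerance = 1e-6)
  expect_equal(f05$rpf$ub, f10$rpf$ub, tolerance = 1e-6)
  # BMDs themselves do change with the BMR
  expect_false(isTRUE(all.equal(f05$fit$bmd, f10$fit$bmd)))
})

test_that("RPFs are invariant to a common rescaling of all doses", {
  set.seed(31)
  ds <- list(draw_dataset("A", n = 50), draw_dataset("B", beta = 25, n = 50))
  scaled <- lapply(ds, function(d) {
    d$dose <- d$dose * 1000
    d
  })
  f1 <- fit_covariate(ds, "A")
  f2 <- fit_covariate(scaled, "A")
  expect_equal(f2$rpf$rpf, f1$rpf$rpf, tolerance = 1e-4)
  expect_equal(f2$rpf$lb, f1$rpf$lb, tolerance = 1e-3)
})

test_that("the joint fit validates its inputs", {
  set.seed(41)
  a <- draw_dataset("A")
  b <- draw_dataset("B")
  expect_error(fit_covariate(list(a), "A"), "at least 2")
  expect_error(fit_covariate(list(a, b), "Z"), "reference compound")
  b_unit <- b; b_unit$dose_unit <- "ppm"
  expect_error(fit_covariate(list(a, b_unit), "A"), "dose unit")
  b_sev <- draw_dataset("B", severity = 2)
  expect_error(fit_covariate(list(a, b_sev), "A"), "severity")
})

test_that("critical-dataset selection takes the lowest BMD, deterministically", {
  set.seed(51)
  # same compound, two tissues with clearly different potencies
  lo <- make_dataset("A", beta = 50, n = 100, tissue = "nose")
  hi <- make_dataset("A", beta = 200, n = 100, tissue = "lung")
  other <- make_dataset("B", beta = 100, n = 100)
  sel <- select_critical(list(hi, lo, other))
  expect_equal(sel[["A"]]$tissue, "nose")
  expect_length(sel, 2L)
  # single dataset per compound: itself
  expect_equal(select_critical(list(other))[["B"]], other)
  # permutation invariance, including exact ties (key order decides)
  tie1 <- make_dataset("A", n = 100, tissue = "kidney")
  tie2 <- make_dataset("A", n = 100, tissue = "liver")
  s1 <- select_critical(list(tie1, tie2))
  s2 <- select_critical(list(tie2, tie1))
  expect_equal(s1[["A"]]$tissue, s2[["A"]]$tissue)
})

test_that("parallelism check accepts parallel data and rejects 3x steepness splits", {
  # null: shared g -> LR small, p not extreme, over a few seeded replicates
  set.seed(61)
  pvals <- replicate(25, {
    ds <- list(draw_dataset("A", n = 100), draw_dataset("B", beta = 25, n = 100))
    check_parallelism(ds, "A")$p_value
  })
  expect_gt(mean(pvals > 0.05), 0.75)  # close to the nominal 95%
  # alternative: g of 1.2 vs 3.6 at n=500/group is essentially always caught
  set.seed(62)
  rej <- replicate(10, {
    ds <- list(draw_dataset("A", n = 500, g = 1.2),
               draw_dataset("B", n = 500, g = 3.6))
    check_parallelism(ds, "A")$p_value < 0.05
  })
  expect_gte(mean(rej), 0.9)
  # single compound: not applicable
  expect_false(check_parallelism(list(draw_dataset("A")), "A")$applicable)
})

test_that("severity-specific intervals pool as a lognormal mixture", {
  one <- data.frame(compound_id = "x", reference_id = "r", severity = 2,
                    rpf = 4, lb = 2, ub = 8)
  out <- combine_severity_rpfs(one)
  expect_equal(c(out$lb, out$ub), c(2, 8))
  expect_equal(out$severity, "combined")

  two_same <- rbind(one, transform(one, severity = 3))
  out2 <- combine_severity_rpfs(two_same)
  expect_equal(c(out2$lb, out2$ub), c(2, 8), tolerance = 1e-6)

  # frozen from an independent 2e7-draw mixture simulation (and analytic
  # CDF inversion): intervals (1,4) and (4,16) pool to (1.1654, 13.729)
  mixed <- data.frame(compound_id = "x", reference_id = "r",
                      severity = c(2, 3), rpf = c(2, 8),
                      lb = c(1, 4), ub = c(4, 16))
  outm <- combine_severity_rpfs(mixed)
  expect_equal(outm$lb, 1.1654, tolerance = 1e-3)
  expect_equal(outm$ub, 13.729, tolerance = 1e-3)
  expect_error(combine_severity_rpfs(rbind(mixed, transform(mixed, compound_id = "y"))),
               "single compound")
})
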