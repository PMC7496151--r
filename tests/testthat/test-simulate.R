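test_that("configurations validate the potency and emission inputs", {
  expect_error(simulation_config(true_rpfs = c(ref = 2), reference_id = "ref"),
               "must be 1")
  expect_error(simulation_config(true_rpfs = c(1, 2)), "named")
  expect_error(simulation_config(true_rpfs = c(a = 1, b = -2),
                                 reference_id = "a"), "positive")
  cfg <- simulation_config()
  expect_length(cfg$true_rpfs, 8L)
  expect_equal(unname(cfg$true_rpfs[cfg$reference_id]), 1)
  expect_equal(max(cfg$true_rpfs) / min(cfg$true_rpfs), 1e4)
})

test_that("simulated incidence converges to the model curve at large n", {
  cfg <- simulation_config(true_rpfs = c(ref = 1, a = 10),
                           reference_id = "ref",
                           group_size = 1e5, seed = 4)
  ds <- simulate_quantal(cfg)
  a <- ds[[which(vapply(ds, `[[`, character(1), "compound_id") == "a")]]
  p_true <- quantal_response(a$dose, cfg$background, cfg$beta_ref / 10,
                             cfg$steepness)
  expect_equal(a$n_affected / a$n_at_risk, p_true, tolerance = 0.01)
  # potency-adjusted dose grids span each compound's own response range
  expect_equal(a$dose, cfg$base_doses / 10)
})

test_that("equal potencies make compounds exchangeable in design", {
  cfg <- simulation_config(true_rpfs = c(ref = 1, a = 1, b = 1),
                           reference_id = "ref", seed = 5)
  ds <- simulate_quantal(cfg)
  expect_true(all(vapply(ds, function(d) identical(d$dose, cfg$base_doses),
                         logical(1))))
})

test_that("generation is reproducible under the config seed", {
  cfg <- simulation_config(seed = 6)
  expect_identical(simulate_quantal(cfg), simulate_quantal(cfg))
  expect_identical(simulate_emissions(cfg), simulate_emissions(cfg))
  cfg2 <- simulation_config(seed = 7)
  expect_false(identical(simulate_quantal(cfg), simulate_quantal(cfg2)))
})

test_that("emission replicates land on the configured geometric mean", {
  cfg <- simulation_config(
    true_rpfs = c(ref = 1), reference_id = "ref",
    emission_gm = data.frame(compound = "ref",
                             product = c("cigarette", "htp"),
                             gm = c(40, 4)),
    emission_gsd = 1.3, n_replicates = 1e4, seed = 8)
  reps <- simulate_emissions(cfg)
  gms <- vapply(reps, function(r) exp(mean(log(r$values))), numeric(1))
  expect_equal(gms, c(40, 4), tolerance = 0.01)
  # GSD of 1: replicates identical to the geometric mean
  cfg1 <- simulation_config(true_rpfs = c(ref = 1), reference_id = "ref",
                            emission_gsd = 1, n_replicates = 5, seed = 8)
  r1 <- simulate_emissions(cfg1)
  expect_true(all(vapply(r1, function(r) all(r$values == r$values[1]),
                         logical(1))))
})

test_that("the configured truth is plain potency-weighted arithmetic", {
  cfg <- simulation_config(
    true_rpfs = c(a = 1, b = 10, c = 100), reference_id = "a",
    emission_gm = rbind(
      data.frame(compound = c("a", "b", "c"), product = "cigarette",
                 gm = c(100, 10, 1)),
      data.frame(compound = c("a", "b", "c"), product = "htp",
                 gm = c(10, 1, 1))))
  expect_equal(end_to_end_truth(cfg), 2.5)  # 300 / 120
  cfg_one <- simulation_config(
    true_rpfs = c(a = 1), reference_id = "a",
    emission_gm = data.frame(compound = "a",
                             product = c("cigarette", "htp"),
                             gm = c(50, 5)))
  expect_equal(end_to_end_truth(cfg_one), 10)
  cfg_eq <- simulation_config(
    true_rpfs = c(a = 1, b = 3), reference_id = "a",
    emission_gm = rbind(
      data.frame(compound = c("a", "b"), product = "cigarette", gm = c(2, 5)),
      data.frame(compound = c("a", "b"), product = "htp", gm = c(2, 5))))
  expect_equal(end_to_end_truth(cfg_eq), 1)
})
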