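# in-code fixtures shared across test files

# dataset with expected (rounded) counts from the quantal exponential curve;
# n = 1000 makes the rounding error negligible ("noise-free" data)
make_dataset <- function(compound = "a", dose = c(0, 50, 100, 200), n = 50,
                         x = NULL, beta = 100, g = 1.2, bg = 0.05,
                         severity = 3, exposure = 104, tissue = "lung",
                         sex = "male", lesion = "carcinoma",
                         dose_unit = "mg/m3") {
  if (is.null(x)) x <- round(n * quantal_response(dose, bg, beta, g))
  quantal_dataset(compound, lesion, severity, tissue, sex, lesion,
                  exposure, exposure, dose, rep(n, length(dose)), x,
                  dose_unit = dose_unit)
}

# binomial draws from the same curve (seeded by the caller)
draw_dataset <- function(compound = "a", dose = c(0, 50, 100, 200), n = 50,
                         beta = 100, g = 1.2, bg = 0.05, severity = 3,
                         exposure = 104, tissue = "lung", sex = "male") {
  p <- quantal_response(dose, bg, beta, g)
  make_dataset(compound, dose, n, x = stats::rbinom(length(dose), n, p),
               beta, g, bg, severity, exposure, tissue, sex)
}

# two-dataset quantal CSV fixture (written fresh per test)
write_quantal_fixture <- function(path) {
  d1 <- make_dataset("aaa", n = 50)
  d2 <- make_dataset("bbb", dose = c(0, 25, 50, 100), n = 50, beta = 50)
  write_quantal_datasets(list(d1, d2), path)
  path
}

point_bq <- function(v) bounded_quantity(v, v)
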