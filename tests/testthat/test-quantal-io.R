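test_that("dataset constructor enforces its invariants", {
  expect_error(make_dataset(x = c(0, 1, 2)), "equal length")
  expect_error(make_dataset(dose = c(0, 50, 50, 100)), "strictly increasing")
  expect_error(
    quantal_dataset("a", "carcinoma", 3, "lung", "m", "c", 104, 104,
                    c(0, 10, 20), c(50, 50, 50), c(0, 60, 10)),
    "n_affected")
  expect_error(
    quantal_dataset("a", "carcinoma", 3, "lung", "m", "c", 104, 104,
                    c(-1, 10, 20), c(50, 50, 50), c(0, 5, 10)),
    "non-negative")
})

test_that("a two-dataset CSV reads back as two validated datasets", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_quantal_fixture(path)
  ds <- read_quantal_datasets(path)
  expect_length(ds, 2L)
  expect_true(all(vapply(ds, function(d) length(d$dose) == 4L, logical(1))))
  expect_setequal(vapply(ds, `[[`, character(1), "compound_id"),
                  c("aaa", "bbb"))
})

test_that("write/read round-trip is the identity on valid data", {
  path <- withr::local_tempfile(fileext = ".csv")
  orig <- list(make_dataset("aaa", n = 50),
               make_dataset("bbb", dose = c(0, 25, 50), n = 30, beta = 40),
               make_dataset("ccc", severity = 2, lesion = "adenoma"))
  write_quantal_datasets(orig, path)
  back <- read_quantal_datasets(path)
  key <- function(l) vapply(l, function(d) d$compound_id, character(1))
  back <- back[match(key(orig), key(back))]
  for (i in seq_along(orig)) expect_equal(back[[i]], orig[[i]])
})

test_that("malformed rows are rejected with their row number", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- utils::read.csv(write_quantal_fixture(path))
  df$n_affected[3] <- df$n_at_risk[3] + 5L
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_quantal_datasets(path), "row 4.*exceeds n_at_risk")

  df <- utils::read.csv(write_quantal_fixture(path))
  df$dose[2] <- df$dose[1]
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_quantal_datasets(path), "duplicate dose")
})

test_that("an empty file yields an empty dataset list", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste("compound_id,lesion_term,severity,tissue,sex,tumor_type,",
                   "exposure_weeks,study_weeks,dose,n_at_risk,n_affected",
                   sep = ""), path)
  expect_identical(read_quantal_datasets(path), list())
})

test_that("eligibility filter applies the exposure and severity rules", {
  ds <- list(make_dataset("a", exposure = 96),             # not > 96
             make_dataset("b", exposure = 97),
             make_dataset("c", exposure = 104, severity = 1,
                          lesion = "hyperplasia"),         # preneoplastic
             make_dataset("d", exposure = 150, severity = 5,
                          lesion = "tumor-bearing animals"))
  kept <- filter_eligible(ds)
  expect_setequal(vapply(kept, `[[`, character(1), "compound_id"),
                  c("b", "d"))
  # never grows, never mutates
  expect_lte(length(kept), length(ds))
  expect_equal(kept[[1]], ds[[2]])
  expect_identical(filter_eligible(list()), list())
})

test_that("dataset inventory counts datasets per compound and severity", {
  ds <- list(make_dataset("a"), make_dataset("a", sex = "female"),
             make_dataset("b", severity = 2, lesion = "adenoma"))
  inv <- dataset_inventory(ds)
  expect_equal(inv$n_datasets[inv$compound_id == "a" & inv$severity == 3], 2L)
  expect_equal(inv$n_groups[inv$compound_id == "b" & inv$severity == 2], 4L)
  expect_equal(nrow(dataset_inventory(list())), 0L)
})
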