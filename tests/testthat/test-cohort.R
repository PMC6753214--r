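test_that("cohort CSV round-trip preserves values, header and missingness", {
  specs <- toy_specs()
  d <- tibble::tibble(id = c("a", "b", "c"),
                      NRS3 = c(7, NA, 5.25),
                      SQ = c(55.5, 41, 12))
  co <- cohort(d, specs)
  expect_s3_class(co, "conselect_cohort")
  expect_equal(nrow(co), 3)

  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  lines <- readLines(path)
  expect_equal(lines[1], "id,NRS3,SQ")
  expect_match(lines[3], "^b,,41")  # missing encoded as empty field

  back <- read_cohort(path, specs)
  expect_equal(back$NRS3, co$NRS3)
  expect_equal(back$SQ, co$SQ)
})

test_that("round-trip is the identity on random tables", {
  for (seed in 1:3) {
    d <- withr::with_seed(seed, tibble::tibble(
      id = sprintf("s%02d", 1:20),
      NRS3 = round(runif(20, 0, 10), 3),
      SQ = replace(rnorm(20), sample(20, 3), NA)
    ))
    co <- cohort(d, toy_specs())
    path <- withr::local_tempfile(fileext = ".csv")
    write_cohort(co, path)
    back <- read_cohort(path, toy_specs())
    expect_equal(back$NRS3, d$NRS3)
    expect_equal(back$SQ, d$SQ)
  }
})

test_that("structural contracts: missing column, duplicate id, binary coding", {
  specs <- var_specs(name = c("id", "PDQ"), role = c("id", "candidate"))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(id = 1:2, other = 1:2), path)
  expect_error(read_cohort(path, specs), "PDQ")

  expect_error(
    cohort(tibble::tibble(id = c("a", "a"), NRS3 = 1:2, SQ = 1:2),
           toy_specs()),
    "Duplicate"
  )

  specs_b <- var_specs(name = c("id", "resp"), role = c("id", "candidate"),
                       scale = c("continuous", "binary"))
  expect_error(cohort(tibble::tibble(id = 1:3, resp = c(0, 1, 2)), specs_b),
               "distinct values")
  expect_silent(cohort(tibble::tibble(id = 1:3, resp = c(0, 1, 0)), specs_b))
})

test_that("zero-row cohorts write a header-only file", {
  co <- cohort(tibble::tibble(id = character(), NRS3 = numeric(),
                              SQ = numeric()), toy_specs())
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  expect_equal(readLines(path), "id,NRS3,SQ")
})

test_that("validate_cohort applies the 1-in-20 variables-per-case guard", {
  make <- function(n, k) {
    d <- withr::with_seed(1, tibble::as_tibble(as.data.frame(
      matrix(rnorm(n * (k + 2)), n))))
    names(d) <- c("y", "y_pre", paste0("c", seq_len(k)))
    d
  }
  cfg7 <- run_config("y", paste0("c", 1:7), "y_pre")
  cfg6 <- run_config("y", paste0("c", 1:6), "y_pre")
  expect_warning(validate_cohort(make(130, 7), cfg7), "7 candidate")
  expect_no_warning(validate_cohort(make(130, 6), cfg6))
  expect_error(validate_cohort(make(130, 6)[0, ], cfg6), "zero rows")
  expect_error(
    validate_cohort(dplyr::rename(make(130, 6), z = "y"), cfg6),
    "Outcome column"
  )

  d <- make(50, 6)
  d$c1[1:5] <- NA
  rep <- suppressWarnings(validate_cohort(d, cfg6))
  expect_equal(rep$n_missing[rep$variable == "c1"], 5L)
})

test_that("run configurations validate thresholds and round-trip as YAML", {
  expect_error(run_config("y", "x", "y_pre", weak_alpha = 0.001,
                          strong_alpha = 0.05), "strong_alpha")
  expect_error(run_config("y", "x", "y_pre", variables_per_case = 0),
               "variables_per_case")
  expect_error(run_config("y", "y", "y_pre"), "own candidate")

  cfg <- run_config("y", c("a", "b"), "y_pre", bootstrap_reps = 50, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back, cfg)
})
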