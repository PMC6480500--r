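test_that("construction validates counts and age grids, naming the offending cell", {
  expect_s3_class(toy_tab(), "age_crosstab")
  b <- matrix(10, 2, 2)
  expect_error(age_crosstab(20:21, 25:26, b, matrix(c(1, 1, 11, 1), 2, 2)),
               "cases exceed births.*maternal 20, paternal 26")
  expect_error(age_crosstab(20:21, 25:26, b, matrix(-1, 2, 2)),
               "non-negative")
  expect_error(age_crosstab(c(20, 22), 25:26, b, matrix(0, 2, 2)),
               "steps of 1")
  expect_error(age_crosstab(20:21, 25:26, matrix(10, 3, 2), matrix(0, 3, 2)),
               "matrices matching")
  expect_error(age_crosstab(20:21, 25:26, matrix(2.5, 2, 2), matrix(0, 2, 2)),
               "non-negative integers")
})

test_that("validation rejects every single-cell corruption of cases <= births", {
  set.seed(42)
  for (rep in 1:20) {
    tab <- toy_tab()
    j <- sample(3, 1); k <- sample(4, 1)
    cases <- tab$cases
    cases[j, k] <- tab$births[j, k] + sample(1:5, 1)
    expect_error(
      age_crosstab(tab$maternal_ages, tab$paternal_ages, tab$births, cases),
      paste0("maternal ", tab$maternal_ages[j], ", paternal ",
             tab$paternal_ages[k]))
  }
})

test_that("CSV round-trip is the identity, including empty outcomes and simulated tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- toy_tab()
  write_crosstab(tab, path)
  back <- read_crosstab(path, outcome = "toy")
  expect_identical(back$births, tab$births)
  expect_identical(back$cases, tab$cases)
  expect_identical(back$maternal_ages, tab$maternal_ages)

  tab$cases[] <- 0L
  write_crosstab(tab, path)
  expect_equal(sum(read_crosstab(path)$cases), 0)

  sim <- simulate_crosstab(small_scenario(), seed = 5)
  write_crosstab(sim$tab, path)
  back <- read_crosstab(path)
  expect_identical(back$births, sim$tab$births)
  expect_identical(back$cases, sim$tab$cases)
})

test_that("missing and duplicated cells are rejected; allow_sparse zero-fills", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(maternal_age = c(20, 20, 21), paternal_age = c(30, 31, 30),
                  births = c(10, 20, 30), cases = c(1, 2, 3))
  write.csv(d, path, row.names = FALSE)
  expect_error(read_crosstab(path), "missing cell.*allow_sparse")
  tab <- read_crosstab(path, allow_sparse = TRUE)
  expect_equal(tab$births[2, 2], 0)
  expect_equal(sum(tab$births), 60)

  d2 <- rbind(d, d[1, ])
  write.csv(d2, path, row.names = FALSE)
  expect_error(read_crosstab(path), "duplicated cell")

  d3 <- d; d3$cases[1] <- 11
  write.csv(d3, path, row.names = FALSE)
  expect_error(read_crosstab(path, allow_sparse = TRUE),
               "cases exceed births")
})

test_that("BUGS rectangular blocks parse in row-major order; vectors give margins", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste0(
    "list(Y = structure(.Data = c(1, 0, 2, 0, 1, 0),  .Dim = c(2, 3)),\n",
    "     n = structure(.Data = c(10, 20, 30, 40, 50, 60), .Dim = c(2, 3)))"),
    path)
  tab <- read_crosstab(path, "bugs_rectangular",
                       maternal_ages = 20:21, paternal_ages = 30:32)
  # .Data is row-major: first row of Y is (1, 0, 2)
  expect_equal(unname(tab$cases[1, ]), c(1, 0, 2))
  expect_equal(unname(tab$births[2, ]), c(40, 50, 60))

  writeLines("list(Y = c(1, 2, 3), n = c(10, 20, 30))", path)
  marg <- read_crosstab(path, "bugs_rectangular",
                        maternal_ages = 20:22, paternal_ages = 30:34)
  expect_s3_class(marg, "age_margin")
  expect_equal(marg$parent, "maternal")
  expect_equal(marg$cases, c(1, 2, 3))
})

test_that("marginalize conserves grand totals over both axes", {
  sim <- simulate_crosstab(small_scenario(), seed = 7)
  for (parent in c("maternal", "paternal")) {
    m <- marginalize(sim$tab, parent)
    expect_identical(sum(m$births), sum(sim$tab$births))
    expect_identical(sum(m$cases), sum(sim$tab$cases))
  }
  m <- marginalize(toy_tab(), "maternal")
  expect_equal(m$births, unname(rowSums(toy_tab()$births)))
})
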