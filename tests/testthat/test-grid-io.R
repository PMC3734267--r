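test_that("ESRI ASCII grids roundtrip including missing cells", {
  m <- matrix(runif(12), 3, 4)
  m[2, 3] <- NA
  g <- sivva_grid(m, cellsize = 0.5, xll = 10, yll = -5)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(g, path)
  g2 <- read_ascii_grid(path)
  expect_equal(g2$values, g$values, tolerance = 1e-9)
  expect_equal(g2$cellsize, 0.5)
  expect_equal(g2$xll, 10)
  expect_equal(g2$yll, -5)
})

test_that("reader flips north-first file rows to south-first matrices", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0", "cellsize 1",
    "3 4", # northern row in the file
    "1 2"  # southern row
  ), path)
  g <- read_ascii_grid(path)
  expect_equal(g$values[1, ], c(1, 2)) # row 1 = southernmost
  expect_equal(g$values[2, ], c(3, 4))
})

test_that("malformed headers and size mismatches are rejected", {
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "xllcorner 0", "cellsize 1", "1 2"), path)
  expect_error(read_ascii_grid(path), "nrows")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "1 2 3"), path)
  expect_error(read_ascii_grid(path), "does not match")
})

test_that("scoresheet and trait CSVs roundtrip through the readers", {
  cfg <- sim_config(seed = 5, n_pairs = 2)
  sheets <- sim_scoresheets(cfg)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_scoresheets(sheets, p1)
  expect_equal(as.data.frame(read_scoresheets(p1)), as.data.frame(sheets))
  traits <- sim_traits(cfg)
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(traits, p2)
  expect_equal(as.data.frame(read_trait_table(p2)), as.data.frame(traits))
})

test_that("shipped synthetic example files load through the readers", {
  sheets <- read_scoresheets(system.file("extdata", "synthetic_scoresheets.csv",
                                         package = "sivva"))
  expect_equal(length(unique(sheets$taxon_id)), 4)
  traits <- read_trait_table(system.file("extdata", "synthetic_traits.csv",
                                         package = "sivva"))
  expect_true(all(traits$value > 0))
  dem <- read_ascii_grid(system.file("extdata", "synthetic_dem.asc",
                                     package = "sivva"))
  expect_equal(dim(dem), c(12, 20))
})
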