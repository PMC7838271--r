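test_that("spectrum normalization scales to peak 1 and is idempotent", {
  s <- spectrum(c(500, 501, 502), c(2, 4, 1))
  ns <- normalize_spectrum(s)
  expect_equal(ns$intensities, c(0.5, 1.0, 0.25))
  expect_equal(normalize_spectrum(ns), ns)
  expect_error(normalize_spectrum(spectrum(1:3 + 500, c(0, 0, 0))),
               "all-zero")
  expect_error(spectrum(c(500, 500), c(1, 1)), "ascending")
  expect_error(spectrum(c(500, 501), c(1, -1)), "negative")
})

test_that("resampling interpolates linearly and is zero outside support", {
  s <- spectrum(c(500, 502), c(0, 1))
  r <- resample_spectrum(s)
  g <- working_grid()
  expect_equal(r$intensities[g == 501], 0.5)
  expect_equal(r$intensities[g == 502], 1)
  expect_equal(r$intensities[g == 700], 0)   # past support
  expect_equal(r$intensities[g == 400], 0)   # before support
  # already on grid: identity; resampling twice: idempotent
  r2 <- resample_spectrum(r)
  expect_identical(r2$intensities, r$intensities)
  # degenerate single point becomes a delta on the nearest grid point
  d <- resample_spectrum(spectrum(550.4, 3))
  expect_equal(d$intensities[g == 550], 3)
  expect_equal(sum(d$intensities > 0), 1L)
})

test_that("library reading normalizes spectra and rescales brightness", {
  lines <- c("fluorophore,kind,wavelength_nm,intensity",
             "A,ex,480,1", "A,ex,490,2", "A,em,520,3", "A,em,540,1",
             "B,ex,530,0.5", "B,ex,545,1", "B,em,570,2", "B,em,600,2")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, f)
  lib <- read_fluorophore_library(f)
  expect_length(lib, 2)
  expect_named(lib, c("A", "B"))
  for (fl in lib) {
    expect_equal(max(fl$excitation$intensities), 1)
    expect_equal(max(fl$emission$intensities), 1)
  }
  # brightness {A: 2.0, B: 1.0} -> {A: 1.0, B: 0.5}
  bf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("fluorophore,brightness", "A,2.0", "B,1.0"), bf)
  lib2 <- read_fluorophore_library(f, brightness_path = bf)
  expect_equal(lib2$A$brightness, 1.0)
  expect_equal(lib2$B$brightness, 0.5)
  # brightness for unknown fluorophore errors
  writeLines(c("fluorophore,brightness", "A,2.0", "Z,1.0"), bf)
  expect_error(read_fluorophore_library(f, brightness_path = bf), "Z")
})

test_that("all-zero emission is rejected naming the fluorophore", {
  lines <- c("fluorophore,kind,wavelength_nm,intensity",
             "Good,ex,480,1", "Good,em,520,1",
             "Dead,ex,480,1", "Dead,em,520,0", "Dead,em,530,0")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, f)
  expect_error(read_fluorophore_library(f), "Dead")
})

test_that("library round-trips through write/read unchanged", {
  lib <- generate_library(synthetic_spec(n_fluorophores = 3, seed = 11))
  f <- withr::local_tempfile(fileext = ".csv")
  b <- withr::local_tempfile(fileext = ".csv")
  write_fluorophore_library(lib, f, brightness_path = b)
  lib2 <- read_fluorophore_library(f, brightness_path = b)
  expect_named(lib2, names(lib))
  for (nm in names(lib)) {
    expect_equal(lib2[[nm]]$excitation$intensities,
                 lib[[nm]]$excitation$intensities, tolerance = 1e-12)
    expect_equal(lib2[[nm]]$emission$intensities,
                 lib[[nm]]$emission$intensities, tolerance = 1e-12)
    expect_equal(lib2[[nm]]$brightness, lib[[nm]]$brightness,
                 tolerance = 1e-12)
  }
})

test_that("instrument configs parse from JSON and YAML with validation", {
  # 5-laser / 19-detector layout (large spectral cytometer scale)
  inst <- generate_instrument()
  expect_length(inst$detectors, 19)
  f <- withr::local_tempfile(fileext = ".json")
  write_instrument_config(inst, f)
  inst2 <- read_instrument_config(f)
  expect_equal(length(inst2$detectors), 19)
  expect_equal(vapply(inst2$detectors, `[[`, integer(1), "bandpass_lo"),
               vapply(inst$detectors, `[[`, integer(1), "bandpass_lo"))
  # 3-laser / 7-detector layout
  small <- generate_instrument(laser_wavelengths = c(405, 488, 561),
                               detectors_per_laser = c(2, 2, 3))
  expect_length(small$detectors, 7)
  # YAML dialect
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    name = "y", lasers = list(list(name = "L1", wavelength_nm = 488)),
    detectors = list(list(name = "D1", laser = "L1",
                          bandpass_lo_nm = 500, bandpass_hi_nm = 550))), fy)
  expect_length(read_instrument_config(fy)$detectors, 1)
  # inverted bandpass and dangling laser reference are errors
  expect_error(detector("bad", laser("L", 488), 600, 580), "bandpass")
  fy2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    name = "y", lasers = list(list(name = "L1", wavelength_nm = 488)),
    detectors = list(list(name = "D1", laser = "NOPE",
                          bandpass_lo_nm = 500, bandpass_hi_nm = 550))), fy2)
  expect_error(read_instrument_config(fy2), "unknown laser")
})

test_that("autofluorescence keys must be detector names and non-negative", {
  l <- laser("L", 488)
  d <- detector("D1", l, 500, 540)
  expect_error(instrument("i", list(l), list(d),
                          autofluorescence = c(DX = 0.1)), "unknown")
  expect_error(instrument("i", list(l), list(d),
                          autofluorescence = c(D1 = -1)), ">= 0")
  inst <- instrument("i", list(l), list(d), autofluorescence = c(D1 = 0.2))
  expect_equal(inst$autofluorescence[["D1"]], 0.2)
})
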