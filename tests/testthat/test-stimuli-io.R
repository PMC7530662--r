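test_that("load_image scales 8-bit rasters to the unit interval", {
  d <- withr::local_tempdir()
  white <- file.path(d, "white.png")
  png::writePNG(array(1, dim = c(8, 8, 3)), white)
  fr <- load_image(white)
  expect_s3_class(fr, "retina_frame")
  expect_true(all(fr$pixels == 1))

  black <- file.path(d, "black.png")
  png::writePNG(array(0, dim = c(8, 8, 3)), black)
  expect_true(all(load_image(black)$pixels == 0))

  mid <- file.path(d, "mid.png")
  png::writePNG(array(128L / 255, dim = c(8, 8)), mid)
  fr <- load_image(mid)
  # 8-bit value 128 decodes to 128/255, replicated onto 3 channels
  expect_equal(unique(as.vector(fr$pixels)), 128 / 255, tolerance = 1e-7)
  expect_equal(dim(fr$pixels)[3], 3L)
})

test_that("load_image reports unreadable files with their path", {
  expect_error(load_image("/nonexistent/img.png"), "img.png")
  d <- withr::local_tempdir()
  bad <- file.path(d, "corrupt.png")
  writeLines("not a png", bad)
  expect_error(load_image(bad), "corrupt.png")
})

test_that("resize_frame is the identity at the native size and on constants", {
  fr <- gray_frame(16, 16, 0.5)
  expect_identical(resize_frame(fr, c(16, 16))$pixels, fr$pixels)
  big <- gray_frame(32, 32, 0.5)
  small <- resize_frame(big, c(16, 16))
  expect_true(all(abs(small$pixels - 0.5) < 1e-12))
  expect_error(resize_frame(fr, c(4, 16)), ">= 8")
})

test_that("resize_frame matches the direct bilinear-interpolation oracle", {
  set.seed(42)
  m <- matrix(runif(64), 8, 8)
  fr <- retina_frame(array(rep(m, 3), dim = c(8, 8, 3)))
  out <- resize_frame(fr, c(16, 16))
  for (r in c(1, 5, 9, 16)) {
    for (c in c(1, 7, 12, 16)) {
      expect_equal(out$pixels[r, c, 1],
                   bilinear_oracle_pixel(m, r, c, 16, 16),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(out$pixels >= 0 & out$pixels <= 1))
})

test_that("scanpath files parse, reorder by onset, and clamp with warnings", {
  d <- withr::local_tempdir()
  f <- file.path(d, "sp.csv")
  writeLines(c("x,y,onset,duration",
               "10,20,0.0,0.2",
               "30,40,0.3,0.25"), f)
  sp <- read_scanpath(f, frame_size = c(100, 100))
  expect_equal(nrow(sp), 2L)
  expect_equal(sp$x, c(10, 30))

  writeLines("x,y,onset,duration", f)
  expect_error(read_scanpath(f, frame_size = c(100, 100)), "parseable")

  writeLines(c("x,y,onset,duration",
               "30,40,0.3,0.25",
               "10,20,0.0,0.2"), f)
  expect_warning(sp <- read_scanpath(f, frame_size = c(100, 100)),
                 "reordered")
  expect_equal(sp$onset, c(0.0, 0.3))
  expect_equal(sp$x, c(10, 30))

  writeLines(c("x,y,onset,duration", "150,20,0.0,0.2"), f)
  expect_warning(sp <- read_scanpath(f, frame_size = c(100, 100)),
                 "clamped")
  expect_equal(sp$x, 99)
})

test_that("the dialect column map supports alternative layouts", {
  d <- withr::local_tempdir()
  f <- file.path(d, "alt.tsv")
  writeLines(c("fy\tfx\tdur", "20\t10\t0.2", "40\t30\t0.3"), f)
  sp <- read_scanpath(
    f, frame_size = c(64, 64),
    dialect = scanpath_dialect(x = "fx", y = "fy", onset = NA,
                               duration = "dur", sep = "\t")
  )
  expect_equal(sp$x, c(10, 30))
  # missing onsets are synthesized as cumulative durations
  expect_equal(sp$onset, c(0, 0.2))
})

test_that("write_scanpath round-trips through read_scanpath", {
  d <- withr::local_tempdir()
  f <- file.path(d, "rt.csv")
  sp <- scanpath(c(1.25, 30.5, 63), c(2, 40.125, 10),
                 duration = c(0.2, 0.3, 0.25), frame_size = c(64, 64))
  write_scanpath(sp, f)
  back <- read_scanpath(f, frame_size = c(64, 64))
  expect_equal(as.data.frame(back), as.data.frame(sp), tolerance = 1e-6)

  empty <- scanpath(numeric(0), numeric(0), duration = numeric(0),
                    frame_size = c(64, 64))
  write_scanpath(empty, f)
  expect_identical(readLines(f), "x,y,onset,duration")
})

test_that("round-trip preserves 1000 random fixations within 1e-6", {
  set.seed(7)
  sp <- random_scanpath(1000, c(512, 512))
  d <- withr::local_tempdir()
  f <- file.path(d, "big.csv")
  write_scanpath(sp, f)
  back <- read_scanpath(f, frame_size = c(512, 512))
  expect_lt(max(abs(back$x - sp$x)), 1e-6)
  expect_lt(max(abs(back$y - sp$y)), 1e-6)
  expect_lt(max(abs(back$onset - sp$onset)), 1e-6)
  expect_lt(max(abs(back$duration - sp$duration)), 1e-6)
})

test_that("scanpath invariants are enforced", {
  expect_error(scanpath(1, 1, onset = 0, duration = -0.1,
                        frame_size = c(64, 64)), "positive")
  expect_error(scanpath(c(1, 2), c(1, 2), onset = c(0.5, 0.2),
                        duration = c(0.1, 0.1), frame_size = c(64, 64)),
               "increasing")
  expect_error(scanpath(70, 1, onset = 0, duration = 0.1,
                        frame_size = c(64, 64)), "inside")
})
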