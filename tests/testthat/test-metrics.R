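test_that("scanpaths quantize to row-major cell labels", {
  sp <- scanpath(c(10, 50, 99), c(10, 10, 99),
                 duration = rep(0.2, 3), frame_size = c(100, 100))
  lab <- scanpath_to_string(sp, c(100, 100), grid_m = 2)
  expect_equal(attr(lab, "cell"), c(0L, 1L, 3L))  # boundary x=50 -> right
  expect_equal(as.character(lab[1]), "a")

  set.seed(18)
  sp <- random_scanpath(20, c(64, 64))
  lab <- scanpath_to_string(sp, c(64, 64), grid_m = 5)
  oracle <- floor(sp$y * 5 / 64) * 5 + floor(sp$x * 5 / 64)
  expect_equal(attr(lab, "cell"), as.integer(oracle))

  bad <- scanpath(10, 10, duration = 0.2, frame_size = c(100, 100))
  expect_error(scanpath_to_string(bad, c(5, 5)), "outside")
})

test_that("edit_distance is the unit-cost Levenshtein distance", {
  expect_equal(edit_distance(letters[1:3], letters[1:3]), 0L)
  expect_equal(edit_distance(c("a", "b", "c"), character(0)), 3L)
  expect_equal(edit_distance(strsplit("kitten", "")[[1]],
                             strsplit("sitting", "")[[1]]), 3L)

  set.seed(19)
  alphabet <- letters[1:8]
  rand_str <- function() sample(alphabet, sample(0:10, 1), replace = TRUE)
  for (i in 1:30) {
    s1 <- rand_str(); s2 <- rand_str(); s3 <- rand_str()
    d12 <- edit_distance(s1, s2)
    # agreement with the generalized-distance oracle
    expect_equal(d12,
                 drop(utils::adist(paste(s1, collapse = ""),
                                   paste(s2, collapse = ""))))
    # metric axioms
    expect_equal(edit_distance(s1, s1), 0L)
    expect_equal(d12, edit_distance(s2, s1))
    expect_lte(d12, edit_distance(s1, s3) + edit_distance(s3, s2))
  }
})

test_that("sed compares quantized sequences", {
  sp <- random_scanpath(8, c(100, 100))
  expect_equal(sed(sp, sp), 0L)
  a <- scanpath(5, 5, duration = 0.2, frame_size = c(100, 100))
  b <- scanpath(7, 7, duration = 0.2, frame_size = c(100, 100))
  c_ <- scanpath(95, 95, duration = 0.2, frame_size = c(100, 100))
  expect_equal(sed(a, b), 0L)  # same cell
  expect_equal(sed(a, c_), 1L) # different cells
  set.seed(20)
  for (i in 1:10) {
    p <- random_scanpath(6); q <- random_scanpath(9)
    expect_equal(sed(p, q), sed(q, p))
  }
  empty <- scanpath(numeric(0), numeric(0), duration = numeric(0),
                    frame_size = c(100, 100))
  expect_error(sed(empty, sp), "empty")
})

test_that("tde matches its definition and the window oracle", {
  sp <- random_scanpath(6)
  expect_equal(tde(sp, sp, 3), 0)
  h <- scanpath(0, 0, duration = 0.2, frame_size = c(100, 100))
  s <- scanpath(3, 4, duration = 0.2, frame_size = c(100, 100))
  expect_equal(tde(h, s, 1), 5)
  expect_error(tde(h, s, 2), "at least")

  set.seed(22)
  for (i in 1:20) {
    h <- random_scanpath(sample(3:8, 1))
    s <- random_scanpath(sample(3:8, 1))
    k <- sample(1:3, 1)
    expect_equal(tde(h, s, k), brute_force_tde(h, s, k),
                 tolerance = 1e-12)
  }
})

test_that("stde is an exp-similarity on frame-normalized coordinates", {
  sp <- random_scanpath(5)
  expect_equal(stde(sp, sp, embed_k = 2), 1)

  h <- scanpath(0, 0, duration = 0.2, frame_size = c(100, 100))
  s <- scanpath(30, 40, duration = 0.2, frame_size = c(100, 100))
  expect_equal(stde(h, s, c(100, 100), 1), exp(-0.5), tolerance = 1e-12)

  # monotone decrease as the simulated path drifts away
  vals <- vapply(c(0, 10, 25, 50), function(shift) {
    s2 <- scanpath(shift, 0, duration = 0.2, frame_size = c(100, 100))
    stde(h, s2, c(100, 100), 1)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))

  # invariance under joint rescaling of scanpaths and frame
  set.seed(23)
  p <- random_scanpath(5, c(100, 100))
  q <- random_scanpath(5, c(100, 100))
  p2 <- scanpath(p$x * 3, p$y * 3, p$onset, p$duration, c(300, 300))
  q2 <- scanpath(q$x * 3, q$y * 3, q$onset, q$duration, c(300, 300))
  expect_equal(stde(p, q, c(100, 100), 2), stde(p2, q2, c(300, 300), 2),
               tolerance = 1e-12)
})

test_that("nss is the mean z-scored saliency at fixations", {
  set.seed(24)
  s <- matrix(runif(64 * 64), 64, 64)

  # fixations tiling every pixel average to ~0
  xy <- expand.grid(x = 0:63, y = 0:63)
  all_fix <- scanpath(xy$x, xy$y, onset = seq_len(nrow(xy)) * 0.1,
                      duration = rep(0.05, nrow(xy)),
                      frame_size = c(64, 64))
  expect_lt(abs(nss(s, all_fix)), 1e-9)

  # a single fixation at the maximum scores (max - mean) / sd
  im <- which(s == max(s), arr.ind = TRUE)
  fx <- scanpath(im[1, "col"] - 1, im[1, "row"] - 1, duration = 0.2,
                 frame_size = c(64, 64))
  expect_equal(nss(s, fx), (max(s) - mean(s)) / sd(s), tolerance = 1e-12)

  # affine invariance of the map
  expect_equal(nss(5 * s + 2, fx), nss(s, fx), tolerance = 1e-12)
  expect_error(nss(matrix(1, 8, 8), fx), "constant")
})

test_that("evaluate_image averages metrics over observers", {
  sim <- random_scanpath(6)
  v <- evaluate_image(sim, list(sim))
  expect_equal(unname(v[c("sed", "tde")]), c(0, 0))
  expect_equal(unname(v["stde"]), 1)

  set.seed(25)
  h1 <- random_scanpath(6); h2 <- random_scanpath(7)
  v <- evaluate_image(sim, list(h1, h2))
  for (m in c("sed", "tde", "stde")) {
    one <- evaluate_image(sim, list(h1))[[m]]
    two <- evaluate_image(sim, list(h2))[[m]]
    expect_equal(v[[m]], (one + two) / 2, tolerance = 1e-12)
  }

  # observers failing the embedding precondition are skipped with warning
  short <- random_scanpath(2)
  expect_warning(v2 <- evaluate_image(sim, list(h1, short)), "skipped")
  expect_equal(v2[["tde"]], evaluate_image(sim, list(h1))[["tde"]])
})

test_that("grid search returns lattice points deterministically", {
  scene <- make_texture_scene(seed = 42)
  obs <- benchmark_observers(scene$centers, dim(scene$frame),
                             n_subjects = 3, seed = 42)
  base <- sim_params(lam = 1, alphas = rep(10, 8), duration = 1,
                     dt = 0.02, time_scale = 16)
  single <- grid_search_tune(list(scene$frame), list(obs),
                             data.frame(lam = 2), base_params = base)
  expect_equal(single$best$lam, 2)

  grid <- data.frame(lam = c(0.5, 1))
  t1 <- grid_search_tune(list(scene$frame), list(obs), grid,
                         base_params = base)
  t2 <- grid_search_tune(list(scene$frame), list(obs), grid,
                         base_params = base)
  expect_identical(t1$scores, t2$scores)
  expect_identical(t1$best_row, t2$best_row)
  expect_error(grid_search_tune(list(scene$frame), list(obs),
                                data.frame(lam = numeric(0)),
                                base_params = base), "empty")
})
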