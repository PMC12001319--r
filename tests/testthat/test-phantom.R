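test_that("subject generation is a pure function of its arguments", {
  a <- generate_subject(12, shape = c(16, 16, 16))
  b <- generate_subject(12, shape = c(16, 16, 16))
  expect_identical(a, b)
  c <- generate_subject(13, shape = c(16, 16, 16))
  expect_false(identical(a$volume$grid, c$volume$grid))
})

test_that("zero image noise gives a piecewise-constant image", {
  s <- generate_subject(5, shape = c(16, 16, 16), noise_sd = 0)
  expect_lte(length(unique(as.vector(s$volume$grid))), 6)
})

test_that("generated subjects satisfy the geometric contract across seeds", {
  for (seed in 1:200) {
    s <- generate_subject(seed, shape = c(24, 24, 24))
    expect_true(validate_subject(s))
  }
})

test_that("too-small volumes are rejected", {
  expect_error(generate_subject(1, shape = c(8, 16, 16)), "at least")
})

test_that("general-model simulation honours its identity and determinism", {
  s <- generate_subject(7, shape = c(16, 16, 16))
  tr <- s$structures$target
  expect_identical(simulate_general_model(tr, 1, severity = 0)$grid, tr$grid)
  g1 <- simulate_general_model(tr, 42, severity = 0.4)
  g2 <- simulate_general_model(tr, 42, severity = 0.4)
  expect_identical(g1$grid, g2$grid)
  expect_true(any(g1$grid))
  empty <- new_mask(array(FALSE, dim(tr$grid)), tr$spacing)
  expect_error(simulate_general_model(empty, 1), "empty")
})

test_that("mean general-model agreement decreases with severity", {
  s <- generate_subject(999, shape = c(24, 24, 24), severity = 0)
  tr <- s$structures$target
  mean_dsc <- function(sev) {
    mean(vapply(1:50, function(i) {
      dsc(simulate_general_model(tr, i, sev), tr)
    }, 0))
  }
  d1 <- mean_dsc(0.1); d4 <- mean_dsc(0.4); d8 <- mean_dsc(0.8)
  expect_gt(d1, d4)
  expect_gt(d4, d8)
})

test_that("default severity is calibrated to the high-80s DSC regime", {
  ds <- vapply(1:50, function(i) {
    s <- generate_subject(i, shape = c(24, 24, 24))
    dsc(s$general_mask, s$structures$target)
  }, 0)
  expect_gte(mean(ds), 0.82)
  expect_lte(mean(ds), 0.92)
})
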