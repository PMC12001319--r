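# tiny seeded fixtures shared by the forward-pass tests
tiny_model <- function(base = 4, seed = 1) init_model(arch_spec(base), seed)

tiny_subjects <- function(n, shape = c(16, 16, 16), seed0 = 400) {
  lapply(seq_len(n), function(i) generate_subject(seed0 + i, shape = shape))
}

test_that("encoder channel and resolution arithmetic scale with the base width", {
  s <- tiny_subjects(1)[[1]]
  for (base in c(4, 8, 32)) {
    m <- tiny_model(base)
    pyr <- encode(m, s$volume, s$general_mask)
    expect_length(pyr, 3)
    expect_equal(vapply(pyr, function(f) dim(f)[1], 0), base * c(1, 2, 4))
    expect_equal(dim(pyr[[1]])[2:4], c(16, 16, 16))
    expect_equal(dim(pyr[[2]])[2:4], c(8, 8, 8))
    expect_equal(dim(pyr[[3]])[2:4], c(4, 4, 4))
  }
  m <- tiny_model(4)
  pyr2 <- encode(m, s$volume, s$general_mask)
  pyr3 <- encode(m, s$volume, s$general_mask)
  expect_identical(pyr2, pyr3)
})

test_that("indivisible spatial dimensions are rejected upstream", {
  m <- tiny_model(4)
  v <- new_volume(array(0, c(18, 16, 16)), c(1, 1, 1))
  msk <- new_mask(array(FALSE, c(18, 16, 16)), c(1, 1, 1))
  expect_error(encode(m, v, msk), "divisible")
})

test_that("difference block is zero for identical support pairs at init", {
  m <- tiny_model(4, seed = 9)
  expect_equal(m$params$ddl_b, numeric(arch_spec(4)$base_features * 4))
  s <- tiny_subjects(1)[[1]]
  pyr <- encode(m, s$volume, s$general_mask)
  style <- ddl_block(m, list(pyr, pyr), list(pyr, pyr))
  expect_equal(max(abs(style)), 0)
})

test_that("difference-block output lies strictly inside (-1, 1)", {
  m <- tiny_model(4, seed = 2)
  subs <- tiny_subjects(2)
  pP <- encode(m, subs[[1]]$volume, subs[[1]]$structures$target)
  pM <- encode(m, subs[[1]]$volume, subs[[1]]$general_mask)
  style <- ddl_block(m, list(pP), list(pM))
  expect_true(all(style > -1 & style < 1))
  # n = 1 equals the unaveraged tanh(conv(difference))
  expect_error(ddl_block(m, list(), list()), "non-empty")
  expect_error(ddl_block(m, list(pP, pP), list(pM)), "equal length")
})

test_that("decoder contract: query-shaped probabilities, zero style allowed", {
  m <- tiny_model(4)
  s <- tiny_subjects(1)[[1]]
  pyr <- encode(m, s$volume, s$general_mask)
  zero_style <- pyr[[3]] * 0
  prob <- decode(m, pyr, zero_style)
  expect_equal(dim(prob), dim(s$volume$grid))
  expect_true(all(prob >= 0 & prob <= 1))
  # the 0-prior forward pass is exactly the zero-style decode
  direct <- ddl_forward(m, list(volume = s$volume, mask = s$general_mask))
  expect_equal(prob, direct, tolerance = 1e-12)
  bad_style <- array(0, c(dim(pyr[[3]])[1], 2, 2, 2, 1))
  expect_error(decode(m, pyr, bad_style), "shape")
})

test_that("forward is frozen and permutation-invariant over supports", {
  m <- tiny_model(4, seed = 5)
  subs <- tiny_subjects(4)
  lib <- style_library()
  sup <- lapply(subs[1:3], function(s) {
    list(volume = s$volume, general = s$general_mask,
         truth = apply_style(lib$dilate1, s$structures))
  })
  q <- list(volume = subs[[4]]$volume, mask = subs[[4]]$general_mask)
  before <- m$digest
  p1 <- ddl_forward(m, q, sup)
  p2 <- ddl_forward(m, q, sup[c(3, 1, 2)])
  p3 <- ddl_forward(m, q, sup[c(2, 3, 1)])
  expect_lt(max(abs(p1 - p2)), 1e-6)
  expect_lt(max(abs(p1 - p3)), 1e-6)
  expect_identical(model_digest(m$params), before)
})

test_that("analytic gradients match finite differences on the smooth loss", {
  old <- options(ddlseg.conv_double = TRUE)
  on.exit(options(old))
  arch <- arch_spec(base_features = 4)
  model <- init_model(arch, seed = 13)
  subs <- tiny_subjects(4, seed0 = 430)
  lib <- style_library()
  ep <- build_episode(subs, lib$dilate1, k = 2, seed = 3)
  x <- ddlseg:::episode_tensor(list(volume = ep$query$volume,
                                    mask = ep$query$mask), ep$supports, 2L)
  truth <- ep$query$truth
  lg <- ddlseg:::loss_and_grads(model$params, arch, x, 2L, truth, w_hd = 0)
  f <- function(params) {
    fw <- ddlseg:::net_forward(params, arch, x, 2L)
    ddlseg:::combined_loss_parts(pmin(pmax(fw$prob, 0), 1), truth, 0)$loss
  }
  set.seed(99)
  errs <- c()
  h <- 1e-6
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      pp <- model$params; pp[[nm]][i] <- pp[[nm]][i] + h
      pm <- model$params; pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (f(pp) - f(pm)) / (2 * h)
      ana <- lg$grads[[nm]][i]
      errs <- c(errs, abs(fd - ana) / max(1e-4, abs(fd), abs(ana)))
    }
  }
  expect_lt(median(errs), 1e-5)
  expect_gte(mean(errs < 1e-3), 0.95)
})
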