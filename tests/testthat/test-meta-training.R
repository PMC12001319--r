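small_cfg <- function(...) {
  train_config(iterations = 5, base_features = 4, shape = c(16, 16, 16),
               n_subjects = 6, max_priors = 4, seed = 7, ...)
}

test_that("episode construction respects the support/query protocol", {
  subs <- lapply(1:6, function(i) generate_subject(700 + i,
                                                   shape = c(16, 16, 16)))
  lib <- style_library()
  for (draw in 1:20) {
    ep <- build_episode(subs, lib$erode1, k = 3, seed = draw)
    sup_ids <- vapply(ep$supports, function(s) s$subject_id, "")
    expect_false(ep$query$subject_id %in% sup_ids)
    expect_length(unique(sup_ids), 3)
  }
  e1 <- build_episode(subs, lib$erode1, k = 2, seed = 5)
  e2 <- build_episode(subs, lib$erode1, k = 2, seed = 5)
  expect_identical(e1, e2)
  expect_error(build_episode(subs[1:3], lib$erode1, k = 3, seed = 1),
               "at least")
  expect_error(build_episode(subs, lib$erode1, k = 0, seed = 1), ">= 1")
})

test_that("training draws cover every support count and only training styles", {
  cfg <- train_config(seed = 12)
  draws <- ddlseg:::training_draws(cfg, 500)
  expect_setequal(sort(unique(draws$k)), 1:10)
  expect_true(all(draws$style %in% cfg$train_styles))
  expect_identical(draws, ddlseg:::training_draws(cfg, 500))
})

test_that("a train step updates all components and reports finite losses", {
  cfg <- small_cfg()
  subs <- make_subjects(cfg)
  lib <- style_library()
  m <- init_model(arch_spec(cfg$base_features), seed = 3)
  ep <- build_episode(subs, lib$dilate1, k = 2, seed = 4)
  st <- train_step(m, ep, epoch = 0, running_dsc = 0, cfg)
  expect_false(identical(st$state$digest, m$digest))
  expect_true(is.finite(st$loss))
  expect_gte(st$batch_dsc, 0)
  # a second step reuses the optimizer state
  st2 <- train_step(st$state, ep, 0, st$batch_dsc, cfg, st$opt)
  expect_false(identical(st2$state$digest, st$state$digest))
})

test_that("repeated steps on one episode reduce the loss (optimization smoke)", {
  cfg <- train_config(iterations = 1, base_features = 4,
                      shape = c(16, 16, 16), n_subjects = 4, seed = 21)
  subs <- make_subjects(cfg)
  lib <- style_library()
  cache <- ddlseg:::make_style_cache()
  ep <- build_episode(subs, lib$erode1, k = 2, seed = 2, cache = cache)
  m <- init_model(arch_spec(4), seed = 8)
  opt <- NULL
  losses <- numeric(200)
  running <- 0
  for (it in 1:200) {
    st <- train_step(m, ep, epoch = (it - 1) %/% 50, running_dsc = running,
                     config = cfg, opt = opt)
    m <- st$state; opt <- st$opt
    running <- 0.9 * running + 0.1 * st$batch_dsc
    losses[it] <- st$loss
  }
  expect_lt(mean(tail(losses, 20)), mean(head(losses, 20)))
  expect_gt(running, 0.5)  # the episode is essentially memorized
})

test_that("meta-training is reproducible and never draws held-out styles", {
  cfg <- small_cfg()
  r1 <- meta_train(cfg)
  r2 <- meta_train(cfg)
  expect_identical(r1$state$digest, r2$state$digest)
  expect_equal(nrow(r1$trace), cfg$iterations)
  expect_true(all(r1$trace$style %in% cfg$train_styles))
  expect_false(any(r1$trace$style %in% cfg$eval_styles))
})

test_that("train and eval style lists must be disjoint", {
  expect_error(train_config(train_styles = c("dilate2", "superior_half"),
                            eval_styles = c("superior_half")), "disjoint")
  expect_error(train_config(train_styles = c("no_such_style")), "unknown")
})
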