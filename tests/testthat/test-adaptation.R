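# Contract tests on an untrained tiny model: adaptation behaviour that must
# hold for any parameter values.

adapt_fixture <- function() {
  list(model = init_model(arch_spec(4), seed = 6),
       subjects = lapply(1:8, function(i) generate_subject(800 + i,
                                                           shape = c(16, 16, 16))),
       lib = style_library(),
       cache = ddlseg:::make_style_cache())
}

test_that("adapt_segment is frozen and defaults to the no-adaptation pass", {
  fx <- adapt_fixture()
  s <- fx$subjects[[1]]
  q <- list(volume = s$volume, mask = s$general_mask)
  before <- fx$model$digest
  pred0 <- adapt_segment(fx$model, prior_bank("any"), q)
  expect_identical(fx$model$digest, before)
  prob <- ddl_forward(fx$model, q, list())
  expect_identical(pred0$grid, prob >= 0.5)
  # bank ordering does not change the prediction
  entries <- lapply(fx$subjects[2:4], function(p) {
    list(volume = p$volume, general = p$general_mask,
         truth = ddlseg:::styled_truth(fx$lib$dilate1, p, fx$cache))
  })
  p1 <- adapt_segment(fx$model, prior_bank("dilate1", entries), q)
  p2 <- adapt_segment(fx$model, prior_bank("dilate1", entries[c(2, 3, 1)]), q)
  expect_identical(p1$grid, p2$grid)
})

test_that("the simulated workflow banks patients in order and scores the rest", {
  fx <- adapt_fixture()
  rec <- simulate_workflow(fx$model, fx$lib$erode1, fx$subjects[1:6],
                           order_seed = 2, max_priors = 3, cache = fx$cache)
  expect_equal(nrow(rec), 5)  # everyone but the first patient is scored
  expect_equal(rec$n_priors, c(1, 2, 3, 3, 3))  # bank saturates at max_priors
  expect_true(all(rec$dsc >= 0 & rec$dsc <= 1))
  expect_error(simulate_workflow(fx$model, fx$lib$erode1, fx$subjects[1],
                                 order_seed = 1), "two subjects")
})

test_that("sweep_priors reports one deterministic row per requested count", {
  fx <- adapt_fixture()
  test_subs <- fx$subjects[1:3]
  prior_subs <- fx$subjects[4:8]
  cv <- sweep_priors(fx$model, fx$lib$dilate1, test_subs, prior_subs,
                     n_values = c(0, 1, 3), cache = fx$cache)
  expect_equal(cv$summary$n_priors, c(0, 1, 3))
  expect_equal(nrow(cv$records), 3 * 3)
  cv2 <- sweep_priors(fx$model, fx$lib$dilate1, test_subs, prior_subs,
                      n_values = c(0, 1, 3), cache = fx$cache)
  expect_identical(cv$records, cv2$records)
  expect_error(sweep_priors(fx$model, fx$lib$dilate1, test_subs, prior_subs,
                            n_values = c(0, 9)), "available")
  expect_error(sweep_priors(fx$model, fx$lib$dilate1, test_subs,
                            fx$subjects[3:5], n_values = 1), "disjoint")
})

test_that("transfer learning changes its copy while the DDL stays frozen", {
  fx <- adapt_fixture()
  before <- fx$model$digest
  res <- transfer_baseline(fx$model, fx$lib$erode1, fx$subjects[1:1],
                           fx$subjects[2:3], tune_iterations = 3,
                           cache = fx$cache)
  expect_false(identical(res$digest, before))
  expect_identical(fx$model$digest, before)
  expect_equal(res$curve$summary$n_priors, 1)
  expect_equal(nrow(res$curve$records), 2)
})
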