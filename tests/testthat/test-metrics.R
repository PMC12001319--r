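sp1 <- c(1, 1, 1)

mk <- function(g, sp = sp1) new_mask(g, sp)

test_that("dsc closed forms and symmetry", {
  g <- array(FALSE, c(4, 4, 4)); g[1:2, 1, 1] <- TRUE
  m <- mk(g)
  expect_equal(dsc(m, m), 1)
  h <- mk(array(FALSE, c(4, 4, 4))); h$grid[4, 4, 4] <- TRUE
  expect_equal(dsc(m, h), 0)
  a <- mk(array(FALSE, c(4, 4, 4))); a$grid[1, 1, 1:3] <- TRUE
  a$grid[2, 1, 1:3] <- TRUE  # |A| = 6
  b <- mk(array(FALSE, c(4, 4, 4))); b$grid[1, 1, 1:2] <- TRUE  # |B| = 2
  expect_equal(dsc(a, b), 0.5)  # 2*2 / 8
  expect_equal(dsc(b, a), dsc(a, b))
  e <- mk(array(FALSE, c(4, 4, 4)))
  expect_equal(dsc(e, e), 1)  # both empty agree perfectly
  expect_error(dsc(m, mk(array(FALSE, c(5, 4, 4)))), "shape")
})

test_that("hausdorff closed forms, spacing scaling, and symmetry", {
  g <- array(FALSE, c(8, 4, 4)); g[2, 2, 2] <- TRUE
  h <- array(FALSE, c(8, 4, 4)); h[6, 2, 2] <- TRUE
  expect_equal(hausdorff(mk(g), mk(g)), 0)
  expect_equal(hausdorff(mk(g), mk(h)), 4)
  expect_equal(hausdorff(mk(g, c(2, 1, 1)), mk(h, c(2, 1, 1))), 8)
  expect_equal(hausdorff(mk(g), mk(h)), hausdorff(mk(h), mk(g)))
  expect_error(hausdorff(mk(g), mk(array(FALSE, c(8, 4, 4)))), "empty")
})

test_that("hausdorff equals all-pairs boundary distances on random masks", {
  set.seed(11)
  for (i in 1:20) {
    d <- c(sample(5:12, 1), sample(5:12, 1), sample(5:12, 1))
    sp <- c(2, 1.17, 1.17)
    a <- random_mask_grid(d); b <- random_mask_grid(d)
    if (!any(a)) a[2, 2, 2] <- TRUE
    if (!any(b)) b[3, 3, 3] <- TRUE
    expect_equal(hausdorff(mk(a, sp), mk(b, sp)), oracle_hausdorff(a, b, sp),
                 tolerance = 1e-12)
  }
})

test_that("soft Dice loss matches its closed form and finite differences", {
  set.seed(3)
  d <- c(4, 4, 4)
  tg <- mk(array(runif(64) < 0.4, d))
  p <- array(runif(64, 0.05, 0.95), d)
  lp <- ddlseg:::soft_dsc_parts(p, tg)
  t <- as.numeric(tg$grid)
  expect_equal(lp$loss, 1 - (2 * sum(p * t) + 1) / (sum(p) + sum(t) + 1))
  h <- 1e-6
  for (i in sample(64, 10)) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    fd <- (soft_dsc_loss(pp, tg) - soft_dsc_loss(pm, tg)) / (2 * h)
    expect_equal(lp$grad[i], fd, tolerance = 1e-4)
  }
  # exact prediction: loss bounded by the epsilon smoothing only
  exact <- array(t, d)
  expect_lt(soft_dsc_loss(exact, tg), 1 / (2 * sum(t)))
  # all-zero prediction approaches 1 as the target grows
  big <- mk(array(TRUE, c(8, 8, 8)))
  expect_gt(soft_dsc_loss(array(0, c(8, 8, 8)), big), 0.99)
  expect_error(soft_dsc_loss(array(1.5, d), tg), "probabilities")
})

test_that("hausdorff surrogate loss is zero at equality and distance-weighted", {
  d <- c(8, 8, 8)
  tg <- array(FALSE, d); tg[3:6, 3:6, 3:6] <- TRUE
  target <- mk(tg)
  expect_equal(hd_loss(array(as.numeric(tg), d), target), 0)
  set.seed(2)
  p <- array(runif(prod(d)), d)
  expect_gte(hd_loss(p, target), 0)
  # one misclassified voxel farther (in mm) from the boundary costs more
  near <- array(as.numeric(tg), d); near[3, 3, 8] <- 1
  far <- array(as.numeric(tg), d); far[1, 1, 8] <- 1
  expect_gt(hd_loss(far, target), hd_loss(near, target))
})

test_that("the HD weight schedule gates on running DSC and ramps by epoch", {
  sc <- loss_schedule(hd_weight_floor = 0.1, hd_weight_ceiling = 0.6,
                      dsc_gate = 0.7, ramp_epochs = 10)
  expect_equal(hd_weight(sc, 0, 0), 0.1)
  expect_equal(hd_weight(sc, 50, 0.69), 0.1)
  expect_equal(hd_weight(sc, 10, 0.8), 0.6)
  expect_equal(hd_weight(sc, 25, 0.9), 0.6)
  w <- vapply(0:12, function(e) hd_weight(sc, e, 0.75), 0)
  expect_true(all(diff(w) >= 0))
  # combined loss equals its parts under the same weight
  d <- c(4, 4, 4)
  tg <- mk(array(c(TRUE, FALSE), d))
  p <- array(0.4, d)
  expect_equal(combined_loss(p, tg, epoch = 20, running_dsc = 0.9, sc),
               soft_dsc_loss(p, tg) + 0.6 * hd_loss(p, tg))
  expect_error(loss_schedule(hd_weight_floor = 1, hd_weight_ceiling = 0.5))
})
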