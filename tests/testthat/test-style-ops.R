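sp1 <- c(1, 1, 1)

test_that("dilation matches the lattice-offset count on a single voxel", {
  g <- array(FALSE, c(9, 9, 9))
  g[5, 5, 5] <- TRUE
  m <- new_mask(g, sp1)
  expect_equal(sum(dilate(m, 2)$grid), 33)  # offsets with |o|^2 <= 4
  expect_identical(dilate(m, 0)$grid, g)
  full <- new_mask(array(TRUE, c(5, 5, 5)), sp1)
  expect_identical(dilate(full, 2)$grid, full$grid)
  expect_error(dilate(m, -1), ">= 0")
})

test_that("erosion matches the structuring-element contract", {
  g <- array(FALSE, c(9, 9, 9))
  g[3:7, 3:7, 3:7] <- TRUE
  m <- new_mask(g, sp1)
  expect_equal(sum(erode(m, 1)$grid), 27)  # 3^3 interior of a 5^3 cube
  single <- new_mask(array(FALSE, c(5, 5, 5)), sp1)
  single$grid[3, 3, 3] <- TRUE
  expect_equal(sum(erode(single, 1)$grid), 0)
  expect_error(erode(m, -2), ">= 0")
})

test_that("closing (dilate then erode) contains the original mask", {
  set.seed(31)
  for (i in 1:10) {
    g <- random_mask_grid(c(10, 10, 10))
    m <- new_mask(g, sp1)
    closed <- erode(dilate(m, 1), 1)
    expect_true(all(closed$grid[g]))
  }
})

test_that("slice selection keeps exactly the reference's slices", {
  d <- c(10, 4, 4)
  mg <- array(FALSE, d)
  mg[, 2, 2:3] <- TRUE
  mg[, 3, 2:3] <- TRUE  # 4 voxels on each of the 10 slices
  rg <- array(FALSE, d)
  rg[3:5, 1, 1] <- TRUE
  m <- new_mask(mg, sp1); r <- new_mask(rg, sp1)
  kept <- keep_slices_with(m, r)
  expect_equal(sum(kept$grid), 12)
  expect_true(all(which(apply(kept$grid, 1, any)) %in% 3:5))
  empty <- new_mask(array(FALSE, d), sp1)
  expect_equal(sum(keep_slices_with(m, empty)$grid), 0)
  allz <- new_mask(array(TRUE, d), sp1)
  expect_identical(keep_slices_with(m, allz)$grid, m$grid)
})

test_that("with/without slice selections partition the mask", {
  set.seed(5)
  for (i in 1:10) {
    d <- c(12, 6, 6)
    m <- new_mask(random_mask_grid(d), sp1)
    r <- new_mask(random_mask_grid(d), sp1)
    a <- keep_slices_with(m, r)
    b <- keep_slices_without(m, list(r))
    expect_identical(a$grid | b$grid, m$grid)
    expect_false(any(a$grid & b$grid))
  }
  m <- new_mask(array(TRUE, c(10, 3, 3)), sp1)
  r1 <- new_mask(array(FALSE, c(10, 3, 3)), sp1); r1$grid[1:5, 1, 1] <- TRUE
  r2 <- new_mask(array(FALSE, c(10, 3, 3)), sp1); r2$grid[4:8, 1, 1] <- TRUE
  out <- keep_slices_without(m, list(r1, r2))
  expect_identical(which(apply(out$grid, 1, any)), 9:10)
  expect_error(keep_slices_without(m, list()), "non-empty")
})

test_that("extension into a neighbour respects the mm depth", {
  d <- c(10, 4, 4)
  tg <- array(FALSE, d); tg[1:3, , ] <- TRUE
  ng <- array(FALSE, d); ng[4:10, , ] <- TRUE
  t <- new_mask(tg, sp1); n <- new_mask(ng, sp1)
  out <- extend_into(t, n, 2)
  expect_identical(which(apply(out$grid, 1, any)), 1:5)  # adds slices 4-5
  expect_identical(extend_into(t, n, 0)$grid, tg)
  far <- new_mask(array(FALSE, d), sp1); far$grid[10, , ] <- TRUE
  expect_identical(extend_into(t, far, 2)$grid, tg)
  t2 <- new_mask(tg, c(2, 1, 1))
  expect_error(extend_into(t2, n, 2), "spacing")
})

test_that("capped extension keeps only shallow voxels of the neighbour", {
  d <- c(9, 5, 5)
  ng <- array(FALSE, d); ng[, , ] <- TRUE  # neighbour covers everything
  tg <- array(FALSE, d); tg[3:7, 2:4, 2:4] <- TRUE
  t <- new_mask(tg, sp1); n <- new_mask(ng, sp1)
  out <- cap_extension_into(t, n, 2)
  want <- oracle_cap_extension(tg, ng, 2, sp1)
  expect_identical(out$grid, want)
  # depth 0 is plain set difference
  n2 <- new_mask(array(FALSE, d), sp1); n2$grid[5:9, , ] <- TRUE
  expect_identical(cap_extension_into(t, n2, 0)$grid, tg & !n2$grid)
  disj <- new_mask(array(FALSE, d), sp1); disj$grid[1, 1, 1] <- TRUE
  expect_identical(cap_extension_into(t, disj, 1)$grid, tg)
})

test_that("structure exclusion equals voxelwise AND-NOT", {
  set.seed(9)
  for (i in 1:10) {
    d <- c(8, 8, 8)
    a <- new_mask(random_mask_grid(d), sp1)
    b <- new_mask(random_mask_grid(d), sp1)
    expect_identical(exclude_structure(a, b)$grid, a$grid & !b$grid)
  }
  e <- new_mask(array(FALSE, c(8, 8, 8)), sp1)
  m <- new_mask(random_mask_grid(c(8, 8, 8)), sp1)
  expect_identical(exclude_structure(m, e)$grid, m$grid)
  expect_equal(sum(exclude_structure(m, m)$grid), 0)
})

test_that("aspect splits follow bounding-box arithmetic", {
  d <- c(14, 8, 8)
  g <- array(FALSE, d); g[3:12, 3:6, 3:6] <- TRUE  # 10-slice cuboid
  m <- new_mask(g, sp1)
  sup <- aspect_split(m, "superior", 0.5)
  expect_identical(which(apply(sup$grid, 1, any)), 3:7)
  expect_identical(aspect_split(m, "superior", 1)$grid, g)
  post <- aspect_split(m, "posterior", 0.5)
  expect_identical(which(apply(post$grid, 2, any)), 5:6)
  expect_identical(sup$grid | (m$grid & !sup$grid), m$grid)
  empty <- new_mask(array(FALSE, d), sp1)
  expect_error(aspect_split(empty, "superior", 0.5), "non-empty")
})

test_that("style application folds steps in order and is deterministic", {
  s <- generate_subject(21, shape = c(16, 16, 16))
  st <- s$structures
  empty_style <- style_transform("noop", list())
  expect_identical(apply_style(empty_style, st)$grid, st$target$grid)

  closing <- style_transform("closing", list(
    style_step("dilate", radius_px = 2), style_step("erode", radius_px = 2)))
  expect_true(all(apply_style(closing, st)$grid[st$target$grid]))

  comp <- style_transform("comp", list(
    style_step("cap_extension_into", depth_mm = 10, ref = "neighbor_sup"),
    style_step("keep_slices_with", ref = "ref_a")))
  manual <- keep_slices_with(
    cap_extension_into(st$target, st$neighbor_sup, 10), st$ref_a)
  expect_identical(apply_style(comp, st)$grid, manual$grid)

  bad <- style_transform("bad", list(style_step("dilate", radius_px = 1,
                                                ref = NULL)))
  bad$steps[[1]]$op <- "frobnicate"
  expect_error(apply_style(bad, st), "unknown style operator")
  missing_ref <- style_transform("m", list(
    style_step("exclude_structure", ref = "no_such")))
  expect_error(apply_style(missing_ref, st), "unknown structure")
})

test_that("the shipped style library loads and separates held-out styles", {
  lib <- style_library()
  expect_gte(length(lib), 20)
  held <- names(Filter(function(s) s$held_out, lib))
  expect_setequal(held, c("cap_sup_3mm", "into_post_9mm", "exclude_ref_b",
                          "superior_half"))
  s <- generate_subject(3, shape = c(16, 16, 16))
  for (nm in c("dilate2", "erode1", "with_ref_a", "superior_half")) {
    styled <- apply_style(lib[[nm]], s$structures)
    expect_identical(dim(styled$grid), dim(s$structures$target$grid))
  }
})

test_that("morphology and slice operators are monotone and grid-preserving", {
  set.seed(77)
  m <- new_mask(random_mask_grid(c(12, 12, 12)), c(2, 1.17, 1.17))
  d1 <- dilate(m, 1); d2 <- dilate(m, 2)
  expect_true(all(d1$grid[m$grid]))
  expect_true(all(d2$grid[d1$grid]))
  e1 <- erode(m, 1); e2 <- erode(m, 2)
  expect_true(all(m$grid[e1$grid]))
  expect_true(all(e1$grid[e2$grid]))
  for (out in list(d2, e2)) {
    expect_identical(dim(out$grid), dim(m$grid))
    expect_identical(out$spacing, m$spacing)
  }
})
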