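# Brute-force voxel-enumeration oracles, written independently of the
# package's shift/distance-transform implementations: everything below works
# from arr.ind coordinate lists and explicit pairwise distances.

oracle_ball <- function(r) {
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  as.matrix(g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE])
}

# value lookup with out-of-bounds -> `fill`
lookup3 <- function(g, coords, fill) {
  d <- dim(g)
  ok <- coords[, 1] >= 1 & coords[, 1] <= d[1] &
    coords[, 2] >= 1 & coords[, 2] <= d[2] &
    coords[, 3] >= 1 & coords[, 3] <= d[3]
  out <- rep(fill, nrow(coords))
  cc <- coords[ok, , drop = FALSE]
  out[ok] <- g[cbind(cc[, 1], cc[, 2], cc[, 3])]
  out
}

all_coords <- function(d) {
  as.matrix(expand.grid(z = seq_len(d[1]), y = seq_len(d[2]),
                        x = seq_len(d[3])))
}

oracle_dilate <- function(g, r) {
  d <- dim(g)
  off <- oracle_ball(r)
  co <- all_coords(d)
  acc <- rep(FALSE, nrow(co))
  for (i in seq_len(nrow(off))) {
    acc <- acc | lookup3(g, sweep(co, 2, -off[i, ]), FALSE)
  }
  array(acc, d)
}

# erosion clips the structuring element at the border (outside = foreground)
oracle_erode <- function(g, r) {
  d <- dim(g)
  off <- oracle_ball(r)
  co <- all_coords(d)
  acc <- rep(TRUE, nrow(co))
  for (i in seq_len(nrow(off))) {
    acc <- acc & lookup3(g, sweep(co, 2, -off[i, ]), TRUE)
  }
  array(acc, d)
}

oracle_slices_with <- function(g, ref) {
  keep <- vapply(seq_len(dim(ref)[1]), function(z) any(ref[z, , ]), TRUE)
  out <- g
  out[!keep, , ] <- FALSE
  out
}

# pairwise mm distances between two arr.ind coordinate sets
pair_dists <- function(a, b, sp) {
  da <- outer(a[, 1] * sp[1], b[, 1] * sp[1], "-")^2 +
    outer(a[, 2] * sp[2], b[, 2] * sp[2], "-")^2 +
    outer(a[, 3] * sp[3], b[, 3] * sp[3], "-")^2
  sqrt(da)
}

oracle_extend_into <- function(target, neighbor, depth, sp) {
  out <- target
  tp <- which(target, arr.ind = TRUE)
  np <- which(neighbor, arr.ind = TRUE)
  if (nrow(tp) == 0 || nrow(np) == 0) return(out)
  dmin <- apply(pair_dists(np, tp, sp), 1, min)
  add <- np[dmin <= depth, , drop = FALSE]
  out[add] <- TRUE
  out
}

oracle_cap_extension <- function(target, neighbor, depth, sp) {
  out <- target
  np <- which(neighbor, arr.ind = TRUE)
  ep <- which(!neighbor, arr.ind = TRUE)
  if (nrow(np) == 0) return(out)
  deep <- if (nrow(ep) == 0) rep(TRUE, nrow(np)) else
    apply(pair_dists(np, ep, sp), 1, min) > depth
  out[np[deep, , drop = FALSE]] <- FALSE
  out & target
}

oracle_boundary <- function(g) {
  d <- dim(g)
  co <- all_coords(d)
  inb <- g[co]
  nb <- rep(FALSE, nrow(co))
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    nb <- nb | !lookup3(g, sweep(co, 2, -o), FALSE)
  }
  array(inb & nb, d)
}

oracle_hausdorff <- function(a, b, sp) {
  pa <- which(oracle_boundary(a), arr.ind = TRUE)
  pb <- which(oracle_boundary(b), arr.ind = TRUE)
  D <- pair_dists(pa, pb, sp)
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

# random test masks: a fuzzy ellipsoid, random sprinkle, or both
random_mask_grid <- function(d, p_sprinkle = 0.05) {
  g <- array(runif(prod(d)) < p_sprinkle, d)
  if (runif(1) < 0.8) {
    cz <- runif(3, 0.3, 0.7) * d
    rr <- runif(3, 0.15, 0.4) * d
    co <- all_coords(d)
    blob <- ((co[, 1] - cz[1]) / rr[1])^2 + ((co[, 2] - cz[2]) / rr[2])^2 +
      ((co[, 3] - cz[3]) / rr[3])^2 <= 1
    g <- g | array(blob, d)
  }
  g
}

expect_same_mask <- function(got, want_grid) {
  expect_equal(got$grid, array(want_grid, dim(want_grid)))
}
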