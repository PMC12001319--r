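#' Dice similarity coefficient of two masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks are defined to agree
#' perfectly (DSC 1): styles can legitimately empty a mask on some subjects,
#' and a prediction that is also empty is then correct.
#'
#' @param a,b `ddl_mask` objects on the same grid.
#' @return Scalar in `[0, 1]`.
#' @examples
#' m <- new_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
#' dsc(m, m)
#' @export
dsc <- function(a, b) {
  stopifnot(is_mask(a), is_mask(b))
  check_same_grid(a, b)
  na <- sum(a$grid); nb <- sum(b$grid)
  if (na + nb == 0) return(1)
  2 * sum(a$grid & b$grid) / (na + nb)
}

#' Hausdorff distance between mask boundaries, in mm
#'
#' The symmetric maximum over directed distances between the boundary voxel
#' centres of the two masks, measured in mm using the grid spacing. Boundary
#' voxels are foreground voxels with at least one 6-neighbour outside the
#' mask (the grid edge counts as outside). Undefined, and an error, for an
#' empty mask.
#'
#' @param a,b non-empty `ddl_mask` objects on the same grid and spacing.
#' @return Scalar distance in mm (0 iff the boundaries coincide).
#' @export
hausdorff <- function(a, b) {
  stopifnot(is_mask(a), is_mask(b))
  check_same_grid(a, b, spacing = TRUE)
  if (!any(a$grid) || !any(b$grid))
    stop("hausdorff distance is undefined for an empty mask")
  ba <- new_mask(mask_boundary(a), a$spacing)
  bb <- new_mask(mask_boundary(b), b$spacing)
  da <- edt_mm(bb)  # distance of every voxel to b's boundary
  db <- edt_mm(ba)
  max(max(da[ba$grid]), max(db[bb$grid]))
}

#' Differentiable training losses
#'
#' `soft_dsc_loss` is the soft Dice loss
#' `1 - (2 * sum(p*t) + eps) / (sum(p) + sum(t) + eps)` with `eps = 1`.
#' `hd_loss` is a differentiable Hausdorff surrogate: the squared
#' prediction error at each voxel is weighted by the sum of squared
#' distances (mm^2) to the boundary of the target and to the boundary of
#' the thresholded prediction, so residual errors far from the boundaries
#' dominate. It is exactly 0 when the prediction equals the binary target.
#' The distance weight of the thresholded prediction is treated as constant
#' under differentiation.
#'
#' @param pred numeric array of probabilities in `[0, 1]`, same shape as the
#'   target grid.
#' @param target `ddl_mask` ground truth.
#' @param eps soft Dice smoothing constant.
#' @return Scalar loss. The gradient helpers used in training are internal.
#' @examples
#' t <- new_mask(array(c(TRUE, FALSE), c(4, 4, 4)), c(1, 1, 1))
#' soft_dsc_loss(array(0.5, c(4, 4, 4)), t)
#' @export
soft_dsc_loss <- function(pred, target, eps = 1) {
  soft_dsc_parts(pred, target, eps)$loss
}

soft_dsc_parts <- function(pred, target, eps = 1) {
  stopifnot(is_mask(target))
  if (!identical(dim(pred), dim(target$grid)))
    stop("prediction and target shapes differ")
  if (any(pred < 0) || any(pred > 1))
    stop("predictions must be probabilities in [0, 1]")
  t <- as.numeric(target$grid)
  num <- 2 * sum(pred * t) + eps
  den <- sum(pred) + sum(t) + eps
  list(loss = 1 - num / den,
       grad = array(-(2 * t * den - num) / den^2, dim(pred)))
}

#' @rdname soft_dsc_loss
#' @export
hd_loss <- function(pred, target) {
  hd_loss_parts(pred, target)$loss
}

hd_loss_parts <- function(pred, target) {
  stopifnot(is_mask(target))
  if (!identical(dim(pred), dim(target$grid)))
    stop("prediction and target shapes differ")
  if (any(pred < 0) || any(pred > 1))
    stop("predictions must be probabilities in [0, 1]")
  w <- boundary_dist_sq(target$grid, target$spacing) +
    boundary_dist_sq(pred >= 0.5, target$spacing)
  t <- as.numeric(target$grid)
  r <- pred - t
  n <- length(pred)
  list(loss = sum(r * r * w) / n, grad = array(2 * r * w / n, dim(pred)))
}

# Squared distance (mm^2) of every voxel to the boundary of a set; zero
# weight everywhere when the set has no boundary (empty or degenerate).
boundary_dist_sq <- function(grid, spacing) {
  m <- new_mask(array(grid, dim(grid)), spacing)
  b <- mask_boundary(m)
  if (!any(b)) return(array(0, dim(grid)))
  d <- edt_mm(new_mask(b, spacing))
  d * d
}

#' Epoch-varying weighting of the Dice and Hausdorff losses
#'
#' The combined training loss is `soft_dsc_loss + w * hd_loss`. Early in
#' training the Dice term dominates (`w` at its floor); once the running
#' training DSC passes the gate (default 0.70), `w` ramps linearly with
#' epoch to a ceiling chosen so the two terms have comparable magnitude.
#' The running DSC used for the gate is an exponential moving average of
#' per-batch DSC (decay 0.9), which is stable at batch size one.
#'
#' @param hd_weight_floor,hd_weight_ceiling weight range for the HD term.
#' @param dsc_gate running-DSC threshold that opens the ramp.
#' @param ramp_epochs epochs over which the weight ramps to its ceiling.
#' @return `loss_schedule()` returns a `ddl_schedule`; `hd_weight()` the
#'   weight at a given epoch and running DSC; `combined_loss()` the scalar
#'   combined loss.
#' @examples
#' sc <- loss_schedule()
#' hd_weight(sc, epoch = 0, running_dsc = 0)
#' hd_weight(sc, epoch = 20, running_dsc = 0.9)
#' @export
loss_schedule <- function(hd_weight_floor = 0.05, hd_weight_ceiling = 0.5,
                          dsc_gate = 0.70, ramp_epochs = 10) {
  if (hd_weight_floor < 0 || hd_weight_floor > hd_weight_ceiling)
    stop("need 0 <= hd_weight_floor <= hd_weight_ceiling")
  if (dsc_gate <= 0 || dsc_gate >= 1) stop("dsc_gate must be in (0, 1)")
  if (ramp_epochs < 1) stop("ramp_epochs must be >= 1")
  structure(list(hd_weight_floor = hd_weight_floor,
                 hd_weight_ceiling = hd_weight_ceiling,
                 dsc_gate = dsc_gate, ramp_epochs = ramp_epochs),
            class = "ddl_schedule")
}

#' @rdname loss_schedule
#' @param schedule a `ddl_schedule`.
#' @param epoch non-negative integer epoch index.
#' @param running_dsc running training DSC in `[0, 1]`.
#' @export
hd_weight <- function(schedule, epoch, running_dsc) {
  stopifnot(inherits(schedule, "ddl_schedule"))
  if (running_dsc < 0 || running_dsc > 1)
    stop("running_dsc must be in [0, 1]")
  if (running_dsc < schedule$dsc_gate) return(schedule$hd_weight_floor)
  frac <- min(1, max(0, epoch / schedule$ramp_epochs))
  schedule$hd_weight_floor +
    (schedule$hd_weight_ceiling - schedule$hd_weight_floor) * frac
}

#' @rdname loss_schedule
#' @param pred probability array; `target` a `ddl_mask`.
#' @param target ground-truth `ddl_mask`.
#' @export
combined_loss <- function(pred, target, epoch, running_dsc,
                          schedule = loss_schedule()) {
  w <- hd_weight(schedule, epoch, running_dsc)
  soft_dsc_loss(pred, target) + w * hd_loss(pred, target)
}

combined_loss_parts <- function(pred, target, w_hd) {
  a <- soft_dsc_parts(pred, target)
  b <- hd_loss_parts(pred, target)
  list(loss = a$loss + w_hd * b$loss, grad = a$grad + w_hd * b$grad,
       dsc_loss = a$loss, hd_loss = b$loss)
}
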