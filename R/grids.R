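#' Image volumes and binary masks on a common voxel grid
#'
#' A volume is a 3D scalar grid with per-axis voxel spacing in mm; a mask is
#' an aligned 3D logical grid with the same spacing. Axis 1 indexes axial
#' slices (increasing index = more inferior), axis 2 runs anterior to
#' posterior, and axis 3 left to right. All higher-level operations in the
#' package (style operators, metrics, the network) assume this convention.
#'
#' @param grid 3D numeric array (volume) or array coercible to logical (mask).
#' @param spacing numeric length-3, voxel spacing in mm as `(sz, sy, sx)`.
#' @return An object of class `ddl_volume` or `ddl_mask`: a list with
#'   elements `grid` and `spacing`.
#' @examples
#' m <- new_mask(array(FALSE, c(8, 8, 8)), spacing = c(2, 1.17, 1.17))
#' dim(m$grid)
#' @export
new_volume <- function(grid, spacing) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  if (!all(is.finite(grid))) stop("volume grid must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive numbers (sz, sy, sx) in mm")
  structure(list(grid = grid, spacing = spacing), class = "ddl_volume")
}

#' @rdname new_volume
#' @export
new_mask <- function(grid, spacing) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("spacing must be three positive numbers (sz, sy, sx) in mm")
  g <- grid
  if (!is.logical(g)) {
    storage.mode(g) <- "logical"
  }
  if (anyNA(g)) stop("mask grid must not contain NA")
  structure(list(grid = g, spacing = spacing), class = "ddl_mask")
}

is_mask <- function(x) inherits(x, "ddl_mask")

#' @export
print.ddl_volume <- function(x, ...) {
  cat("<ddl_volume> ", paste(dim(x$grid), collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.ddl_mask <- function(x, ...) {
  cat("<ddl_mask> ", paste(dim(x$grid), collapse = "x"),
      " voxels, ", sum(x$grid), " foreground, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

check_same_grid <- function(a, b, spacing = FALSE) {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("grids have mismatched shapes: ",
         paste(dim(a$grid), collapse = "x"), " vs ",
         paste(dim(b$grid), collapse = "x"))
  if (spacing && !isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6)))
    stop("grids have mismatched spacing")
  invisible(TRUE)
}

# Euclidean distance (mm) from every voxel to the nearest TRUE voxel.
# Returns +Inf everywhere for an empty mask.
edt_mm <- function(mask) {
  g <- mask$grid
  if (!any(g)) {
    out <- array(Inf, dim(g))
    return(out)
  }
  sq <- .edt3_sq_cpp(g, mask$spacing)
  array(sqrt(sq), dim(g))
}

# Boundary voxels of a mask: foreground voxels with at least one 6-neighbour
# that is background or outside the grid.
mask_boundary <- function(mask) {
  g <- mask$grid
  if (!any(g)) return(g)
  interior <- array(TRUE, dim(g))
  d <- dim(g)
  shift_and <- function(acc, dz, dy, dx) {
    acc & shift3(g, dz, dy, dx, fill = FALSE)
  }
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
    interior <- shift_and(interior, o[1], o[2], o[3])
  }
  g & !interior
}

# Shift a 3D array by (dz, dy, dx), filling vacated voxels with `fill`.
shift3 <- function(a, dz, dy, dx, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, k) {
    # destination range and matching source range for a shift of k
    if (k >= 0) list(dst = seq_len(n - k) + k, src = seq_len(n - k))
    else list(dst = seq_len(n + k), src = seq_len(n + k) - k)
  }
  rz <- src(d[1], dz); ry <- src(d[2], dy); rx <- src(d[3], dx)
  if (length(rz$dst) == 0 || length(ry$dst) == 0 || length(rx$dst) == 0)
    return(out)
  out[rz$dst, ry$dst, rx$dst] <- a[rz$src, ry$src, rx$src]
  out
}
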