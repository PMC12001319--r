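#' Binary-mask style operators
#'
#' Composable operators that turn an anatomical ground-truth mask into a
#' systematically "styled" mask: isotropic morphology in voxel units,
#' slice-selection against reference structures, depth-limited extension
#' into (or trimming out of) a neighbouring structure in mm, set difference,
#' and bounding-box aspect splits. These are the primitives from which
#' simulated contouring styles are built for meta-training and held-out
#' evaluation.
#'
#' Morphological radii are in voxels with a Euclidean ball structuring
#' element (anisotropy deliberately ignored, matching the "N pixels
#' isometrically" convention); depth-based operators measure true Euclidean
#' distance in mm between voxel centres using the grid spacing, and include
#' ties (distance exactly equal to the threshold).
#'
#' @param mask,target a `ddl_mask` to be styled.
#' @param radius_px non-negative integer ball radius in voxels.
#' @param ref,neighbor,other reference `ddl_mask` on the same grid.
#' @param refs list of reference `ddl_mask` objects (non-empty list).
#' @param depth_mm non-negative depth in mm.
#' @param axis `"superior"` (keep low axial indices) or `"posterior"`
#'   (keep high anterior-posterior indices).
#' @param keep_fraction fraction of the mask's bounding-box extent to keep,
#'   in `(0, 1]`.
#' @return A `ddl_mask` on the same grid and spacing as the input.
#' @examples
#' m <- new_mask(array(FALSE, c(8, 8, 8)), c(1, 1, 1))
#' m$grid[4, 4, 4] <- TRUE
#' sum(dilate(m, 2)$grid)  # 33 voxels in a radius-2 Euclidean ball
#' @name style_ops
NULL

ball_offsets <- function(radius_px) {
  r <- as.integer(radius_px)
  g <- expand.grid(dz = -r:r, dy = -r:r, dx = -r:r)
  g[g$dz^2 + g$dy^2 + g$dx^2 <= r^2, , drop = FALSE]
}

#' @rdname style_ops
#' @export
dilate <- function(mask, radius_px) {
  stopifnot(is_mask(mask))
  if (radius_px < 0) stop("radius_px must be >= 0")
  if (radius_px == 0 || !any(mask$grid)) return(mask)
  off <- ball_offsets(radius_px)
  out <- array(FALSE, dim(mask$grid))
  for (i in seq_len(nrow(off)))
    out <- out | shift3(mask$grid, off$dz[i], off$dy[i], off$dx[i], FALSE)
  new_mask(out, mask$spacing)
}

#' @rdname style_ops
#' @export
erode <- function(mask, radius_px) {
  stopifnot(is_mask(mask))
  if (radius_px < 0) stop("radius_px must be >= 0")
  if (radius_px == 0 || !any(mask$grid)) return(mask)
  off <- ball_offsets(radius_px)
  out <- array(TRUE, dim(mask$grid))
  # structuring element clipped at the volume border (outside counts as
  # foreground), so closing always contains the original mask
  for (i in seq_len(nrow(off)))
    out <- out & shift3(mask$grid, -off$dz[i], -off$dy[i], -off$dx[i], TRUE)
  new_mask(out, mask$spacing)
}

slices_with_any <- function(mask) {
  apply(mask$grid, 1, any)
}

# Recycle a per-slice logical along axes 2 and 3 of the grid.
expand_slices <- function(keep, d) {
  array(rep(keep, times = d[2] * d[3]), d)
}

#' @rdname style_ops
#' @export
keep_slices_with <- function(mask, ref) {
  stopifnot(is_mask(mask), is_mask(ref))
  check_same_grid(mask, ref)
  keep <- slices_with_any(ref)
  new_mask(mask$grid & expand_slices(keep, dim(mask$grid)), mask$spacing)
}

#' @rdname style_ops
#' @export
keep_slices_without <- function(mask, refs) {
  stopifnot(is_mask(mask))
  if (!is.list(refs) || length(refs) == 0)
    stop("refs must be a non-empty list of masks")
  bad <- rep(FALSE, dim(mask$grid)[1])
  for (r in refs) {
    stopifnot(is_mask(r))
    check_same_grid(mask, r)
    bad <- bad | slices_with_any(r)
  }
  new_mask(mask$grid & expand_slices(!bad, dim(mask$grid)), mask$spacing)
}

#' @rdname style_ops
#' @export
extend_into <- function(target, neighbor, depth_mm) {
  stopifnot(is_mask(target), is_mask(neighbor))
  check_same_grid(target, neighbor, spacing = TRUE)
  if (depth_mm < 0) stop("depth_mm must be >= 0")
  if (!any(target$grid) || !any(neighbor$grid)) return(target)
  d <- edt_mm(target)
  new_mask(target$grid | (neighbor$grid & d <= depth_mm), target$spacing)
}

#' @rdname style_ops
#' @export
cap_extension_into <- function(target, neighbor, depth_mm) {
  stopifnot(is_mask(target), is_mask(neighbor))
  check_same_grid(target, neighbor, spacing = TRUE)
  if (depth_mm < 0) stop("depth_mm must be >= 0")
  if (!any(neighbor$grid)) return(target)
  exterior <- new_mask(!neighbor$grid, neighbor$spacing)
  dn <- edt_mm(exterior)  # depth inside the neighbour, mm; Inf if no exterior
  remove <- neighbor$grid & dn > depth_mm
  new_mask(target$grid & !remove, target$spacing)
}

#' @rdname style_ops
#' @export
exclude_structure <- function(target, other) {
  stopifnot(is_mask(target), is_mask(other))
  check_same_grid(target, other)
  new_mask(target$grid & !other$grid, target$spacing)
}

#' @rdname style_ops
#' @export
aspect_split <- function(mask, axis = c("superior", "posterior"),
                         keep_fraction = 0.5) {
  stopifnot(is_mask(mask))
  axis <- match.arg(axis)
  if (!any(mask$grid)) stop("aspect_split needs a non-empty mask")
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must be in (0, 1]")
  if (keep_fraction == 1) return(mask)
  ax <- if (axis == "superior") 1L else 2L
  present <- apply(mask$grid, ax, any)
  lo <- which(present)[1]
  hi <- tail(which(present), 1)
  n <- hi - lo + 1
  k <- floor(n * keep_fraction)
  keep <- rep(FALSE, dim(mask$grid)[ax])
  if (k > 0) {
    idx <- if (axis == "superior") lo:(lo + k - 1) else (hi - k + 1):hi
    keep[idx] <- TRUE
  }
  d <- dim(mask$grid)
  keep_arr <- if (ax == 1L) expand_slices(keep, d) else
    aperm(array(rep(keep, times = d[1] * d[3]), c(d[2], d[1], d[3])),
          c(2, 1, 3))
  new_mask(mask$grid & keep_arr, mask$spacing)
}

#' Style transforms: named, ordered compositions of mask operators
#'
#' A style transform records the operator pipeline that maps an anatomical
#' ground-truth target to its styled counterpart. [apply_style()] folds the
#' steps in order, starting from `structures$target`; reference-structure
#' arguments are looked up by name in the structure set, so the same
#' transform applies to every subject.
#'
#' @param name style name.
#' @param steps list of steps created by [style_step()].
#' @param held_out logical; held-out styles are reserved for evaluation and
#'   never drawn during meta-training.
#' @param op operator name: one of `"dilate"`, `"erode"`,
#'   `"keep_slices_with"`, `"keep_slices_without"`, `"extend_into"`,
#'   `"cap_extension_into"`, `"exclude_structure"`, `"aspect_split"`.
#' @param ... operator parameters (`radius_px`, `depth_mm`, `axis`,
#'   `keep_fraction`).
#' @param ref reference structure name (or character vector of names for
#'   `keep_slices_without`), or `NULL` for operators without a reference.
#' @return `style_transform()` returns a `ddl_style`; `apply_style()`
#'   returns the styled `ddl_mask`.
#' @examples
#' s <- generate_subject(3, shape = c(16, 16, 16))
#' st <- style_transform("demo", list(
#'   style_step("erode", radius_px = 1),
#'   style_step("keep_slices_with", ref = "ref_a")
#' ))
#' styled <- apply_style(st, s$structures)
#' @export
style_transform <- function(name, steps, held_out = FALSE) {
  stopifnot(is.character(name), length(name) == 1, is.list(steps))
  structure(list(name = name, steps = steps, held_out = isTRUE(held_out)),
            class = "ddl_style")
}

#' @rdname style_transform
#' @export
style_step <- function(op, ..., ref = NULL) {
  known <- c("dilate", "erode", "keep_slices_with", "keep_slices_without",
             "extend_into", "cap_extension_into", "exclude_structure",
             "aspect_split")
  if (!op %in% known) stop("unknown style operator: ", op)
  list(op = op, params = list(...), ref = ref)
}

#' @export
print.ddl_style <- function(x, ...) {
  cat("<ddl_style> ", x$name, if (x$held_out) " (held out)", ": ",
      paste(vapply(x$steps, function(s) s$op, ""), collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

#' @rdname style_transform
#' @param transform a `ddl_style`.
#' @param structures a `ddl_structures` set containing `target` and every
#'   structure the transform references.
#' @export
apply_style <- function(transform, structures) {
  stopifnot(inherits(transform, "ddl_style"),
            inherits(structures, "ddl_structures"))
  get_ref <- function(nm) {
    if (!nm %in% names(structures))
      stop("style '", transform$name, "' references unknown structure '",
           nm, "'")
    structures[[nm]]
  }
  m <- structures$target
  for (s in transform$steps) {
    m <- switch(s$op,
      dilate = dilate(m, s$params$radius_px),
      erode = erode(m, s$params$radius_px),
      keep_slices_with = keep_slices_with(m, get_ref(s$ref)),
      keep_slices_without = keep_slices_without(m, lapply(s$ref, get_ref)),
      extend_into = extend_into(m, get_ref(s$ref), s$params$depth_mm),
      cap_extension_into = cap_extension_into(m, get_ref(s$ref),
                                              s$params$depth_mm),
      exclude_structure = exclude_structure(m, get_ref(s$ref)),
      aspect_split = aspect_split(m, s$params$axis, s$params$keep_fraction),
      stop("unknown style operator: ", s$op)
    )
  }
  m
}

#' The shipped style library
#'
#' Reads the package's style-transform presets from a structured YAML file:
#' sixteen training styles (morphology at several radii, slice selection
#' against neighbours and reference structures, depth-limited extension into
#' neighbours, complete exclusion of the superior neighbour) and four
#' held-out evaluation styles (a capped extension into the superior
#' neighbour, a deeper extension into the posterior neighbour, exclusion of
#' `ref_b`, and a superior aspect split). Held-out styles are never used in
#' meta-training; they exist to test adaptation to unseen styles.
#'
#' @param path YAML file to read; defaults to the preset library shipped
#'   with the package.
#' @return Named list of `ddl_style` objects.
#' @examples
#' lib <- style_library()
#' names(Filter(function(s) s$held_out, lib))
#' @export
style_library <- function(path = system.file("extdata", "styles.yaml",
                                             package = "ddlseg")) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  for (st in cfg$styles) {
    steps <- lapply(st$steps, function(s) {
      params <- s[setdiff(names(s), c("op", "ref"))]
      do.call(style_step, c(list(op = s$op), params,
                            list(ref = unlist(s$ref))))
    })
    out[[st$name]] <- style_transform(st$name, steps,
                                      held_out = isTRUE(st$held_out))
  }
  out
}

style_names <- function(lib, held_out) {
  names(Filter(function(s) s$held_out == held_out, lib))
}
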