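#' Write and read subjects as NIfTI
#'
#' A subject on disk is three NIfTI files plus a JSON manifest entry: the
#' image, a label map encoding all structure masks, and the general-model
#' mask. Structures may overlap (the target deliberately overlaps its
#' neighbours), so the label map is a bit field: each structure owns one
#' bit, declared in the manifest's `structure_bits` table, and a voxel's
#' label is the sum of the bits of the structures covering it. This makes
#' the write/read round trip lossless for every mask. Spacing travels in
#' the NIfTI header (stored as 32-bit float, hence preserved to about
#' 1e-6 mm relative).
#'
#' @param subjects list of `ddl_subject`.
#' @param dir output directory (created if missing).
#' @return `write_subjects()` returns the manifest path invisibly;
#'   `read_subject()` returns a `ddl_subject`.
#' @export
write_subjects <- function(subjects, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bits <- structure_bits()
  entries <- lapply(subjects, function(s) {
    id <- s$subject_id
    label <- array(0L, dim(s$volume$grid))
    for (nm in names(bits)) label <- label + bits[[nm]] * s$structures[[nm]]$grid
    write_nifti_grid(s$volume$grid, s$volume$spacing,
                     file.path(dir, paste0(id, "_image.nii.gz")), "double")
    write_nifti_grid(label, s$volume$spacing,
                     file.path(dir, paste0(id, "_labels.nii.gz")), "uint8")
    write_nifti_grid(s$general_mask$grid, s$volume$spacing,
                     file.path(dir, paste0(id, "_general.nii.gz")), "uint8")
    list(subject_id = id, seed = s$seed, spacing = s$volume$spacing,
         shape = dim(s$volume$grid))
  })
  manifest <- list(format = "ddlseg-subjects-1", structure_bits = bits,
                   subjects = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

structure_bits <- function() {
  list(target = 1L, neighbor_sup = 2L, neighbor_post = 4L, ref_a = 8L,
       ref_b = 16L)
}

write_nifti_grid <- function(grid, spacing, path, datatype) {
  a <- if (datatype == "uint8") array(as.integer(grid), dim(grid))
       else array(as.numeric(grid), dim(grid))
  attr(a, "pixdim") <- spacing
  RNifti::writeNifti(RNifti::asNifti(a, datatype = datatype), path)
}

#' @rdname write_subjects
#' @param subject_id id of the subject to read back.
#' @export
read_subject <- function(dir, subject_id) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("manifest not found: ", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  entry <- NULL
  for (i in seq_len(nrow(manifest$subjects))) {
    if (manifest$subjects$subject_id[i] == subject_id)
      entry <- manifest$subjects[i, ]
  }
  if (is.null(entry)) stop("subject '", subject_id, "' not in manifest")
  paths <- file.path(dir, paste0(subject_id,
                                 c("_image.nii.gz", "_labels.nii.gz",
                                   "_general.nii.gz")))
  for (p in paths) if (!file.exists(p)) stop("missing file: ", p)
  img <- RNifti::readNifti(paths[1])
  lab <- RNifti::readNifti(paths[2])
  gen <- RNifti::readNifti(paths[3])
  spacing <- RNifti::pixdim(img)
  grids <- list(img, lab, gen)
  d <- dim(img)
  for (g in grids) {
    if (!identical(dim(g), d)) stop("incongruent grids for ", subject_id)
    if (!isTRUE(all.equal(RNifti::pixdim(g), spacing, tolerance = 1e-5)))
      stop("incongruent spacing for ", subject_id)
  }
  bits <- manifest$structure_bits
  lab <- array(as.integer(lab), d)
  declared <- Reduce(`+`, bits)  # union of declared bits
  bad <- setdiff(unique(as.vector(bitwAnd(lab, bitwNot(as.integer(declared))))),
                 0L)
  if (length(bad) > 0)
    stop("label map contains undeclared codes: ",
         paste(sort(unique(as.vector(lab[bitwAnd(lab,
           bitwNot(as.integer(declared))) != 0]))), collapse = ", "))
  structures <- lapply(bits, function(b) {
    new_mask(array(bitwAnd(lab, as.integer(b)) != 0, d), spacing)
  })
  structure(list(
    volume = new_volume(array(as.numeric(img), d), spacing),
    structures = structure(structures, class = "ddl_structures"),
    general_mask = new_mask(array(as.integer(gen) != 0, d), spacing),
    subject_id = subject_id,
    seed = as.integer(entry$seed)
  ), class = "ddl_subject")
}

#' Save and load model checkpoints
#'
#' A checkpoint stores the architecture spec, all learnable parameters and
#' the parameter digest. On load the digest is recomputed and must match
#' the stored value (otherwise the file is corrupt), and, when an expected
#' architecture is supplied, every architecture field must match.
#'
#' @param state a `ddl_model`.
#' @param path file path.
#' @param expected_arch optional `ddl_arch` the caller requires.
#' @return `load_checkpoint()` returns the `ddl_model`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "ddl_model"))
  saveRDS(list(format = "ddlseg-checkpoint-1",
               arch = unclass(state$arch), params = state$params,
               digest = state$digest), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expected_arch = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt checkpoint ", path, ": ",
                                           conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "ddlseg-checkpoint-1"))
    stop("corrupt checkpoint ", path, ": unrecognized format")
  if (!identical(model_digest(obj$params), obj$digest))
    stop("corrupt checkpoint ", path, ": parameter digest mismatch")
  arch <- do.call(arch_spec, obj$arch)
  if (!is.null(expected_arch) &&
      !identical(unclass(arch), unclass(expected_arch)))
    stop("checkpoint architecture (base ", arch$base_features,
         ") does not match the requested configuration (base ",
         expected_arch$base_features, ")")
  new_model(arch, obj$params)
}
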