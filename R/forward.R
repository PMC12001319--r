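#' Forward computation: encoder, difference block, decoder
#'
#' `encode()` runs one (image, mask) pair through the shared encoder and
#' returns the feature pyramid (one array per level, channels first,
#' spatial size halved and channels doubled per level). `ddl_block()`
#' subtracts each prior's general-model features from its approved-contour
#' features at the deepest level, applies the learnable 3D convolution and
#' tanh, and averages over priors; its output lies strictly in (-1, 1).
#' `decode()` concatenates a style grid with the deepest query features and
#' decodes to a probability volume; an all-zero style grid is the
#' "no adaptation" forward pass. `ddl_forward()` composes the three for a
#' query and a (possibly empty) support set. None of these functions
#' mutates the model: the parameter digest is identical before and after.
#'
#' @param state a `ddl_model`.
#' @param volume a `ddl_volume` image.
#' @param mask a `ddl_mask` aligned with `volume` (the general-model
#'   contour).
#' @return `encode()`: list of per-level feature arrays `(C, Z, Y, X, 1)`.
#' @examples
#' m <- init_model(arch_spec(base_features = 4), seed = 1)
#' s <- generate_subject(1, shape = c(16, 16, 16))
#' pyr <- encode(m, s$volume, s$general_mask)
#' vapply(pyr, function(f) dim(f)[1], 0)  # 4, 8, 16 channels
#' @export
encode <- function(state, volume, mask) {
  stopifnot(inherits(state, "ddl_model"))
  check_same_grid(volume, mask)
  d <- dim(volume$grid)
  if (any(d %% 2^state$arch$pool_steps != 0))
    stop("spatial dimensions must be divisible by 2^pool_steps; pad upstream")
  x <- pairs_to_tensor(list(list(image = normalize_grid(volume$grid),
                                 mask = mask$grid)))
  enc_forward(state$params, state$arch, x, keep_cache = FALSE)$f
}

#' @rdname encode
#' @param support_P_feats,support_M_feats equal-length lists of feature
#'   pyramids from [encode()]: the approved styled contour pair and the
#'   general-model pair of each prior.
#' @return `ddl_block()`: style feature array `(C_deep, z, y, x, 1)`.
#' @export
ddl_block <- function(state, support_P_feats, support_M_feats) {
  stopifnot(inherits(state, "ddl_model"))
  n <- length(support_P_feats)
  if (n == 0 || n != length(support_M_feats))
    stop("support feature lists must be non-empty and of equal length")
  L <- state$arch$pool_steps + 1
  acc <- NULL
  for (i in seq_len(n)) {
    diff <- support_P_feats[[i]][[L]] - support_M_feats[[i]][[L]]
    s <- tanh(conv3_fwd(diff, state$params$ddl_w, state$params$ddl_b, 1L))
    acc <- if (is.null(acc)) s else acc + s
  }
  acc / n
}

#' @rdname encode
#' @param query_feats feature pyramid of the query pair from [encode()].
#' @param style style feature array from [ddl_block()], or an all-zero
#'   array for the no-adaptation pass.
#' @return `decode()`: probability array `(Z, Y, X)` in `[0, 1]` at input
#'   resolution.
#' @export
decode <- function(state, query_feats, style) {
  stopifnot(inherits(state, "ddl_model"))
  params <- state$params
  arch <- state$arch
  ch <- arch_channels(arch)
  L <- length(ch)
  deep <- query_feats[[L]]
  if (!identical(dim(style), dim(deep)))
    stop("style grid shape does not match the deepest query features")
  cat3 <- ch_cat(style, deep)
  c3 <- conv3_fwd(cat3, params$dec_cat_w, params$dec_cat_b, 1L)
  d_cur <- gn_fwd(relu_fwd(c3), params$dec_cat_gn_g, params$dec_cat_gn_b,
                  gn_groups(ch[L], arch$groupnorm_features_per_group))$y
  for (l in rev(seq_len(L - 1))) {
    pre <- paste0("dec", l, "_")
    catl <- ch_cat(upsample_fwd(d_cur), query_feats[[l]])
    cc <- conv3_fwd(catl, params[[paste0(pre, "w")]],
                    params[[paste0(pre, "b")]], 1L)
    d_cur <- gn_fwd(relu_fwd(cc), params[[paste0(pre, "gn_g")]],
                    params[[paste0(pre, "gn_b")]],
                    gn_groups(ch[l], arch$groupnorm_features_per_group))$y
  }
  logits <- params$out_w %*% matrix(d_cur, nrow = ch[1]) + params$out_b
  array(sigmoid(logits), dim(d_cur)[2:4])
}

#' @rdname encode
#' @param query list with elements `volume` (a `ddl_volume`) and `mask`
#'   (the general-model `ddl_mask`).
#' @param supports list (possibly empty) of priors, each a list with
#'   `volume`, `general` and `truth` (approved styled `ddl_mask`).
#' @return `ddl_forward()`: probability array `(Z, Y, X)`.
#' @export
ddl_forward <- function(state, query, supports = list()) {
  stopifnot(inherits(state, "ddl_model"))
  k <- length(supports)
  x <- episode_tensor(query, supports, state$arch$pool_steps)
  net_forward(state$params, state$arch, x, k)$prob
}

# Build the (2, Z, Y, X, 2k+1) batch for a query and k supports.
episode_tensor <- function(query, supports, pool_steps = 2L) {
  d <- dim(query$volume$grid)
  if (any(d %% 2^pool_steps != 0))
    stop("spatial dimensions must be divisible by 2^pool_steps; pad upstream")
  for (s in supports) {
    check_same_grid(s$volume, query$volume, spacing = TRUE)
  }
  pairs <- vector("list", 1 + 2 * length(supports))
  pairs[[1]] <- list(image = normalize_grid(query$volume$grid),
                     mask = query$mask$grid)
  k <- length(supports)
  for (i in seq_len(k)) {
    img <- normalize_grid(supports[[i]]$volume$grid)
    pairs[[1 + i]] <- list(image = img, mask = supports[[i]]$truth$grid)
    pairs[[1 + k + i]] <- list(image = img, mask = supports[[i]]$general$grid)
  }
  pairs_to_tensor(pairs)
}
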