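#' Architecture hyperparameters
#'
#' The network is a shared 3D encoder, a feature-difference block, and a
#' decoder. Each encoder level applies a 3x3x3 convolution, ReLU, group
#' normalization, then three parallel atrous (dilated) convolutions whose
#' outputs are summed, followed by 2x2x2 max pooling; channels double at
#' each level (`base`, `2*base`, `4*base` for two pooling steps). The
#' difference block subtracts the encoded features of each prior's approved
#' contour pair from those of its general-model pair at the deepest level,
#' applies a learnable 3D convolution and tanh, and averages over priors.
#' The decoder concatenates that style signal with the deepest query
#' features and upsamples back through the levels, merging the query's skip
#' features.
#'
#' @param base_features channels at the top resolution level (32 at full
#'   scale; 8 is the desk-scale default used by the reference training
#'   configuration).
#' @param pool_steps number of pooling steps (levels minus one).
#' @param atrous_rates three dilation rates for the parallel atrous
#'   convolutions.
#' @param groupnorm_features_per_group target features per normalization
#'   group; the group count at a level is
#'   `max(1, channels %/% groupnorm_features_per_group)`.
#' @param in_channels encoder input channels (image + mask = 2).
#' @return An `ddl_arch` list.
#' @examples
#' arch_spec(base_features = 8)
#' @export
arch_spec <- function(base_features = 32, pool_steps = 2,
                      atrous_rates = c(6, 12, 24),
                      groupnorm_features_per_group = 32, in_channels = 2) {
  stopifnot(base_features >= 1, pool_steps >= 1, length(atrous_rates) == 3,
            all(atrous_rates >= 1), groupnorm_features_per_group >= 1,
            in_channels >= 1)
  structure(list(base_features = as.integer(base_features),
                 pool_steps = as.integer(pool_steps),
                 atrous_rates = as.integer(atrous_rates),
                 groupnorm_features_per_group =
                   as.integer(groupnorm_features_per_group),
                 in_channels = as.integer(in_channels)),
            class = "ddl_arch")
}

arch_channels <- function(arch) {
  arch$base_features * 2^(seq_len(arch$pool_steps + 1) - 1)
}

#' Initialize a model
#'
#' Seeded fan-in-scaled normal initialization for all convolution weights;
#' biases and group-norm shifts start at zero, group-norm scales at one.
#' The difference-block convolution bias starts (and its gradient keeps it
#' near) zero so that identical support pairs produce an exactly zero style
#' signal at initialization.
#'
#' @param arch an `ddl_arch`.
#' @param seed integer seed.
#' @return A `ddl_model`: list with `arch`, `params` (named list of
#'   arrays), and `digest`, a content hash over all learnable parameters.
#'   Every training update changes the digest; inference never does.
#' @examples
#' m <- init_model(arch_spec(base_features = 4), seed = 1)
#' nchar(m$digest) > 0
#' @export
init_model <- function(arch, seed) {
  stopifnot(inherits(arch, "ddl_arch"))
  ch <- arch_channels(arch)
  L <- length(ch)
  with_seed(seed, {
    p <- list()
    he <- function(cout, cin_k) {
      matrix(rnorm(cout * cin_k, sd = sqrt(2 / cin_k)), cout, cin_k)
    }
    cin <- arch$in_channels
    for (l in seq_len(L)) {
      pre <- paste0("enc", l, "_")
      p[[paste0(pre, "w1")]] <- he(ch[l], cin * 27L)
      p[[paste0(pre, "b1")]] <- numeric(ch[l])
      p[[paste0(pre, "gn_g")]] <- rep(1, ch[l])
      p[[paste0(pre, "gn_b")]] <- numeric(ch[l])
      for (j in 1:3) {
        p[[paste0(pre, "wa", j)]] <- he(ch[l], ch[l] * 27L)
        p[[paste0(pre, "ba", j)]] <- numeric(ch[l])
      }
      cin <- ch[l]
    }
    cl <- ch[L]
    p$ddl_w <- he(cl, cl * 27L)
    p$ddl_b <- numeric(cl)
    p$dec_cat_w <- he(cl, 2L * cl * 27L)
    p$dec_cat_b <- numeric(cl)
    p$dec_cat_gn_g <- rep(1, cl)
    p$dec_cat_gn_b <- numeric(cl)
    for (l in rev(seq_len(L - 1))) {
      pre <- paste0("dec", l, "_")
      cin_l <- ch[l + 1] + ch[l]
      p[[paste0(pre, "w")]] <- he(ch[l], cin_l * 27L)
      p[[paste0(pre, "b")]] <- numeric(ch[l])
      p[[paste0(pre, "gn_g")]] <- rep(1, ch[l])
      p[[paste0(pre, "gn_b")]] <- numeric(ch[l])
    }
    p$out_w <- he(1L, ch[1])
    p$out_b <- 0
    new_model(arch, p)
  })
}

new_model <- function(arch, params) {
  structure(list(arch = arch, params = params,
                 digest = model_digest(params)), class = "ddl_model")
}

#' Content digest of a model's learnable parameters
#'
#' @param params named list of parameter arrays (or a `ddl_model`).
#' @return Character hash; changes whenever any parameter changes.
#' @export
model_digest <- function(params) {
  if (inherits(params, "ddl_model")) params <- params$params
  digest::digest(params, algo = "xxhash64")
}

#' @export
print.ddl_model <- function(x, ...) {
  ch <- arch_channels(x$arch)
  npar <- sum(vapply(x$params, length, 0L))
  cat("<ddl_model> channels ", paste(ch, collapse = "/"), ", ",
      format(npar, big.mark = ","), " parameters, digest ", x$digest,
      "\n", sep = "")
  invisible(x)
}

# Per-volume intensity standardization applied before the encoder.
normalize_grid <- function(grid) {
  (grid - mean(grid)) / (sd(grid) + 1e-8)
}

# Assemble a (2, Z, Y, X, B) encoder input tensor from (image, mask) pairs.
# Each pair is list(image = 3D array already normalized, mask = logical 3D).
pairs_to_tensor <- function(pairs) {
  d <- dim(pairs[[1]]$image)
  B <- length(pairs)
  x <- array(0, c(2L, d, B))
  for (b in seq_len(B)) {
    x[1L, , , , b] <- pairs[[b]]$image
    x[2L, , , , b] <- as.numeric(pairs[[b]]$mask)
  }
  x
}

enc_forward <- function(params, arch, x, keep_cache = FALSE) {
  ch <- arch_channels(arch)
  L <- length(ch)
  rates <- arch$atrous_rates
  f <- vector("list", L)
  caches <- if (keep_cache) vector("list", L) else NULL
  pools <- if (keep_cache) vector("list", L - 1) else NULL
  for (l in seq_len(L)) {
    pre <- paste0("enc", l, "_")
    r1 <- conv3_fwd(x, params[[paste0(pre, "w1")]],
                    params[[paste0(pre, "b1")]], 1L, relu_out = TRUE)
    gn <- gn_fwd(r1, params[[paste0(pre, "gn_g")]],
                 params[[paste0(pre, "gn_b")]],
                 gn_groups(ch[l], arch$groupnorm_features_per_group))
    a <- conv3_fwd(gn$y, params[[paste0(pre, "wa1")]],
                   params[[paste0(pre, "ba1")]], rates[1]) +
      conv3_fwd(gn$y, params[[paste0(pre, "wa2")]],
                params[[paste0(pre, "ba2")]], rates[2]) +
      conv3_fwd(gn$y, params[[paste0(pre, "wa3")]],
                params[[paste0(pre, "ba3")]], rates[3])
    f[[l]] <- relu_fwd(a)
    if (keep_cache)
      caches[[l]] <- list(x = x, r1 = r1, gny = gn$y, gncache = gn$cache)
    if (l < L) {
      pool <- maxpool_fwd(f[[l]])
      x <- pool$y
      if (keep_cache) pools[[l]] <- pool$cache
    }
  }
  list(f = f, caches = caches, pools = pools)
}

# df_list: per-level gradients w.r.t. the level outputs f[[l]] (arrays of the
# same shape, possibly contributed by both the pooling chain and skips).
enc_backward <- function(params, arch, enc, df_list) {
  ch <- arch_channels(arch)
  L <- length(ch)
  rates <- arch$atrous_rates
  g <- list()
  dcur <- df_list[[L]]
  for (l in rev(seq_len(L))) {
    pre <- paste0("enc", l, "_")
    cache <- enc$caches[[l]]
    da <- relu_bwd(dcur, enc$f[[l]])  # post-ReLU mask equals pre-ReLU mask
    dgny <- 0
    for (j in 1:3) {
      wj <- params[[paste0(pre, "wa", j)]]
      dgny <- dgny + conv3_bwd_input(da, wj, rates[j])
      gw <- conv3_bwd_weight(cache$gny, da, rates[j])
      g[[paste0(pre, "wa", j)]] <- gw$dw
      g[[paste0(pre, "ba", j)]] <- gw$db
    }
    gnb <- gn_bwd(dgny, cache$gncache, params[[paste0(pre, "gn_g")]])
    g[[paste0(pre, "gn_g")]] <- gnb$dgamma
    g[[paste0(pre, "gn_b")]] <- gnb$dbeta
    dc1 <- relu_bwd(gnb$dx, cache$r1)
    gw1 <- conv3_bwd_weight(cache$x, dc1, 1L)
    g[[paste0(pre, "w1")]] <- gw1$dw
    g[[paste0(pre, "b1")]] <- gw1$db
    dx <- conv3_bwd_input(dc1, params[[paste0(pre, "w1")]], 1L)
    if (l > 1) {
      dcur <- maxpool_bwd(dx, enc$pools[[l - 1]]) + df_list[[l - 1]]
    }
  }
  g
}

# Full forward pass over one episode-shaped batch.
#   x: (2, Z, Y, X, 2k+1) with slot 1 = query {X, M}, slots 2..k+1 the
#   support {X_i, P_i} pairs and slots k+2..2k+1 the support {X_i, M_i}
#   pairs. k = 0 gives a single-slot batch and a zero style signal.
net_forward <- function(params, arch, x, k, keep_cache = FALSE) {
  ch <- arch_channels(arch)
  L <- length(ch)
  enc <- enc_forward(params, arch, x, keep_cache)
  f <- enc$f
  deep <- f[[L]]
  dd <- dim(deep)
  sp <- dd[2:4]
  if (k > 0) {
    idx_p <- 1 + seq_len(k)
    idx_m <- 1 + k + seq_len(k)
    diff <- deep[, , , , idx_p, drop = FALSE] -
      deep[, , , , idx_m, drop = FALSE]
    pre_tanh <- conv3_fwd(diff, params$ddl_w, params$ddl_b, 1L)
    s <- tanh(pre_tanh)
    style <- array(rowMeans(matrix(s, ncol = k)), c(ch[L], sp, 1L))
  } else {
    diff <- NULL; s <- NULL
    style <- array(0, c(ch[L], sp, 1L))
  }
  q_deep <- deep[, , , , 1L, drop = FALSE]
  cat3 <- ch_cat(style, q_deep)
  dec <- list()
  r3 <- conv3_fwd(cat3, params$dec_cat_w, params$dec_cat_b, 1L,
                  relu_out = TRUE)
  gn3 <- gn_fwd(r3, params$dec_cat_gn_g, params$dec_cat_gn_b,
                gn_groups(ch[L], arch$groupnorm_features_per_group))
  d_cur <- gn3$y
  dec$top <- list(cat3 = cat3, r3 = r3, gncache = gn3$cache)
  for (l in rev(seq_len(L - 1))) {
    pre <- paste0("dec", l, "_")
    u <- upsample_fwd(d_cur)
    skip <- f[[l]][, , , , 1L, drop = FALSE]
    catl <- ch_cat(u, skip)
    rr <- conv3_fwd(catl, params[[paste0(pre, "w")]],
                    params[[paste0(pre, "b")]], 1L, relu_out = TRUE)
    gg <- gn_fwd(rr, params[[paste0(pre, "gn_g")]],
                 params[[paste0(pre, "gn_b")]],
                 gn_groups(ch[l], arch$groupnorm_features_per_group))
    dec[[paste0("l", l)]] <- list(in_dim = dim(d_cur), catl = catl, rr = rr,
                                  gncache = gg$cache)
    d_cur <- gg$y
  }
  d1 <- d_cur
  N <- prod(dim(d1)[2:4])
  logits <- params$out_w %*% matrix(d1, nrow = ch[1]) + params$out_b
  prob <- array(sigmoid(logits), dim(d1)[2:4])
  res <- list(prob = prob, style = style)
  if (keep_cache)
    res$cache <- list(enc = enc, f = f, diff = diff, s = s, dec = dec,
                      d1 = d1, k = k, dd = dd)
  res
}

net_backward <- function(params, arch, fw, dprob) {
  ch <- arch_channels(arch)
  L <- length(ch)
  cache <- fw$cache
  k <- cache$k
  g <- list()
  prob <- fw$prob
  dlogits <- matrix(dprob * prob * (1 - prob), nrow = 1)
  d1m <- matrix(cache$d1, nrow = ch[1])
  g$out_w <- dlogits %*% t(d1m)
  g$out_b <- sum(dlogits)
  d_cur <- array(t(params$out_w) %*% dlogits, dim(cache$d1))
  for (l in seq_len(L - 1)) {
    pre <- paste0("dec", l, "_")
    dc <- cache$dec[[paste0("l", l)]]
    gnb <- gn_bwd(d_cur, dc$gncache, params[[paste0(pre, "gn_g")]])
    g[[paste0(pre, "gn_g")]] <- gnb$dgamma
    g[[paste0(pre, "gn_b")]] <- gnb$dbeta
    dcc <- relu_bwd(gnb$dx, dc$rr)
    gw <- conv3_bwd_weight(dc$catl, dcc, 1L)
    g[[paste0(pre, "w")]] <- gw$dw
    g[[paste0(pre, "b")]] <- gw$db
    dcat <- conv3_bwd_input(dcc, params[[paste0(pre, "w")]], 1L)
    sp <- ch_split(dcat, ch[l + 1])
    g[[paste0("skip", l)]] <- sp[[2]]  # gradient into the query skip
    d_cur <- upsample_bwd(sp[[1]], dc$in_dim)
  }
  gnb <- gn_bwd(d_cur, cache$dec$top$gncache, params$dec_cat_gn_g)
  g$dec_cat_gn_g <- gnb$dgamma
  g$dec_cat_gn_b <- gnb$dbeta
  dc3 <- relu_bwd(gnb$dx, cache$dec$top$r3)
  gw <- conv3_bwd_weight(cache$dec$top$cat3, dc3, 1L)
  g$dec_cat_w <- gw$dw
  g$dec_cat_b <- gw$db
  dcat3 <- conv3_bwd_input(dc3, params$dec_cat_w, 1L)
  sp <- ch_split(dcat3, ch[L])
  dstyle <- sp[[1]]
  dq_deep <- sp[[2]]

  dd <- cache$dd
  df_deep <- array(0, dd)
  df_deep[, , , , 1L] <- dq_deep
  if (k > 0) {
    s <- cache$s
    ds <- array(rep(as.vector(dstyle) / k, k), dim(s))
    dpre <- ds * (1 - s * s)
    gd <- conv3_bwd_weight(cache$diff, dpre, 1L)
    g$ddl_w <- gd$dw
    g$ddl_b <- gd$db
    ddiff <- conv3_bwd_input(dpre, params$ddl_w, 1L)
    idx_p <- 1 + seq_len(k)
    idx_m <- 1 + k + seq_len(k)
    df_deep[, , , , idx_p] <- df_deep[, , , , idx_p, drop = FALSE] + ddiff
    df_deep[, , , , idx_m] <- df_deep[, , , , idx_m, drop = FALSE] - ddiff
  } else {
    g$ddl_w <- params$ddl_w * 0
    g$ddl_b <- params$ddl_b * 0
  }
  df_list <- vector("list", L)
  df_list[[L]] <- df_deep
  for (l in seq_len(L - 1)) {
    dfl <- array(0, dim(cache$f[[l]]))
    dfl[, , , , 1L] <- g[[paste0("skip", l)]]
    df_list[[l]] <- dfl
    g[[paste0("skip", l)]] <- NULL
  }
  ge <- enc_backward(params, arch, cache$enc, df_list)
  c(g, ge)
}

# Combined loss + full parameter gradient for one episode batch.
loss_and_grads <- function(params, arch, x, k, truth, w_hd) {
  fw <- net_forward(params, arch, x, k, keep_cache = TRUE)
  prob <- pmin(pmax(fw$prob, 0), 1)  # guard FP round-off at the boundaries
  lp <- combined_loss_parts(prob, truth, w_hd)
  grads <- net_backward(params, arch, fw, lp$grad)
  pred_mask <- new_mask(prob >= 0.5, truth$spacing)
  list(loss = lp$loss, grads = grads, prob = prob,
       batch_dsc = dsc(pred_mask, truth),
       dsc_loss = lp$dsc_loss, hd_loss = lp$hd_loss)
}
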