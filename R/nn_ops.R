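# Low-level differentiable tensor operations.
#
# Feature tensors are numeric arrays with dim (C, Z, Y, X, B): channels
# fastest so that channel concatenation and 1x1x1 convolutions are plain
# matrix operations. All forward functions return what their backward
# counterparts need; backward functions return gradients of the same shape
# as their inputs. Convolution GEMMs run in single precision unless the
# option ddlseg.conv_double is TRUE (used by gradient-check tests).

conv_use_double <- function() isTRUE(getOption("ddlseg.conv_double", FALSE))

conv3_fwd <- function(x, w, b, dilation = 1L, relu_out = FALSE) {
  .conv3_fwd_cpp(x, w, b, as.integer(dilation), conv_use_double(), relu_out)
}

# Gradient w.r.t. the input of a stride-1 "same" dilated convolution: a
# convolution of dy with the spatially flipped, channel-transposed kernel.
conv3_bwd_input <- function(dy, w, dilation = 1L) {
  cout <- nrow(w)
  cin <- ncol(w) / 27L
  warr <- array(w, c(cout, cin, 27))
  wt <- aperm(warr[, , 27:1, drop = FALSE], c(2, 1, 3))
  dim(wt) <- c(cin, cout * 27L)
  .conv3_fwd_cpp(dy, wt, numeric(cin), as.integer(dilation),
                 conv_use_double(), FALSE)
}

conv3_bwd_weight <- function(x, dy, dilation = 1L) {
  .conv3_bwd_weight_cpp(x, dy, dim(dy)[1], as.integer(dilation),
                        conv_use_double())
}

relu_fwd <- function(x) {
  .relu_fwd_cpp(x)
}

relu_bwd <- function(dy, x) {
  .relu_bwd_cpp(dy, x)
}

# Group normalization over (channels-in-group x space) per batch element.
gn_groups <- function(channels, features_per_group) {
  max(1L, channels %/% as.integer(features_per_group))
}

gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  r <- .gn_fwd_cpp(x, as.numeric(gamma), as.numeric(beta),
                   as.integer(groups), eps)
  list(y = r$y, cache = list(xhat = r$xhat, sdv = r$sdv,
                             G = as.integer(groups)))
}

gn_bwd <- function(dy, cache, gamma) {
  .gn_bwd_cpp(dy, cache$xhat, cache$sdv, as.numeric(gamma), cache$G)
}

# 2x2x2 max pooling with stride 2 (first maximum wins on ties).
maxpool_fwd <- function(x) {
  d <- dim(x)
  if (any(d[2:4] %% 2 != 0))
    stop("spatial dimensions must be divisible by 2 for pooling")
  r <- .maxpool_fwd_cpp(x)
  list(y = r$y, cache = list(chosen = r$argmax, in_dim = d))
}

maxpool_bwd <- function(dy, cache) {
  dx <- array(0, cache$in_dim)
  dx[cache$chosen] <- dy
  dx
}

# Factor-2 trilinear upsampling, implemented as per-axis interpolation
# matrices (so the backward pass is the transposed matrices).
upsample_matrix_env <- new.env(parent = emptyenv())

upsample_matrix <- function(n) {
  key <- as.character(n)
  hit <- upsample_matrix_env[[key]]
  if (!is.null(hit)) return(hit)
  U <- matrix(0, 2 * n, n)
  for (i in seq_len(2 * n)) {
    p <- (i - 0.5) / 2 + 0.5  # voxel-centre aligned source position
    j <- floor(p)
    w <- p - j
    jl <- min(max(j, 1), n)
    jh <- min(max(j + 1, 1), n)
    U[i, jl] <- U[i, jl] + (1 - w)
    U[i, jh] <- U[i, jh] + w
  }
  upsample_matrix_env[[key]] <- U
  U
}

apply_along <- function(x, M, axis) {
  d <- dim(x)
  perm <- c(axis, setdiff(seq_along(d), axis))
  xp <- aperm(x, perm)
  dim(xp) <- c(d[axis], prod(d[-axis]))
  out <- M %*% xp
  dim(out) <- c(nrow(M), d[perm[-1]])
  aperm(out, order(perm))
}

upsample_fwd <- function(x) {
  d <- dim(x)
  for (ax in 2:4) x <- apply_along(x, upsample_matrix(d[ax]), ax)
  x
}

upsample_bwd <- function(dy, in_dim) {
  for (ax in 2:4) dy <- apply_along(dy, t(upsample_matrix(in_dim[ax])), ax)
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Concatenate two tensors along the channel axis.
ch_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[-1], db[-1]))
  dim(a) <- c(da[1], prod(da[-1]))
  dim(b) <- c(db[1], prod(db[-1]))
  out <- rbind(a, b)
  dim(out) <- c(da[1] + db[1], da[-1])
  out
}

ch_split <- function(x, c1) {
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  a <- x[seq_len(c1), , drop = FALSE]
  b <- x[-seq_len(c1), , drop = FALSE]
  dim(a) <- c(c1, d[-1])
  dim(b) <- c(d[1] - c1, d[-1])
  list(a, b)
}

# Adam optimizer over a named list of parameter arrays/vectors.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
    p <- params[[nm]] - step
    attributes(p) <- attributes(params[[nm]])
    params[[nm]] <- p
  }
  list(params = params, opt = opt)
}
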