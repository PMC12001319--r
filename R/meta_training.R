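#' Training configuration
#'
#' Bundles every knob of the episodic meta-training loop. The default is
#' the desk-scale reference configuration: 8 base features, 24^3 phantoms
#' at clinical voxel spacing, 1500 iterations at batch size one with Adam
#' at learning rate 1e-3, and 1 to 10 priors drawn uniformly per
#' iteration. The "epoch" used by the loss schedule is a fixed block of
#' `epoch_iters` iterations, since the phantom pool is unbounded.
#'
#' @param iterations optimizer steps (one episode each).
#' @param learning_rate Adam learning rate.
#' @param lr_decay_after fraction of the iterations after which the
#'   learning rate is multiplied by `lr_decay_factor` (a single late-stage
#'   step decay; stabilizes batch-size-one training).
#' @param lr_decay_factor late-stage learning-rate multiplier.
#' @param max_priors largest support-set size drawn during training.
#' @param seed master seed; all episode sampling derives from it.
#' @param base_features encoder width at the top level.
#' @param shape,spacing,noise_sd,severity phantom generation parameters
#'   (see [generate_subject()]).
#' @param n_subjects number of phantom subjects in the training pool.
#' @param schedule a [loss_schedule()].
#' @param train_styles,eval_styles character vectors of style names; they
#'   must be disjoint. Defaults: all non-held-out styles for training, the
#'   held-out styles for evaluation.
#' @param epoch_iters iterations per schedule epoch.
#' @return A `ddl_train_config`.
#' @export
train_config <- function(iterations = 1500, learning_rate = 1e-3,
                         lr_decay_after = 2 / 3, lr_decay_factor = 0.3,
                         max_priors = 10, seed = 1, base_features = 8,
                         shape = c(24, 24, 24), spacing = c(2, 1.17, 1.17),
                         noise_sd = 6, severity = 0.28, n_subjects = 400,
                         schedule = loss_schedule(), train_styles = NULL,
                         eval_styles = NULL, epoch_iters = 50) {
  lib <- style_library()
  if (is.null(train_styles)) train_styles <- style_names(lib, FALSE)
  if (is.null(eval_styles)) eval_styles <- style_names(lib, TRUE)
  if (length(intersect(train_styles, eval_styles)) > 0)
    stop("train_styles and eval_styles must be disjoint (held-out protocol)")
  missing <- setdiff(c(train_styles, eval_styles), names(lib))
  if (length(missing) > 0)
    stop("unknown styles: ", paste(missing, collapse = ", "))
  structure(list(iterations = as.integer(iterations),
                 learning_rate = learning_rate,
                 lr_decay_after = lr_decay_after,
                 lr_decay_factor = lr_decay_factor,
                 max_priors = as.integer(max_priors),
                 seed = as.integer(seed),
                 base_features = as.integer(base_features),
                 shape = as.integer(shape), spacing = spacing,
                 noise_sd = noise_sd, severity = severity,
                 n_subjects = as.integer(n_subjects), schedule = schedule,
                 train_styles = train_styles, eval_styles = eval_styles,
                 epoch_iters = as.integer(epoch_iters)),
            class = "ddl_train_config")
}

#' Generate the seeded phantom pool for a configuration
#'
#' @param config a [train_config()].
#' @param n number of subjects (defaults to `config$n_subjects`).
#' @param offset seed offset, used to generate pools disjoint from the
#'   training pool (test subjects, prior subjects).
#' @return List of `ddl_subject`.
#' @export
make_subjects <- function(config, n = config$n_subjects, offset = 0L) {
  lapply(seq_len(n), function(i) {
    generate_subject(derive_seed(config$seed, 1000L * offset + i),
                     shape = config$shape, spacing = config$spacing,
                     noise_sd = config$noise_sd, severity = config$severity)
  })
}

# Seeded per-iteration draws: style uniform over the training styles, k
# uniform over 1..max_priors, plus an episode seed. Pure in the config.
training_draws <- function(config, n_it) {
  with_seed(derive_seed(config$seed, 101), {
    list(style = sample(config$train_styles, n_it, replace = TRUE),
         k = sample.int(config$max_priors, n_it, replace = TRUE),
         ep_seed = sample.int(2147483646L, n_it, replace = TRUE))
  })
}

# Styled-truth cache: applying a style involves distance transforms, so
# styled masks are computed once per (style, subject) pair.
make_style_cache <- function() new.env(parent = emptyenv())

styled_truth <- function(style, subject, cache = NULL) {
  if (is.null(cache)) return(apply_style(style, subject$structures))
  key <- paste(style$name, subject$subject_id, sep = "|")
  hit <- cache[[key]]
  if (is.null(hit)) {
    hit <- apply_style(style, subject$structures)
    cache[[key]] <- hit
  }
  hit
}

#' Build one meta-training episode
#'
#' Samples, without replacement, one query subject and `k` support subjects
#' from the pool, applies the style transform to every member's ground
#' truth, and pairs each with its simulated general-model contour. The
#' query is never among the supports, and the network is never shown the
#' unstyled anatomical truth as a target.
#'
#' @param subjects list of `ddl_subject` (at least `k + 1`).
#' @param style a `ddl_style`.
#' @param k number of supports (>= 1 for training episodes).
#' @param seed integer seed for the draw.
#' @param cache optional style cache from `make_style_cache()`.
#' @return A `ddl_episode`: list with `style`, `query` (list `volume`,
#'   `mask`, `truth`) and `supports` (list of `volume`, `general`,
#'   `truth`).
#' @export
build_episode <- function(subjects, style, k, seed, cache = NULL) {
  stopifnot(inherits(style, "ddl_style"))
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (length(subjects) < k + 1)
    stop("need at least k + 1 = ", k + 1, " subjects, got ", length(subjects))
  idx <- with_seed(seed, sample.int(length(subjects), k + 1))
  q <- subjects[[idx[1]]]
  supports <- lapply(idx[-1], function(i) {
    s <- subjects[[i]]
    list(volume = s$volume, general = s$general_mask,
         truth = styled_truth(style, s, cache), subject_id = s$subject_id)
  })
  structure(list(style = style$name,
                 query = list(volume = q$volume, mask = q$general_mask,
                              truth = styled_truth(style, q, cache),
                              subject_id = q$subject_id),
                 supports = supports),
            class = "ddl_episode")
}

#' One optimizer step on an episode
#'
#' Runs the full forward pass (encoder on query and supports, difference
#' block, decoder), evaluates the combined Dice + weighted Hausdorff loss
#' against the query's styled truth, backpropagates through all three
#' components, and applies one Adam update. The returned model has a new
#' parameter digest.
#'
#' @param state a `ddl_model`.
#' @param episode a `ddl_episode` from [build_episode()].
#' @param epoch schedule epoch index.
#' @param running_dsc running training DSC for the loss gate.
#' @param config a [train_config()].
#' @param opt Adam state from a previous step, or `NULL` to start fresh.
#' @param lr learning rate override (the training loop passes the decayed
#'   rate); defaults to `config$learning_rate`.
#' @return List: `state` (updated model), `opt`, `loss`, `batch_dsc`.
#' @export
train_step <- function(state, episode, epoch, running_dsc, config,
                       opt = NULL, lr = NULL) {
  stopifnot(inherits(state, "ddl_model"), inherits(episode, "ddl_episode"))
  k <- length(episode$supports)
  x <- episode_tensor(list(volume = episode$query$volume,
                           mask = episode$query$mask),
                      episode$supports, state$arch$pool_steps)
  w <- hd_weight(config$schedule, epoch, running_dsc)
  lg <- loss_and_grads(state$params, state$arch, x, k, episode$query$truth, w)
  if (!is.finite(lg$loss))
    stop("non-finite loss on episode (style ", episode$style, ", k = ", k,
         "); check inputs and learning rate")
  if (is.null(opt)) opt <- adam_init(state$params)
  upd <- adam_step(state$params, lg$grads, opt, lr %||% config$learning_rate)
  list(state = new_model(state$arch, upd$params), opt = upd$opt,
       loss = lg$loss, batch_dsc = lg$batch_dsc)
}

#' Episodic meta-training
#'
#' The training loop: at every iteration a style is drawn uniformly from
#' the training styles and a support count `k` uniformly from
#' `1..max_priors`; an episode is sampled and one optimizer step taken.
#' Evaluation (held-out) styles are never drawn. The run is a pure
#' function of the configuration: identical configs give bit-identical
#' final models.
#'
#' By default every episode is built from freshly generated phantom
#' subjects (the phantom pool is unbounded): no support subject ever
#' repeats, so the network cannot memorize subject-specific cues and must
#' learn the style mapping itself — in particular how to separate a
#' prior's style delta from that prior's idiosyncratic general-model
#' error. Passing an explicit `subjects` pool instead trains on a fixed
#' cohort, which is faster to cache but overfits the support pathway at
#' small pool sizes.
#'
#' @param config a [train_config()].
#' @param subjects optional fixed phantom pool; `NULL` (default) draws
#'   fresh subjects each episode.
#' @param verbose print progress every 100 iterations.
#' @return List: `state` (trained `ddl_model`), `trace` (data frame with
#'   one row per iteration: `iter`, `style`, `k`, `loss`, `batch_dsc`,
#'   `running_dsc`, `hd_weight`), `config`.
#' @export
meta_train <- function(config, subjects = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "ddl_train_config"))
  fresh <- is.null(subjects)
  lib <- style_library()
  cache <- if (fresh) NULL else make_style_cache()
  arch <- arch_spec(base_features = config$base_features)
  state <- init_model(arch, derive_seed(config$seed, 77))
  opt <- NULL
  running_dsc <- 0
  n_it <- config$iterations
  trace <- data.frame(iter = seq_len(n_it), style = "", k = 0L, loss = NA_real_,
                      batch_dsc = NA_real_, running_dsc = NA_real_,
                      hd_weight = NA_real_, stringsAsFactors = FALSE)
  draws <- training_draws(config, n_it)
  for (it in seq_len(n_it)) {
    epoch <- (it - 1) %/% config$epoch_iters
    pool <- if (fresh) {
      lapply(seq_len(draws$k[it] + 1L), function(j) {
        generate_subject(derive_seed(draws$ep_seed[it], j),
                         shape = config$shape, spacing = config$spacing,
                         noise_sd = config$noise_sd,
                         severity = config$severity)
      })
    } else subjects
    episode <- build_episode(pool, lib[[draws$style[it]]], draws$k[it],
                             draws$ep_seed[it], cache)
    lr_it <- config$learning_rate *
      if (it > config$lr_decay_after * n_it) config$lr_decay_factor else 1
    stp <- train_step(state, episode, epoch, running_dsc, config, opt, lr_it)
    state <- stp$state
    opt <- stp$opt
    running_dsc <- 0.9 * running_dsc + 0.1 * stp$batch_dsc
    trace$style[it] <- draws$style[it]
    trace$k[it] <- draws$k[it]
    trace$loss[it] <- stp$loss
    trace$batch_dsc[it] <- stp$batch_dsc
    trace$running_dsc[it] <- running_dsc
    trace$hd_weight[it] <- hd_weight(config$schedule, epoch, running_dsc)
    if (verbose && it %% 100 == 0)
      message(sprintf("iter %5d  loss %.4f  dsc %.3f  (running %.3f)",
                      it, stp$loss, stp$batch_dsc, running_dsc))
  }
  if (any(trace$style %in% config$eval_styles))
    stop("internal error: a held-out style was drawn during training")
  list(state = state, trace = trace, config = config)
}
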