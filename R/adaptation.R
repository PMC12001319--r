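#' Prior banks: approved styled contours used to condition prediction
#'
#' A prior bank holds up to `max_priors` (volume, general-model mask,
#' approved styled mask) triples for one style. When more entries are
#' offered than fit, the earliest entries are kept — which priors to use
#' is deliberately left to the user.
#'
#' @param style style name.
#' @param entries list of priors, each `list(volume, general, truth)`.
#' @param max_priors bank capacity.
#' @return A `ddl_prior_bank`.
#' @export
prior_bank <- function(style, entries = list(), max_priors = 10) {
  if (length(entries) > max_priors)
    entries <- entries[seq_len(max_priors)]  # first-in retention
  structure(list(style = style, entries = entries,
                 max_priors = as.integer(max_priors)),
            class = "ddl_prior_bank")
}

bank_add <- function(bank, entry) {
  if (length(bank$entries) < bank$max_priors)
    bank$entries[[length(bank$entries) + 1]] <- entry
  bank
}

#' Segment a query in the bank's style, without updating the model
#'
#' Runs the frozen meta-learned model on the query (image, general-model
#' mask) conditioned on the bank's priors and thresholds the probability
#' output at 0.5. With an empty bank this is the no-adaptation baseline.
#' The model's parameter digest is asserted unchanged by the call.
#'
#' @param state a trained `ddl_model`.
#' @param bank a [prior_bank()] (possibly empty).
#' @param query list with `volume` (a `ddl_volume`) and `mask` (the
#'   general-model `ddl_mask`).
#' @param threshold probability threshold for the output mask.
#' @return Predicted `ddl_mask`.
#' @export
adapt_segment <- function(state, bank, query, threshold = 0.5) {
  stopifnot(inherits(state, "ddl_model"), inherits(bank, "ddl_prior_bank"))
  before <- state$digest
  prob <- ddl_forward(state, query, bank$entries)
  after <- model_digest(state$params)
  if (!identical(before, after))
    stop("model parameters changed during adaptation; frozen-weight ",
         "contract violated")
  new_mask(prob >= threshold, query$volume$spacing)
}

#' Simulate the clinical adaptation workflow for one new style
#'
#' Patients arrive in a seeded order. The first patient's general-model
#' contour is "corrected by the clinician" (simulated by substituting the
#' styled ground truth) and enters the prior bank. Every later patient is
#' first predicted with the current bank, scored against its styled truth,
#' and then its approved (ground-truth) contour joins the bank, up to
#' `max_priors`. No model parameters are updated at any point.
#'
#' @param state a trained `ddl_model`.
#' @param style a `ddl_style` (the new local style).
#' @param subjects list of at least two `ddl_subject`.
#' @param order_seed seed for the arrival order.
#' @param max_priors bank capacity.
#' @param cache optional style cache.
#' @return Data frame with one row per predicted patient: `position`,
#'   `subject_id`, `n_priors`, `dsc`, `hd_mm` (NA when either mask is
#'   empty).
#' @export
simulate_workflow <- function(state, style, subjects, order_seed = 1,
                              max_priors = 10, cache = NULL) {
  stopifnot(inherits(state, "ddl_model"), inherits(style, "ddl_style"))
  if (length(subjects) < 2) stop("workflow needs at least two subjects")
  before <- state$digest
  ord <- with_seed(order_seed, sample.int(length(subjects)))
  bank <- prior_bank(style$name, max_priors = max_priors)
  first <- subjects[[ord[1]]]
  bank <- bank_add(bank, list(volume = first$volume,
                              general = first$general_mask,
                              truth = styled_truth(style, first, cache)))
  rows <- vector("list", length(ord) - 1)
  for (p in seq_along(ord)[-1]) {
    s <- subjects[[ord[p]]]
    truth <- styled_truth(style, s, cache)
    pred <- adapt_segment(state, bank,
                          list(volume = s$volume, mask = s$general_mask))
    hd <- if (any(pred$grid) && any(truth$grid)) hausdorff(pred, truth)
          else NA_real_
    rows[[p - 1]] <- data.frame(position = p, subject_id = s$subject_id,
                                n_priors = length(bank$entries),
                                dsc = dsc(pred, truth), hd_mm = hd,
                                stringsAsFactors = FALSE)
    bank <- bank_add(bank, list(volume = s$volume, general = s$general_mask,
                                truth = truth))
  }
  if (!identical(model_digest(state$params), before))
    stop("model parameters changed during the workflow")
  do.call(rbind, rows)
}

#' Evaluate adaptation across prior counts
#'
#' For each requested number of priors `n` (0 means the no-adaptation
#' baseline), every test subject is segmented with the first `n` priors
#' from the prior pool and scored against its styled truth. Prior and
#' test subjects must be disjoint.
#'
#' @param state a trained `ddl_model`.
#' @param style a `ddl_style`.
#' @param test_subjects,prior_subjects disjoint lists of `ddl_subject`.
#' @param n_values prior counts to evaluate (0 is always meaningful).
#' @param cache optional style cache.
#' @return A `ddl_evalcurve`: list with `summary` (data frame `n_priors`,
#'   `mean_dsc`, `sd_dsc`, `mean_hd`, `sd_hd`) and `records` (per-subject
#'   rows).
#' @export
sweep_priors <- function(state, style, test_subjects, prior_subjects,
                         n_values = c(0, 1, 3, 5, 10), cache = NULL) {
  stopifnot(inherits(state, "ddl_model"), inherits(style, "ddl_style"))
  n_values <- sort(unique(as.integer(n_values)))
  if (max(n_values) > length(prior_subjects))
    stop("requested n = ", max(n_values), " priors but only ",
         length(prior_subjects), " prior subjects are available")
  test_ids <- vapply(test_subjects, function(s) s$subject_id, "")
  prior_ids <- vapply(prior_subjects, function(s) s$subject_id, "")
  if (length(intersect(test_ids, prior_ids)) > 0)
    stop("prior subjects must be disjoint from test subjects")
  before <- state$digest
  priors <- lapply(prior_subjects, function(s) {
    list(volume = s$volume, general = s$general_mask,
         truth = styled_truth(style, s, cache))
  })
  rows <- list()
  for (n in n_values) {
    bank <- prior_bank(style$name, priors[seq_len(n)], max_priors = max(10, n))
    for (s in test_subjects) {
      truth <- styled_truth(style, s, cache)
      pred <- adapt_segment(state, bank,
                            list(volume = s$volume, mask = s$general_mask))
      hd <- if (any(pred$grid) && any(truth$grid)) hausdorff(pred, truth)
            else NA_real_
      rows[[length(rows) + 1]] <-
        data.frame(style = style$name, subject_id = s$subject_id,
                   n_priors = n, dsc = dsc(pred, truth), hd_mm = hd,
                   stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  if (!identical(model_digest(state$params), before))
    stop("model parameters changed during the sweep")
  summary <- do.call(rbind, lapply(split(records, records$n_priors),
    function(d) data.frame(n_priors = d$n_priors[1],
                           mean_dsc = mean(d$dsc), sd_dsc = sd(d$dsc),
                           mean_hd = mean(d$hd_mm, na.rm = TRUE),
                           sd_hd = sd(d$hd_mm, na.rm = TRUE))))
  summary <- summary[order(summary$n_priors), ]
  rownames(summary) <- NULL
  structure(list(summary = summary, records = records, style = style$name),
            class = "ddl_evalcurve")
}

#' @export
print.ddl_evalcurve <- function(x, ...) {
  cat("<ddl_evalcurve> style ", x$style, "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Transfer-learning baseline: fine-tune instead of conditioning
#'
#' The comparison the difference learner is designed to beat in the
#' low-data regime: take the same meta-trained backbone without the
#' difference block (an all-zero style signal), fine-tune every layer on
#' the `k` styled tuning subjects with the combined loss, and evaluate on
#' the test subjects. Unlike adaptation, this changes the model's
#' parameters — the returned digest differs from the input model's.
#'
#' @param state a trained `ddl_model` used as the starting point.
#' @param style a `ddl_style`.
#' @param tune_subjects `k >= 1` subjects used for fine-tuning.
#' @param test_subjects evaluation subjects.
#' @param tune_iterations optimizer steps over the tuning subjects
#'   (cycled).
#' @param learning_rate Adam learning rate for fine-tuning.
#' @param schedule loss schedule; the fine-tuning epoch is 0.
#' @param cache optional style cache.
#' @return List: `curve` (a `ddl_evalcurve` whose `n_priors` column holds
#'   `k`, for side-by-side plotting with [sweep_priors()]), `digest`
#'   (tuned parameters), `k`.
#' @export
transfer_baseline <- function(state, style, tune_subjects, test_subjects,
                              tune_iterations = 150, learning_rate = 1e-3,
                              schedule = loss_schedule(), cache = NULL) {
  stopifnot(inherits(state, "ddl_model"), inherits(style, "ddl_style"))
  k <- length(tune_subjects)
  if (k < 1) stop("transfer learning needs at least one tuning subject")
  params <- state$params
  arch <- state$arch
  opt <- adam_init(params)
  running_dsc <- 0
  for (it in seq_len(tune_iterations)) {
    s <- tune_subjects[[(it - 1) %% k + 1]]
    truth <- styled_truth(style, s, cache)
    x <- episode_tensor(list(volume = s$volume, mask = s$general_mask),
                        list(), arch$pool_steps)
    w <- hd_weight(schedule, 0, running_dsc)
    lg <- loss_and_grads(params, arch, x, 0L, truth, w)
    if (!is.finite(lg$loss)) stop("non-finite loss during fine-tuning")
    upd <- adam_step(params, lg$grads, opt, learning_rate)
    params <- upd$params
    opt <- upd$opt
    running_dsc <- 0.9 * running_dsc + 0.1 * lg$batch_dsc
  }
  tuned <- new_model(arch, params)
  rows <- lapply(test_subjects, function(s) {
    truth <- styled_truth(style, s, cache)
    pred <- adapt_segment(tuned, prior_bank(style$name),
                          list(volume = s$volume, mask = s$general_mask))
    hd <- if (any(pred$grid) && any(truth$grid)) hausdorff(pred, truth)
          else NA_real_
    data.frame(style = style$name, subject_id = s$subject_id, n_priors = k,
               dsc = dsc(pred, truth), hd_mm = hd, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  summary <- data.frame(n_priors = k, mean_dsc = mean(records$dsc),
                        sd_dsc = sd(records$dsc),
                        mean_hd = mean(records$hd_mm, na.rm = TRUE),
                        sd_hd = sd(records$hd_mm, na.rm = TRUE))
  curve <- structure(list(summary = summary, records = records,
                          style = style$name), class = "ddl_evalcurve")
  list(curve = curve, digest = tuned$digest, k = k)
}
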