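# Evaluation orchestration: run a fitted model over held-out sounds with
# repeated-trial references and assemble the full metric report.

#' Bundle an evaluation sound with its repeated-trial references
#'
#' @param stimulus a `sound_stimulus`
#' @param responses list of two (or more) `mua_response` trials of the same
#'   sound; each carries its recording time in `t0_s`
#' @param branch decoder branch the references belong to
#' @param id stimulus identifier (used to refuse train/eval overlap)
#' @export
evaluation_set <- function(stimulus, responses, branch = 1L, id = NULL) {
  stopifnot(inherits(stimulus, "sound_stimulus"), length(responses) >= 2)
  structure(list(stimulus = stimulus, responses = responses,
                 branch = as.integer(branch), id = id),
            class = "evaluation_set")
}

#' Evaluate a model against repeated-trial references
#'
#' For each evaluation sound the model predicts the count distribution at
#' the recording time of each reference trial, samples a simulated response
#' (seeded), and computes the overall metrics (RMSE averaged over the two
#' trials, mean log-likelihood) and the noise-corrected predictive-power
#' metrics (correlation and variance explained, flattened and per-unit with
#' bootstrap CIs across units). Setting `fixed_time_s` pins the time input
#' (stationary mode). Evaluation stimuli whose ids appear in `train_ids`
#' are refused.
#'
#' @param fit a `spikecoder_fit` or `spikecoder_model`
#' @param sets list of [evaluation_set()] objects
#' @param seed seed for response sampling and bootstrap
#' @param fixed_time_s optional constant time input
#' @param train_ids ids of sounds used in training (overlap is an error)
#' @param n_boot bootstrap resamples across units
#' @return tibble: one row per sound x metric with value and bootstrap CI
#' @export
evaluate_model <- function(fit, sets, seed = 1L, fixed_time_s = NULL,
                           train_ids = NULL, n_boot = 200) {
  if (inherits(sets, "evaluation_set")) sets <- list(sets)
  ids <- purrr::map_chr(sets, function(s) if (is.null(s$id)) NA_character_ else as.character(s$id))
  if (!is.null(train_ids) && any(stats::na.omit(ids) %in% as.character(train_ids))) {
    stop("refused: evaluation stimuli overlap the training set", call. = FALSE)
  }
  purrr::imap_dfr(sets, function(es, si) {
    r1 <- es$responses[[1]]; r2 <- es$responses[[2]]
    d1 <- predict_distribution(fit, es$stimulus, start_time_s = r1$t0_s,
                               branch = es$branch, fixed_time_s = fixed_time_s)
    d2 <- predict_distribution(fit, es$stimulus, start_time_s = r2$t0_s,
                               branch = es$branch, fixed_time_s = fixed_time_s)
    nb <- min(ncol(r1$counts), dim(d1)[2])
    clipd <- function(d, nb) {
      if (d$kind == "poisson") count_distribution("poisson", lambda = d$lambda[, seq_len(nb), drop = FALSE])
      else count_distribution("categorical", prob = d$prob[, seq_len(nb), , drop = FALSE])
    }
    d1 <- clipd(d1, nb); d2 <- clipd(d2, nb)
    R1 <- r1$counts[, seq_len(nb), drop = FALSE]
    R2 <- r2$counts[, seq_len(nb), drop = FALSE]
    s1 <- sample_response(d1, seed = derive_seed(seed, paste0("s1_", si)))$counts
    s2 <- sample_response(d2, seed = derive_seed(seed, paste0("s2_", si)))$counts
    pair <- trial_pair(R1, R2, rhat1 = s1, rhat2 = s2, dist1 = d1, dist2 = d2)
    id <- if (is.null(es$id)) paste0("sound", si) else as.character(es$id)
    row <- function(metric, value, per_unit = NULL) {
      ci <- if (!is.null(per_unit)) {
        bootstrap_metric(per_unit, n_boot = n_boot,
                         seed = derive_seed(seed, paste0(metric, si)))
      } else tibble::tibble(boot_median = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, n_units = nrow(R1), n_masked = 0L)
      tibble::tibble(id = id, branch = es$branch, metric = metric,
                     value = value, boot_median = ci$boot_median,
                     ci_lo = ci$ci_lo, ci_hi = ci$ci_hi,
                     n_units = ci$n_units, n_masked = ci$n_masked)
    }
    ll <- mean(c(loglik_metric(d1, R1), loglik_metric(d2, R2)))
    dplyr::bind_rows(
      row("rmse", mean(c(rmse_metric(R1, s1), rmse_metric(R2, s2)))),
      row("log_likelihood", ll),
      row("correlation_explained", suppressWarnings(correlation_explained(pair)),
          suppressWarnings(correlation_explained(pair, per_unit = TRUE))),
      row("variance_explained", suppressWarnings(variance_explained(pair)),
          suppressWarnings(variance_explained(pair, per_unit = TRUE)))
    )
  })
}

#' Write a metric report to CSV and JSON
#'
#' @param report tibble from [evaluate_model()]
#' @param path base path (without extension)
#' @return `path`, invisibly
#' @export
write_metric_report <- function(report, path) {
  utils::write.csv(report, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
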