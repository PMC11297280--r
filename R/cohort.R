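# Generative probit signal-detection model of recognition responses.

#' Parameters of the generative response model
#'
#' Recognition decisions are generated from a probit signal-detection
#' model: on each trial a latent familiarity signal
#' `eta + e`, `e ~ N(0, 1)`, is compared against zero, where for foils
#' `eta = b0_foil + b_age * I(old) + participant_effect` and for targets
#' and lures `eta` additionally contains `(b_sim + b_sim_age * I(old)) * s`
#' with `s` the phrase cosine similarity (targets carry `s = 1`). A lapse
#' probability mixes in uniform guessing, and confidence is read from the
#' magnitude of the latent signal against two thresholds.
#'
#' The defaults are a preset chosen so that simulated per-condition 'old'
#' proportions show the qualitative sMST pattern (targets well above close
#' lures, close above distant lures, distant lures near foils; older
#' adults above younger ones on lures with a shallower similarity slope).
#' They are module defaults for synthetic data, not estimates of any
#' observed cohort.
#'
#' @param b0_foil Baseline probit intercept (default -4.0).
#' @param b_sim Similarity slope for the young group (default 5.0).
#' @param b_age Additive intercept offset for the old group (default 1.3).
#' @param b_sim_age Similarity-by-age interaction, old minus young
#'   (default -1.4: a shallower slope for older adults).
#' @param sd_participant SD of the per-participant random intercept
#'   (default 0.3; set 0 for a pure fixed-effects generator).
#' @param lapse Probability of a uniform random response, in `[0, 0.5]`
#'   (default 0.02).
#' @param conf_thresholds Two increasing cutoffs on `|latent|` separating
#'   guessing / unsure / sure (default `c(0.5, 1.5)`).
#' @return An object of class `response_model_params`.
#' @export
response_model_params <- function(b0_foil = -4.0, b_sim = 5.0, b_age = 1.3,
                                  b_sim_age = -1.4, sd_participant = 0.3,
                                  lapse = 0.02, conf_thresholds = c(0.5, 1.5)) {
  stopifnot(is_scalar_number(b0_foil), is_scalar_number(b_sim),
            is_scalar_number(b_age), is_scalar_number(b_sim_age),
            is_scalar_number(sd_participant), is_scalar_number(lapse),
            is.numeric(conf_thresholds), length(conf_thresholds) == 2L)
  if (sd_participant < 0) {
    abort_smst("sd_participant must be non-negative", "smst_validation_error")
  }
  if (lapse < 0 || lapse > 0.5) {
    abort_smst("lapse must lie in [0, 0.5]", "smst_validation_error")
  }
  if (diff(conf_thresholds) <= 0) {
    abort_smst("conf_thresholds must be strictly increasing",
               "smst_validation_error")
  }
  structure(list(b0_foil = b0_foil, b_sim = b_sim, b_age = b_age,
                 b_sim_age = b_sim_age, sd_participant = sd_participant,
                 lapse = lapse, conf_thresholds = as.numeric(conf_thresholds)),
            class = "response_model_params")
}

# Linear predictor of the generative model (vectorised).
response_linear_predictor <- function(condition, similarity, age_group,
                                      participant_effect, params) {
  n <- length(condition)
  old <- rep_len(as.numeric(age_group == "old"), n)
  eta <- params$b0_foil + params$b_age * old +
    rep_len(participant_effect, n)
  is_sim <- condition != "foil"
  if (any(is_sim)) {
    s <- similarity[is_sim]
    if (anyNA(s) || any(s < 0 | s > 1)) {
      abort_smst("similarity must lie in [0, 1] for target/lure trials",
                 "smst_domain_error")
    }
    eta[is_sim] <- eta[is_sim] +
      (params$b_sim + params$b_sim_age * old[is_sim]) * s
  }
  eta
}

#' Probability of an 'old' response under the generative model
#'
#' For foils: `lapse/2 + (1 - lapse) * pnorm(b0_foil + b_age*I(old) + u)`;
#' for targets and lures the argument additionally contains
#' `(b_sim + b_sim_age*I(old)) * similarity`. All arguments are vectorised.
#'
#' @param condition `"target"`, `"close_lure"`, `"distant_lure"` or `"foil"`.
#' @param similarity Cosine similarity in `[0, 1]` (`NA` for foils;
#'   targets use 1).
#' @param age_group `"young"` or `"old"`.
#' @param participant_effect Participant random intercept (default 0).
#' @param params A [response_model_params()].
#' @return Probability in `[0, 1]`.
#' @examples
#' p <- response_model_params(b0_foil = 0, lapse = 0)
#' response_probability("foil", NA, "young", 0, p) # 0.5
#' @export
response_probability <- function(condition, similarity, age_group,
                                 participant_effect = 0, params) {
  stopifnot(inherits(params, "response_model_params"))
  eta <- response_linear_predictor(condition, similarity, age_group,
                                   participant_effect, params)
  params$lapse / 2 + (1 - params$lapse) * stats::pnorm(eta)
}

#' Simulate a cohort of recognition responses
#'
#' Draws one participant effect per participant from
#' `N(0, sd_participant)`, then one response per recognition trial:
#' a latent familiarity `eta + N(0, 1)` decides 'old' vs 'new' (lapse
#' trials respond uniformly instead) and its magnitude against
#' `conf_thresholds` yields the confidence rating. Random draws come from
#' per-participant sub-streams of `seed` (see [substream_seed()]), so
#' results are reproducible and independent of participant order.
#'
#' @param schedules List of `trial_schedule` objects
#'   (see [generate_trial_schedule()]).
#' @param age_assignment Character vector (`"young"`/`"old"`) named or
#'   positionally indexed by participant id.
#' @param params A [response_model_params()].
#' @param seed Integer master seed.
#' @return Tibble with one row per recognition trial: `participant_id`,
#'   `age_group`, `trial_index`, `condition`, `similarity`, `response`
#'   (`"old"`/`"new"`), `confidence` (`"guessing"`/`"unsure"`/`"sure"`).
#' @export
simulate_cohort <- function(schedules, age_assignment, params, seed = 1L) {
  stopifnot(inherits(params, "response_model_params"))
  ids <- vapply(schedules, `[[`, integer(1L), "participant_id")
  age_of <- function(pid) {
    a <- if (!is.null(names(age_assignment))) age_assignment[[as.character(pid)]]
         else age_assignment[[pid]]
    if (is.na(a) || !a %in% c("young", "old")) {
      abort_smst(sprintf("participant %d has no valid age assignment", pid),
                 "smst_validation_error")
    }
    a
  }
  out <- lapply(schedules, function(s) {
    pid <- s$participant_id
    age <- age_of(pid)
    rec <- s$recognition
    local_seed_eval(substream_seed(seed, c(pid, 3L)), {
      u <- stats::rnorm(1L, 0, params$sd_participant)
      eta <- response_linear_predictor(rec$condition, rec$similarity, age, u,
                                       params)
      latent <- eta + stats::rnorm(nrow(rec))
      is_lapse <- stats::runif(nrow(rec)) < params$lapse
      old <- ifelse(is_lapse, stats::runif(nrow(rec)) < 0.5, latent > 0)
      conf <- cut(abs(latent), c(-Inf, params$conf_thresholds, Inf),
                  labels = c("guessing", "unsure", "sure"))
      tibble::tibble(participant_id = pid, age_group = age,
                     trial_index = rec$trial_index, condition = rec$condition,
                     similarity = rec$similarity,
                     response = ifelse(old, "old", "new"),
                     confidence = as.character(conf))
    })
  })
  dplyr::bind_rows(out)
}

#' Simulate encoding-phase editorial responses
#'
#' The incidental-encoding cover task (would you print this phrase?) is
#' simulated as a fair coin per encoding trial; these responses are
#' carried for format completeness and never analysed.
#'
#' @inheritParams simulate_cohort
#' @return Tibble `participant_id`, `trial_index`, `response`
#'   (`"yes"`/`"no"`).
#' @export
simulate_encoding_responses <- function(schedules, seed = 1L) {
  out <- lapply(schedules, function(s) {
    pid <- s$participant_id
    local_seed_eval(substream_seed(seed, c(pid, 4L)), {
      tibble::tibble(participant_id = pid,
                     trial_index = s$encoding$trial_index,
                     response = ifelse(stats::runif(nrow(s$encoding)) < 0.5,
                                       "yes", "no"))
    })
  })
  dplyr::bind_rows(out)
}

#' Write / read response tables
#'
#' CSV with columns `participant_id, age_group, trial_index, condition,
#' similarity, response, confidence`.
#'
#' @param responses Tibble as produced by [simulate_cohort()].
#' @param path CSV file path.
#' @return `write_responses()` returns `path` invisibly; `read_responses()`
#'   the tibble.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(responses, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
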