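# Signal-detection scoring: per-condition 'old' proportions, d-prime
# contrasts, and the MST lure discrimination index.

#' Per-participant, per-condition 'old' proportions
#'
#' Missing responses (`NA`, e.g. no press inside the response window) are
#' excluded from the denominators. Errors if any participant lacks trials
#' in a condition present in the data.
#'
#' @param responses Tibble with `participant_id`, `condition`, `response`
#'   (`"old"`/`"new"` or `NA`) and optionally `age_group`.
#' @return Tibble, one row per participant, with `p_old_<cond>` and
#'   `n_<cond>` columns for each of target / close_lure / distant_lure /
#'   foil (plus `age_group` if supplied).
#' @export
response_proportions <- function(responses) {
  stopifnot(all(c("participant_id", "condition", "response") %in% names(responses)))
  conds <- c("target", "close_lure", "distant_lure", "foil")
  bad <- setdiff(unique(responses$condition), conds)
  if (length(bad)) {
    abort_smst(sprintf("unknown condition '%s'", bad[[1L]]),
               "smst_validation_error")
  }
  answered <- responses[!is.na(responses$response), , drop = FALSE]
  agg <- dplyr::summarise(
    dplyr::group_by(answered, .data$participant_id, .data$condition),
    p_old = mean(.data$response == "old"),
    n = dplyr::n(),
    .groups = "drop"
  )
  present <- sort(intersect(conds, unique(responses$condition)))
  for (pid in unique(agg$participant_id)) {
    have <- agg$condition[agg$participant_id == pid]
    miss <- setdiff(present, have)
    if (length(miss)) {
      abort_smst(sprintf("participant %s has no trials in condition '%s'",
                         pid, miss[[1L]]),
                 "smst_validation_error")
    }
  }
  wide <- pivot_proportions(agg, present)
  if ("age_group" %in% names(responses)) {
    ages <- unique(responses[, c("participant_id", "age_group")])
    wide <- dplyr::left_join(wide, ages, by = "participant_id")
  }
  wide
}

# Minimal long-to-wide reshape (p_old_<cond> and n_<cond> columns).
pivot_proportions <- function(agg, conds) {
  ids <- sort(unique(agg$participant_id))
  out <- tibble::tibble(participant_id = ids)
  for (cond in conds) {
    sub <- agg[agg$condition == cond, ]
    m <- match(ids, sub$participant_id)
    out[[paste0("p_old_", cond)]] <- sub$p_old[m]
    out[[paste0("n_", cond)]] <- sub$n[m]
  }
  out
}

#' Signal-detection d-prime from hit and false-alarm proportions
#'
#' `qnorm(p_hit') - qnorm(p_fa')`, where the primed proportions are
#' edge-corrected. With `correction = "clip"` (default) a proportion is
#' replaced by `1/(2N)` or `1 - 1/(2N)` only when it is exactly 0 or 1;
#' with `"loglinear"` every proportion is recomputed as
#' `(count + 0.5) / (N + 1)`.
#'
#' @param p_hit,p_fa Proportions in `[0, 1]`.
#' @param n_hit_trials,n_fa_trials Trial counts behind the proportions.
#' @param correction `"clip"` or `"loglinear"`.
#' @return d-prime (vectorised over its arguments).
#' @examples
#' dprime(0.84, 0.16, 50, 50) # ~1.989
#' @export
dprime <- function(p_hit, p_fa, n_hit_trials, n_fa_trials,
                   correction = c("clip", "loglinear")) {
  correction <- match.arg(correction)
  if (any(c(p_hit, p_fa) < 0 | c(p_hit, p_fa) > 1, na.rm = FALSE) ||
      anyNA(c(p_hit, p_fa))) {
    abort_smst("proportions must lie in [0, 1]", "smst_domain_error")
  }
  if (any(c(n_hit_trials, n_fa_trials) < 1)) {
    abort_smst("trial counts must be positive", "smst_domain_error")
  }
  fix <- function(p, n) {
    if (correction == "clip") {
      pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
    } else {
      (p * n + 0.5) / (n + 1)
    }
  }
  stats::qnorm(fix(p_hit, n_hit_trials)) - stats::qnorm(fix(p_fa, n_fa_trials))
}

#' Score a cohort: proportions plus the three d-prime contrasts
#'
#' Computes [response_proportions()] and the three discriminability
#' contrasts of the sMST: target vs close lure, target vs distant lure and
#' target vs foil, with the chosen edge correction. `correction_applied`
#' flags participants for whom any proportion entering a d-prime was 0 or 1.
#'
#' @inheritParams response_proportions
#' @inheritParams dprime
#' @return One row per participant with proportions, `dprime_target_vs_close`,
#'   `dprime_target_vs_distant`, `dprime_target_vs_foil`, and
#'   `correction_applied`.
#' @export
score_responses <- function(responses, correction = c("clip", "loglinear")) {
  correction <- match.arg(correction)
  props <- response_proportions(responses)
  contrasts <- c(close = "close_lure", distant = "distant_lure", foil = "foil")
  edge <- rep(FALSE, nrow(props))
  for (nm in names(contrasts)) {
    cond <- contrasts[[nm]]
    props[[paste0("dprime_target_vs_", nm)]] <- dprime(
      props$p_old_target, props[[paste0("p_old_", cond)]],
      props$n_target, props[[paste0("n_", cond)]], correction = correction
    )
    edge <- edge | props$p_old_target %in% c(0, 1) |
      props[[paste0("p_old_", cond)]] %in% c(0, 1)
  }
  props$correction_applied <- edge
  props
}

#' Lure discrimination index (MST three-response format)
#'
#' `p('similar' | foil) - p('similar' | lure)`, computed per participant
#' exactly in that orientation (note this is the negation of the more
#' common lure-minus-foil convention). Input rows must carry a `condition`
#' of `"foil"` or `"lure"` (close/distant lures may be pre-collapsed;
#' `"close_lure"`/`"distant_lure"` are accepted and collapsed) and a
#' three-way `response` in `old`/`similar`/`new`.
#'
#' @param responses Tibble with `participant_id`, `condition`, `response`.
#' @return Tibble `participant_id`, `ldi`.
#' @export
ldi <- function(responses) {
  stopifnot(all(c("participant_id", "condition", "response") %in% names(responses)))
  cond <- responses$condition
  cond[cond %in% c("close_lure", "distant_lure")] <- "lure"
  if (!any(responses$response == "similar", na.rm = TRUE)) {
    warning("no 'similar' responses in input; LDI computed anyway")
  }
  keep <- !is.na(responses$response) & cond %in% c("lure", "foil")
  d <- tibble::tibble(participant_id = responses$participant_id[keep],
                      condition = cond[keep],
                      similar = responses$response[keep] == "similar")
  agg <- dplyr::summarise(
    dplyr::group_by(d, .data$participant_id, .data$condition),
    p = mean(.data$similar), .groups = "drop"
  )
  ids <- sort(unique(d$participant_id))
  pf <- agg$p[match(paste(ids, "foil"), paste(agg$participant_id, agg$condition))]
  pl <- agg$p[match(paste(ids, "lure"), paste(agg$participant_id, agg$condition))]
  tibble::tibble(participant_id = ids, ldi = pf - pl)
}
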