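# Counterbalanced list rotation and pseudorandomised trial schedules.

#' Experiment design configuration
#'
#' Defaults reproduce the sMST design: 40 participants, 200 encoding
#' trials (100 targets + 100 fillers) and 125 recognition trials (50 exact
#' repeats, 25 close lures, 25 distant lures, 25 foils) drawn from pools
#' of 100 triplets and 125 foils, with at most 3 consecutive recognition
#' trials from one condition. Exact exposure equalisation across
#' participants requires `n_participants * rec_<cond>` to be divisible by
#' the corresponding pool size; with the defaults every target is seen 20
#' times, every lure 10 times and every foil 8 times across the sample.
#'
#' @param n_participants Number of participants (default 40).
#' @param enc_targets,enc_fillers Encoding-list composition (default 100 + 100).
#' @param rec_targets,rec_close,rec_distant,rec_foils Recognition-list
#'   composition (defaults 50, 25, 25, 25).
#' @param pool_triplets,pool_foils Stimulus pool sizes (defaults 100, 125).
#' @param max_run Maximum consecutive same-condition trials (default 3).
#' @param seed Integer master seed for schedule pseudorandomisation.
#' @return An object of class `design_config`.
#' @export
design_config <- function(n_participants = 40L, enc_targets = 100L,
                          enc_fillers = 100L, rec_targets = 50L,
                          rec_close = 25L, rec_distant = 25L, rec_foils = 25L,
                          pool_triplets = 100L, pool_foils = 125L,
                          max_run = 3L, seed = 1L) {
  stopifnot(is_count(n_participants, 1L), is_count(enc_targets, 1L),
            is_count(enc_fillers), is_count(rec_targets, 1L),
            is_count(rec_close), is_count(rec_distant), is_count(rec_foils),
            is_count(pool_triplets, 1L), is_count(pool_foils),
            is_count(max_run, 1L), is_count(abs(seed)))
  cfg <- lapply(
    list(n_participants = n_participants, enc_targets = enc_targets,
         enc_fillers = enc_fillers, rec_targets = rec_targets,
         rec_close = rec_close, rec_distant = rec_distant,
         rec_foils = rec_foils, pool_triplets = pool_triplets,
         pool_foils = pool_foils, max_run = max_run, seed = seed),
    as.integer
  )
  if (cfg$rec_targets + cfg$rec_close + cfg$rec_distant > cfg$pool_triplets) {
    abort_smst("per-list triplet draws exceed the triplet pool",
               "smst_design_error")
  }
  if (cfg$enc_targets != cfg$rec_targets + cfg$rec_close + cfg$rec_distant) {
    abort_smst(
      "enc_targets must equal rec_targets + rec_close + rec_distant (every tested triplet is encoded)",
      "smst_design_error"
    )
  }
  for (cond in c("rec_targets", "rec_close", "rec_distant")) {
    if ((cfg$n_participants * cfg[[cond]]) %% cfg$pool_triplets != 0L) {
      abort_smst(
        sprintf("n_participants * %s (%d) is not divisible by pool_triplets (%d): exact equalization impossible",
                cond, cfg$n_participants * cfg[[cond]], cfg$pool_triplets),
        "smst_design_error"
      )
    }
  }
  if (cfg$rec_foils > 0L && (cfg$n_participants * cfg$rec_foils) %% cfg$pool_foils != 0L) {
    abort_smst(
      sprintf("n_participants * rec_foils (%d) is not divisible by pool_foils (%d): exact equalization impossible",
              cfg$n_participants * cfg$rec_foils, cfg$pool_foils),
      "smst_design_error"
    )
  }
  structure(cfg, class = "design_config")
}

#' Rotate stimulus pools across participants
#'
#' Assigns pool items to recognition conditions per participant by cyclic
#' window rotation: triplets are laid out on a circle; participant `p`
#' takes a window of `rec_targets` triplets as exact-repeat targets, the
#' next `rec_close` as close-lure sources and the next `rec_distant` as
#' distant-lure sources, with the window offset advancing by the greatest
#' common divisor of the three lengths per participant (foils rotate the
#' same way on their own circle). Under the divisibility conditions of
#' [design_config()] this yields exact exposure equalisation: each item
#' appears in its own condition exactly
#' `n_participants * per_list_count / pool_size` times, which is verified
#' post hoc. Triplets left outside all three windows are that
#' participant's first source of encoding fillers.
#'
#' @param config A [design_config()].
#' @param stimulus_set Optional `stimulus_set`; when supplied, pool sizes
#'   are checked against it.
#' @return An object of class `rotation_plan`: per-participant lists of
#'   triplet indices (`targets`, `close`, `distant`, `filler_triplets`)
#'   and foil indices (`foils`).
#' @export
make_rotation_plan <- function(config, stimulus_set = NULL) {
  stopifnot(inherits(config, "design_config"))
  if (!is.null(stimulus_set)) {
    stopifnot(inherits(stimulus_set, "stimulus_set"))
    if (nrow(stimulus_set$triplets) != config$pool_triplets ||
        nrow(stimulus_set$foils) != config$pool_foils) {
      abort_smst(
        sprintf("stimulus set sizes (%d triplets, %d foils) do not match config pools (%d, %d)",
                nrow(stimulus_set$triplets), nrow(stimulus_set$foils),
                config$pool_triplets, config$pool_foils),
        "smst_design_error"
      )
    }
  }
  P <- config$pool_triplets
  lens <- c(config$rec_targets, config$rec_close, config$rec_distant)
  step <- Reduce(gcd_int, lens[lens > 0L])
  wrap <- function(idx, n) ((idx - 1L) %% n) + 1L

  participants <- lapply(seq_len(config$n_participants), function(p) {
    off <- ((p - 1L) * step) %% P
    tgt <- wrap(off + seq_len(config$rec_targets), P)
    cls <- wrap(off + config$rec_targets + seq_len(config$rec_close), P)
    dst <- wrap(off + config$rec_targets + config$rec_close +
                  seq_len(config$rec_distant), P)
    foil <- integer(0)
    if (config$rec_foils > 0L) {
      foff <- ((p - 1L) * config$rec_foils) %% config$pool_foils
      foil <- wrap(foff + seq_len(config$rec_foils), config$pool_foils)
    }
    list(targets = tgt, close = cls, distant = dst, foils = foil,
         filler_triplets = setdiff(seq_len(P), c(tgt, cls, dst)))
  })
  plan <- structure(list(config = config, participants = participants),
                    class = "rotation_plan")

  counts <- rotation_exposure_counts(plan)
  want <- c(targets = config$n_participants * config$rec_targets / P,
            close = config$n_participants * config$rec_close / P,
            distant = config$n_participants * config$rec_distant / P,
            foils = if (config$pool_foils > 0L)
              config$n_participants * config$rec_foils / config$pool_foils else 0)
  for (cond in names(counts)) {
    if (length(counts[[cond]]) && any(counts[[cond]] != want[[cond]])) {
      abort_smst(
        sprintf("rotation cannot equalize '%s' exposures for this configuration", cond),
        "smst_design_error"
      )
    }
  }
  plan
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Exposure counts implied by a rotation plan
#'
#' Tabulates, for each pool item, how often it is scheduled in its own
#' condition across all participants.
#'
#' @param plan A `rotation_plan`.
#' @return List of integer vectors `targets`, `close`, `distant`, `foils`,
#'   one count per pool item.
#' @export
rotation_exposure_counts <- function(plan) {
  stopifnot(inherits(plan, "rotation_plan"))
  P <- plan$config$pool_triplets
  Pf <- plan$config$pool_foils
  count <- function(field, n) {
    idx <- unlist(lapply(plan$participants, `[[`, field))
    tabulate(idx, nbins = n)
  }
  list(targets = count("targets", P), close = count("close", P),
       distant = count("distant", P), foils = count("foils", Pf))
}

# Pseudorandomise a condition-label vector so that no more than max_run
# consecutive entries share a label. Trials are drawn sequentially: at
# each position a label is sampled with probability proportional to its
# remaining count among the labels that would not extend the current run
# beyond max_run; a dead end restarts the draw (bounded restarts, so
# pathological compositions fail loudly instead of looping).
limit_runs <- function(labels, max_run, seed, retries = 1000L) {
  n <- length(labels)
  if (n == 0L) return(integer(0))
  lab <- as.character(labels)
  idx_by <- split(seq_len(n), lab)
  if (length(idx_by) == 1L) {
    # single condition: the run rule is vacuous, any order is a run
    return(local_seed_eval(seed, sample.int(n)))
  }
  local_seed_eval(seed, {
    for (attempt in seq_len(retries)) {
      pools <- lapply(idx_by, function(x) x[sample.int(length(x))])
      counts <- vapply(pools, length, integer(1L))
      out <- integer(n)
      run_label <- ""
      run_len <- 0L
      ok <- TRUE
      for (pos in seq_len(n)) {
        avail <- names(counts)[counts > 0L]
        allowed <- avail[avail != run_label | rep(run_len, length(avail)) < max_run]
        if (!length(allowed)) {
          ok <- FALSE
          break
        }
        pick <- if (length(allowed) == 1L) allowed else
          sample(allowed, 1L, prob = counts[allowed])
        out[pos] <- pools[[pick]][counts[[pick]]]
        counts[[pick]] <- counts[[pick]] - 1L
        if (identical(pick, run_label)) {
          run_len <- run_len + 1L
        } else {
          run_label <- pick
          run_len <- 1L
        }
      }
      if (ok) return(out)
    }
    abort_smst("run-length constraint unsatisfiable for this composition",
               "smst_scheduling_error")
  })
}

#' Generate one participant's trial schedule
#'
#' Builds the encoding list (the target phrases of every triplet assigned
#' to this participant's recognition conditions, plus fillers) and the
#' recognition list (exact repeats for targets, the lure phrase for lure
#' conditions, foil phrases for foils), both pseudorandomised under the
#' run-length constraint. Fillers are target phrases of triplets not
#' assigned to any of this participant's recognition conditions, topped up
#' from the stimulus set's dedicated filler phrases when that pool is
#' exhausted.
#'
#' @param plan A `rotation_plan` from [make_rotation_plan()].
#' @param participant_id Integer participant index (1-based).
#' @param stimulus_set The `stimulus_set` the plan indexes into.
#' @return An object of class `trial_schedule`: `participant_id` plus
#'   tibbles `encoding` (`trial_index`, `adjective`, `noun`, `role`) and
#'   `recognition` (`trial_index`, `adjective`, `noun`, `condition`,
#'   `similarity`; targets carry similarity 1, foils `NA`).
#' @export
generate_trial_schedule <- function(plan, participant_id, stimulus_set) {
  stopifnot(inherits(plan, "rotation_plan"), inherits(stimulus_set, "stimulus_set"))
  config <- plan$config
  if (!is_count(participant_id, 1L) || participant_id > config$n_participants) {
    abort_smst("participant_id outside the plan", "smst_design_error")
  }
  pp <- plan$participants[[participant_id]]
  trip <- stimulus_set$triplets

  enc_idx <- c(pp$targets, pp$close, pp$distant)
  enc <- tibble::tibble(adjective = trip$target_adj[enc_idx],
                        noun = trip$noun[enc_idx], role = "target")
  n_fill <- config$enc_fillers
  fill_adj <- trip$target_adj[pp$filler_triplets]
  fill_noun <- trip$noun[pp$filler_triplets]
  if (length(fill_adj) < n_fill) {
    need <- n_fill - length(fill_adj)
    pool <- stimulus_set$fillers
    if (nrow(pool) < need) {
      abort_smst(
        sprintf("participant %d needs %d dedicated fillers but the stimulus set provides %d",
                participant_id, need, nrow(pool)),
        "smst_design_error"
      )
    }
    off <- ((participant_id - 1L) * need) %% nrow(pool)
    take <- ((off + seq_len(need) - 1L) %% nrow(pool)) + 1L
    fill_adj <- c(fill_adj, pool$adjective[take])
    fill_noun <- c(fill_noun, pool$noun[take])
  } else {
    fill_adj <- fill_adj[seq_len(n_fill)]
    fill_noun <- fill_noun[seq_len(n_fill)]
  }
  enc <- rbind(enc, tibble::tibble(adjective = fill_adj, noun = fill_noun,
                                   role = "filler"))
  perm <- limit_runs(enc$role, config$max_run,
                     substream_seed(config$seed, c(participant_id, 1L)))
  enc <- enc[perm, ]
  enc$trial_index <- seq_len(nrow(enc))
  enc <- enc[, c("trial_index", "adjective", "noun", "role")]

  rec <- rbind(
    tibble::tibble(adjective = trip$target_adj[pp$targets],
                   noun = trip$noun[pp$targets], condition = "target",
                   similarity = 1),
    tibble::tibble(adjective = trip$close_adj[pp$close],
                   noun = trip$noun[pp$close], condition = "close_lure",
                   similarity = trip$sim_close[pp$close]),
    tibble::tibble(adjective = trip$distant_adj[pp$distant],
                   noun = trip$noun[pp$distant], condition = "distant_lure",
                   similarity = trip$sim_distant[pp$distant]),
    tibble::tibble(adjective = stimulus_set$foils$adjective[pp$foils],
                   noun = stimulus_set$foils$noun[pp$foils],
                   condition = "foil", similarity = NA_real_)
  )
  perm <- limit_runs(rec$condition, config$max_run,
                     substream_seed(config$seed, c(participant_id, 2L)))
  rec <- rec[perm, ]
  rec$trial_index <- seq_len(nrow(rec))
  rec <- rec[, c("trial_index", "adjective", "noun", "condition", "similarity")]

  structure(list(participant_id = as.integer(participant_id),
                 encoding = tibble::as_tibble(enc),
                 recognition = tibble::as_tibble(rec)),
            class = "trial_schedule")
}

#' Generate schedules for every participant in a plan
#'
#' @inheritParams generate_trial_schedule
#' @return List of `trial_schedule` objects, one per participant.
#' @export
generate_all_schedules <- function(plan, stimulus_set) {
  lapply(seq_len(plan$config$n_participants),
         function(p) generate_trial_schedule(plan, p, stimulus_set))
}

#' Validate a trial schedule against the design invariants
#'
#' Checks list lengths, per-condition counts, the run-length constraint in
#' both phases, and noun provenance (every lure and repeated target noun
#' was encoded as a target; no foil noun was encoded).
#'
#' @param schedule A `trial_schedule`.
#' @param config The [design_config()] it should satisfy.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_schedule <- function(schedule, config) {
  stopifnot(inherits(schedule, "trial_schedule"), inherits(config, "design_config"))
  v <- character(0)
  enc <- schedule$encoding
  rec <- schedule$recognition
  if (nrow(enc) != config$enc_targets + config$enc_fillers) {
    v <- c(v, sprintf("encoding has %d trials, expected %d", nrow(enc),
                      config$enc_targets + config$enc_fillers))
  }
  want <- c(target = config$rec_targets, close_lure = config$rec_close,
            distant_lure = config$rec_distant, foil = config$rec_foils)
  if (nrow(rec) != sum(want)) {
    v <- c(v, sprintf("recognition has %d trials, expected %d", nrow(rec), sum(want)))
  }
  got <- table(factor(rec$condition, levels = names(want)))
  for (cond in names(want)) {
    if (got[[cond]] != want[[cond]]) {
      v <- c(v, sprintf("condition '%s' has %d trials, expected %d",
                        cond, got[[cond]], want[[cond]]))
    }
  }
  for (phase in list(c("encoding", "role"), c("recognition", "condition"))) {
    r <- rle(schedule[[phase[[1L]]]][[phase[[2L]]]])
    if (length(unique(r$values)) < 2L) next # single condition: rule vacuous
    if (any(r$lengths > config$max_run)) {
      v <- c(v, sprintf("%s run of %d consecutive '%s' trials exceeds max_run=%d",
                        phase[[1L]], max(r$lengths),
                        r$values[[which.max(r$lengths)]], config$max_run))
    }
  }
  enc_target_nouns <- enc$noun[enc$role == "target"]
  lure_nouns <- rec$noun[rec$condition %in% c("close_lure", "distant_lure", "target")]
  bad <- setdiff(lure_nouns, enc_target_nouns)
  if (length(bad)) {
    v <- c(v, sprintf("noun '%s' tested at recognition but never encoded as a target",
                      bad[[1L]]))
  }
  foil_nouns <- rec$noun[rec$condition == "foil"]
  bad <- intersect(foil_nouns, enc$noun)
  if (length(bad)) {
    v <- c(v, sprintf("foil noun '%s' appeared at encoding", bad[[1L]]))
  }
  v
}

#' Write / read trial schedules as one CSV
#'
#' Long format, one row per trial:
#' `participant_id, phase, trial_index, adjective, noun, role_or_condition,
#' similarity`.
#'
#' @param schedules List of `trial_schedule` objects.
#' @param path CSV file path.
#' @return `write_schedules()` returns `path` invisibly; `read_schedules()`
#'   a list of `trial_schedule` objects.
#' @export
write_schedules <- function(schedules, path) {
  rows <- lapply(schedules, function(s) {
    rbind(
      data.frame(participant_id = s$participant_id, phase = "encoding",
                 trial_index = s$encoding$trial_index,
                 adjective = s$encoding$adjective, noun = s$encoding$noun,
                 role_or_condition = s$encoding$role, similarity = NA_real_),
      data.frame(participant_id = s$participant_id, phase = "recognition",
                 trial_index = s$recognition$trial_index,
                 adjective = s$recognition$adjective, noun = s$recognition$noun,
                 role_or_condition = s$recognition$condition,
                 similarity = s$recognition$similarity)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedules
#' @export
read_schedules <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(sort(unique(df$participant_id)), function(pid) {
    d <- df[df$participant_id == pid, ]
    enc <- d[d$phase == "encoding", ]
    rec <- d[d$phase == "recognition", ]
    structure(list(
      participant_id = as.integer(pid),
      encoding = tibble::tibble(trial_index = enc$trial_index,
                                adjective = enc$adjective, noun = enc$noun,
                                role = enc$role_or_condition),
      recognition = tibble::tibble(trial_index = rec$trial_index,
                                   adjective = rec$adjective, noun = rec$noun,
                                   condition = rec$role_or_condition,
                                   similarity = rec$similarity)
    ), class = "trial_schedule")
  })
}
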