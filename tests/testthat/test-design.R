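# Rotation plans, trial schedules, and their validation.

test_that("the paper-shaped rotation equalizes exposures exactly", {
  plan <- make_rotation_plan(design_config(), paper_stimuli())
  cnt <- rotation_exposure_counts(plan)
  expect_true(all(cnt$targets == 20L))
  expect_true(all(cnt$close == 10L))
  expect_true(all(cnt$distant == 10L))
  expect_true(all(cnt$foils == 8L))
})

test_that("divisibility violations are design errors", {
  expect_error(design_config(n_participants = 39), class = "smst_design_error")
  expect_error(design_config(rec_targets = 51),
               class = "smst_design_error") # enc_targets mismatch too
  expect_error(design_config(enc_targets = 99), class = "smst_design_error")
})

test_that("a single participant taking the whole pool is an identity rotation", {
  cfg <- design_config(n_participants = 1, enc_targets = 4, enc_fillers = 0,
                       rec_targets = 4, rec_close = 0, rec_distant = 0,
                       rec_foils = 3, pool_triplets = 4, pool_foils = 3)
  plan <- make_rotation_plan(cfg)
  cnt <- rotation_exposure_counts(plan)
  expect_true(all(cnt$targets == 1L))
  expect_true(all(cnt$foils == 1L))
  expect_setequal(plan$participants[[1]]$targets, 1:4)
})

test_that("paper-shaped schedules have the published list lengths", {
  sch <- paper_schedules()
  expect_length(sch, 40L)
  expect_equal(nrow(sch[[1]]$encoding), 200L)
  expect_equal(nrow(sch[[1]]$recognition), 125L)
  got <- table(sch[[1]]$recognition$condition)
  expect_equal(unname(got[c("target", "close_lure", "distant_lure", "foil")]),
               c(50L, 25L, 25L, 25L), ignore_attr = TRUE)
})

test_that("every generated schedule passes validation", {
  cfg <- design_config()
  for (s in paper_schedules()) {
    expect_length(validate_schedule(s, cfg), 0L)
  }
})

test_that("schedule appearances reproduce the plan's exposure counts", {
  stim <- paper_stimuli()
  sch <- paper_schedules()
  key <- function(adj, noun) paste(adj, noun)
  seen <- table(unlist(lapply(sch, function(s) {
    key(s$recognition$adjective, s$recognition$noun)
  })))
  expect_equal(unname(seen[key(stim$triplets$target_adj, stim$triplets$noun)]),
               rep(20L, 100L), ignore_attr = TRUE)
  expect_equal(unname(seen[key(stim$triplets$close_adj, stim$triplets$noun)]),
               rep(10L, 100L), ignore_attr = TRUE)
  expect_equal(unname(seen[key(stim$triplets$distant_adj, stim$triplets$noun)]),
               rep(10L, 100L), ignore_attr = TRUE)
  expect_equal(unname(seen[key(stim$foils$adjective, stim$foils$noun)]),
               rep(8L, 125L), ignore_attr = TRUE)
})

test_that("each triplet feeds exactly one recognition condition per participant", {
  plan <- make_rotation_plan(design_config(), paper_stimuli())
  for (pp in plan$participants) {
    expect_equal(anyDuplicated(c(pp$targets, pp$close, pp$distant)), 0L)
  }
})

test_that("schedules are reproducible and distinct across participants", {
  stim <- paper_stimuli()
  plan <- make_rotation_plan(design_config(seed = 7L), stim)
  a <- generate_trial_schedule(plan, 3, stim)
  b <- generate_trial_schedule(plan, 3, stim)
  expect_identical(a$recognition, b$recognition)
  expect_identical(a$encoding, b$encoding)
  d <- generate_trial_schedule(plan, 4, stim)
  expect_false(identical(a$recognition$noun, d$recognition$noun))
})

test_that("run-length and provenance violations are flagged", {
  cfg <- design_config()
  s <- paper_schedules()[[1]]
  # inject 4 consecutive foils
  bad <- s
  foil_rows <- which(bad$recognition$condition == "foil")[1:4]
  other_rows <- setdiff(seq_len(nrow(bad$recognition)), foil_rows)
  bad$recognition <- bad$recognition[c(foil_rows, other_rows), ]
  bad$recognition$trial_index <- seq_len(nrow(bad$recognition))
  expect_match(paste(validate_schedule(bad, cfg), collapse = "; "),
               "run of 4 consecutive 'foil'")

  # lure whose noun was never encoded
  bad2 <- s
  lure_row <- which(bad2$recognition$condition == "close_lure")[1]
  bad2$recognition$noun[lure_row] <- "never_encoded_noun"
  expect_match(paste(validate_schedule(bad2, cfg), collapse = "; "),
               "never encoded")
})

test_that("max_run = 1 forces strict alternation at encoding", {
  fx <- small_fixture()
  stim <- build_stimulus_set(fx$lexicon, fx$space, n_triplets = 2,
                             n_foils = 1, n_fillers = 2, seed = 5)
  cfg <- design_config(n_participants = 2, enc_targets = 2, enc_fillers = 2,
                       rec_targets = 1, rec_close = 1, rec_distant = 0,
                       rec_foils = 1, pool_triplets = 2, pool_foils = 1,
                       max_run = 1)
  plan <- make_rotation_plan(cfg, stim)
  s <- generate_trial_schedule(plan, 1, stim)
  expect_true(all(rle(s$encoding$role)$lengths == 1L))
})

test_that("random divisible configs always yield valid schedules", {
  fx <- small_fixture()
  withr::with_seed(51, {
    for (rep in 1:15) {
      P <- sample(c(4L, 6L, 8L), 1)
      k <- P / 2L
      n_part <- sample(c(2L, 4L), 1)
      pool_f <- n_part # rec_foils = 1 divides any pool equal to n_part
      stim <- build_stimulus_set(fx$lexicon, fx$space, n_triplets = P,
                                 n_foils = pool_f, seed = rep)
      cfg <- design_config(n_participants = n_part, enc_targets = P,
                           enc_fillers = 0, rec_targets = k, rec_close = k,
                           rec_distant = 0, rec_foils = 1, pool_triplets = P,
                           pool_foils = pool_f, max_run = 3, seed = rep)
      plan <- make_rotation_plan(cfg, stim)
      for (p in seq_len(n_part)) {
        s <- generate_trial_schedule(plan, p, stim)
        expect_length(validate_schedule(s, cfg), 0L)
      }
    }
  })
})

test_that("schedules survive the CSV round trip", {
  sch <- paper_schedules()[1:3]
  path <- withr::local_tempfile(fileext = ".csv")
  write_schedules(sch, path)
  back <- read_schedules(path)
  expect_length(back, 3L)
  expect_equal(back[[2]]$recognition$noun, sch[[2]]$recognition$noun)
  expect_equal(back[[2]]$recognition$similarity,
               sch[[2]]$recognition$similarity, tolerance = 1e-12)
  expect_equal(back[[3]]$encoding$role, sch[[3]]$encoding$role)
})
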