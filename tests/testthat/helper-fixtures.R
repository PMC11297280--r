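# Shared fixtures, memoised so expensive objects are built once per run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small clustered embedding + lexicon for module tests.
small_fixture <- function() {
  memo("small_fixture", function() {
    generate_fixture_embedding(fixture_config(
      n_nouns = 300L, n_adjectives = 700L, dim = 32L, n_clusters = 12L,
      seed = 101L
    ))
  })
}

# Paper-shaped fixture, stimulus set, plan and schedules (40 participants).
paper_fixture <- function() {
  memo("paper_fixture", function() {
    generate_fixture_embedding(fixture_config(seed = 7L))
  })
}

paper_stimuli <- function() {
  memo("paper_stimuli", function() {
    fx <- paper_fixture()
    build_stimulus_set(fx$lexicon, fx$space, n_triplets = 100L,
                       n_foils = 125L, n_fillers = 100L, seed = 7L)
  })
}

paper_schedules <- function() {
  memo("paper_schedules", function() {
    plan <- make_rotation_plan(design_config(seed = 7L), paper_stimuli())
    generate_all_schedules(plan, paper_stimuli())
  })
}

# A tiny embedding where every vector is chosen by hand.
toy_space <- function() {
  embedding_space(rbind(
    a1 = c(1, 0, 0, 0),
    n1 = c(0, 1, 0, 0),
    a2 = c(0, 0, 1, 0),
    n2 = c(0, 0, 0, 1)
  ))
}

# Build an embedding in which the compound (adjective + noun) of each
# candidate phrase sits at a prescribed cosine to the target compound.
# The noun is shared; adjective i is placed at compound_i - noun, which
# makes phrase similarity exactly cos(theta_i) by construction.
angled_space <- function(target_sims) {
  n_vec <- c(3, 0)
  t_comp <- c(4, 0) # target compound along the x axis
  rows <- list(noun = n_vec, tadj = t_comp - n_vec)
  for (i in seq_along(target_sims)) {
    th <- acos(target_sims[[i]])
    comp <- 4 * c(cos(th), sin(th))
    rows[[paste0("adj", i)]] <- comp - n_vec
  }
  embedding_space(do.call(rbind, rows))
}

# Minimal hand-built trial schedule for simulator tests (recognition only).
fake_schedule <- function(pid, conditions, similarities) {
  structure(list(
    participant_id = as.integer(pid),
    encoding = tibble::tibble(trial_index = integer(0), adjective = character(0),
                              noun = character(0), role = character(0)),
    recognition = tibble::tibble(
      trial_index = seq_along(conditions),
      adjective = paste0("a", seq_along(conditions)),
      noun = paste0("n", seq_along(conditions)),
      condition = conditions, similarity = similarities
    )
  ), class = "trial_schedule")
}
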