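# Triplet assembly, foil selection, and full stimulus-set construction.

test_that("candidate ranking matches a full-sort oracle", {
  fx <- small_fixture()
  space <- fx$space
  nouns <- fx$lexicon$token[fx$lexicon$pos == "noun"]
  adjs <- fx$lexicon$token[fx$lexicon$pos == "adjective"][1:30]
  noun <- nouns[[1]]

  expect_equal(nrow(rank_candidate_phrases(space, noun, adjs, k = 0)), 0L)

  all_ranked <- rank_candidate_phrases(space, noun, adjs, k = 1000)
  expect_equal(nrow(all_ranked), 30L) # k saturates at the candidate count
  # oracle: plain loop over candidates, sorted descending
  sims <- vapply(adjs, function(a) {
    cosine_similarity(embedding_vector(space, a), embedding_vector(space, noun))
  }, numeric(1))
  ord <- order(-sims, adjs)
  expect_equal(all_ranked$adjective, adjs[ord])
  expect_equal(all_ranked$similarity, unname(sims[ord]))
  expect_equal(rank_candidate_phrases(space, noun, adjs, k = 3),
               all_ranked[1:3, ])
})

test_that("triplet selection picks the prescribed band members", {
  # candidates engineered to sit at exact phrase similarities
  space <- angled_space(c(0.72, 0.50, 0.30))
  tr <- build_triplet(space, "noun", "tadj", c("adj1", "adj2", "adj3"))
  expect_s3_class(tr, "triplet")
  expect_equal(tr$close_adj, "adj1")
  expect_equal(tr$sim_close, 0.72, tolerance = 1e-12)
  expect_equal(tr$distant_adj, "adj2")
  expect_equal(tr$sim_distant, 0.50, tolerance = 1e-12)
})

test_that("similarities in the 0.65-0.70 gap satisfy neither band", {
  space <- angled_space(c(0.68, 0.68, 0.66))
  res <- build_triplet(space, "noun", "tadj", c("adj1", "adj2", "adj3"))
  expect_s3_class(res, "triplet_not_found")
  expect_setequal(res$missing, c("close", "distant"))
})

test_that("triplet selection matches a brute-force band scan", {
  fx <- small_fixture()
  space <- fx$space
  nouns <- fx$lexicon$token[fx$lexicon$pos == "noun"]
  adjs <- fx$lexicon$token[fx$lexicon$pos == "adjective"]
  withr::with_seed(41, {
    checked <- 0
    for (noun in sample(nouns, 25)) {
      target <- rank_candidate_phrases(space, noun, adjs, k = 1)$adjective
      cand <- sample(setdiff(adjs, target), 50)
      res <- build_triplet(space, noun, target, cand)
      sims <- vapply(cand, function(a) {
        phrase_similarity(space, phrase(a, noun), phrase(target, noun))
      }, numeric(1))
      in_close <- sims >= 0.7 & sims < 1
      if (inherits(res, "triplet_not_found")) {
        if ("close" %in% res$missing) expect_false(any(in_close))
        next
      }
      checked <- checked + 1
      expect_equal(res$sim_close, max(sims[in_close]))
      in_dist <- sims >= 0.4 & sims <= 0.65 & cand != res$close_adj
      expect_equal(res$distant_adj,
                   cand[in_dist][which.min(abs(sims[in_dist] - 0.525))])
    }
    expect_gt(checked, 5) # the fixture must exercise the found branch
  })
})

test_that("foil adjectives near a target adjective are never used", {
  # adj_far is orthogonal to the target; adj_near is nearly parallel to it
  space <- embedding_space(rbind(
    tadj = c(1, 0, 0), adj_near = c(0.95, 0.1, 0), adj_far = c(0, 0, 1),
    fn1 = c(0, 1, 0)
  ))
  foils <- select_foils(space, nouns = "fn1",
                        adjectives = c("adj_near", "adj_far"),
                        target_adjs = "tadj", n = 1)
  expect_equal(foils$adjective, "adj_far")
  expect_equal(nrow(select_foils(space, "fn1", c("adj_near", "adj_far"),
                                 "tadj", n = 0)), 0L)
  expect_error(
    select_foils(space, "fn1", c("adj_near", "adj_far"), "tadj", n = 2),
    class = "smst_infeasibility_error"
  )
})

test_that("a paper-shaped stimulus set satisfies the design arithmetic", {
  stim <- paper_stimuli()
  expect_equal(nrow(stim$triplets), 100L)
  expect_equal(nrow(stim$foils), 125L)
  expect_equal(length(unique(stim$triplets$noun)), 100L)
  # 3 phrases per triplet + 125 foil phrases; all adjectives distinct
  adjs <- c(stim$triplets$target_adj, stim$triplets$close_adj,
            stim$triplets$distant_adj, stim$foils$adjective)
  expect_equal(length(adjs), 425L)
  expect_equal(length(unique(adjs)), 425L)
  expect_equal(length(unique(c(stim$triplets$noun, stim$foils$noun))), 225L)
  expect_false(any(stim$foils$noun %in% stim$triplets$noun))
  # within-triplet adjectives pairwise distinct
  expect_true(all(stim$triplets$target_adj != stim$triplets$close_adj &
                  stim$triplets$target_adj != stim$triplets$distant_adj &
                  stim$triplets$close_adj != stim$triplets$distant_adj))
})

test_that("emitted lure similarities respect the bands on re-scoring", {
  fx <- paper_fixture()
  stim <- paper_stimuli()
  for (i in seq_len(nrow(stim$triplets))) {
    tp <- phrase(stim$triplets$target_adj[i], stim$triplets$noun[i])
    sc <- phrase_similarity(fx$space, phrase(stim$triplets$close_adj[i],
                                             stim$triplets$noun[i]), tp)
    sd_ <- phrase_similarity(fx$space, phrase(stim$triplets$distant_adj[i],
                                              stim$triplets$noun[i]), tp)
    expect_equal(sc, stim$triplets$sim_close[i])
    expect_equal(sd_, stim$triplets$sim_distant[i])
    expect_gte(sc, 0.70)
    expect_gte(sd_, 0.40)
    expect_lte(sd_, 0.65)
  }
})

test_that("stimulus builds are reproducible and respond to the seed", {
  fx <- small_fixture()
  a <- build_stimulus_set(fx$lexicon, fx$space, n_triplets = 10,
                          n_foils = 12, seed = 3)
  b <- build_stimulus_set(fx$lexicon, fx$space, n_triplets = 10,
                          n_foils = 12, seed = 3)
  expect_identical(a$triplets, b$triplets)
  expect_identical(a$foils, b$foils)
  c <- build_stimulus_set(fx$lexicon, fx$space, n_triplets = 10,
                          n_foils = 12, seed = 4)
  expect_false(identical(a$triplets$noun, c$triplets$noun))
})

test_that("a minimal build emits exactly what was asked for", {
  fx <- small_fixture()
  stim <- build_stimulus_set(fx$lexicon, fx$space, n_triplets = 1,
                             n_foils = 0, seed = 1)
  expect_equal(nrow(stim$triplets), 1L)
  expect_equal(nrow(stim$foils), 0L)
})

test_that("stimulus sets survive the TSV round trip", {
  stim <- paper_stimuli()
  dir <- withr::local_tempdir()
  write_stimulus_set(stim, dir)
  back <- read_stimulus_set(dir)
  expect_equal(back$triplets$noun, stim$triplets$noun)
  expect_equal(back$triplets$sim_close, stim$triplets$sim_close,
               tolerance = 1e-12)
  expect_equal(back$foils, stim$foils)
  expect_equal(back$fillers, stim$fillers)
  expect_error(read_stimulus_set(file.path(dir, "nope")),
               class = "smst_format_error")
})
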