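# Stimulus construction: cosine-band triplet assembly and foil selection.

#' Cosine-similarity bands for lure and foil selection
#'
#' Close lures must reach `close_min` phrase similarity with their target;
#' distant lures must fall inside `[distant_min, distant_max]` (both ends
#' inclusive); foil adjectives must stay below `foil_adj_max` token-level
#' cosine with every target adjective. The default distant-band ceiling is
#' 0.65, leaving a buffer below the close band.
#'
#' @param close_min Minimum phrase similarity of a close lure (default 0.70).
#' @param distant_min,distant_max Distant-lure band (defaults 0.40, 0.65).
#' @param foil_adj_max Exclusive upper bound on foil-adjective-to-target-
#'   adjective cosine (default 0.70).
#' @return An object of class `similarity_bands`.
#' @export
similarity_bands <- function(close_min = 0.70, distant_min = 0.40,
                             distant_max = 0.65, foil_adj_max = 0.70) {
  stopifnot(is_scalar_number(close_min), is_scalar_number(distant_min),
            is_scalar_number(distant_max), is_scalar_number(foil_adj_max))
  if (!(distant_min < distant_max && distant_max <= close_min && close_min <= 1)) {
    abort_smst("bands must satisfy distant_min < distant_max <= close_min <= 1",
               "smst_validation_error")
  }
  structure(list(close_min = close_min, distant_min = distant_min,
                 distant_max = distant_max, foil_adj_max = foil_adj_max),
            class = "similarity_bands")
}

#' Rank candidate adjectives for a noun by token-level cosine
#'
#' Scores each adjective by the cosine between its word vector and the
#' noun's word vector (a proxy for how meaningful the phrase is) and
#' returns the top `k` pairings in descending order. Ties are broken by
#' lexicographic adjective order, so ranking is deterministic.
#'
#' @param space An [embedding_space()].
#' @param noun Noun token.
#' @param adjectives Character vector of candidate adjective tokens.
#' @param k Number of pairings to return (`k = 0` gives an empty table;
#'   `k` beyond the candidate count returns all candidates sorted).
#' @return Tibble with columns `adjective`, `noun`, `similarity`.
#' @export
rank_candidate_phrases <- function(space, noun, adjectives, k = 10L) {
  stopifnot(inherits(space, "embedding_space"), is_count(k))
  missing <- setdiff(c(noun, adjectives), embedding_tokens(space))
  if (length(missing)) {
    abort_smst(sprintf("token '%s' not present in embedding", missing[[1L]]),
               "smst_lookup_error")
  }
  if (length(adjectives) == 0L || k == 0L) {
    return(tibble::tibble(adjective = character(0), noun = character(0),
                          similarity = numeric(0)))
  }
  sims <- token_cosine_many(space, adjectives, noun)
  ord <- order(-sims, adjectives)
  take <- ord[seq_len(min(k, length(adjectives)))]
  tibble::tibble(adjective = adjectives[take], noun = noun,
                 similarity = sims[take])
}

#' Build one target / close-lure / distant-lure triplet
#'
#' Given a target phrase and a pool of candidate lure adjectives, selects
#' the close lure as the candidate whose phrase similarity with the target
#' phrase is maximal within `[close_min, 1)`, and the distant lure as the
#' candidate (excluding the chosen close lure) whose phrase similarity is
#' nearest the midpoint of `[distant_min, distant_max]` within that band.
#' If either band is empty a not-found report naming the empty band(s) is
#' returned instead of an error, so callers can skip infeasible nouns.
#'
#' @param space An [embedding_space()].
#' @param noun Noun token shared by all three phrases.
#' @param target_adj Target adjective token.
#' @param candidates Candidate lure adjectives (must not contain `target_adj`).
#' @param bands A [similarity_bands()].
#' @return A `triplet` (list with `noun`, `target_adj`, `close_adj`,
#'   `distant_adj`, `sim_close`, `sim_distant`) or a `triplet_not_found`
#'   report with the empty band name(s).
#' @export
build_triplet <- function(space, noun, target_adj, candidates,
                          bands = similarity_bands()) {
  stopifnot(inherits(space, "embedding_space"), inherits(bands, "similarity_bands"))
  if (target_adj %in% candidates) {
    abort_smst("candidate pool must not contain the target adjective",
               "smst_validation_error")
  }
  if (length(candidates) == 0L) {
    return(structure(list(noun = noun, missing = c("close", "distant")),
                     class = "triplet_not_found"))
  }
  target_phrase <- phrase(target_adj, noun)
  ref <- compound_vector(space, target_phrase)
  sims <- phrase_similarity_many(space, candidates, noun, ref)

  in_close <- sims >= bands$close_min & sims < 1
  close_adj <- NA_character_
  sim_close <- NA_real_
  if (any(in_close)) {
    ord <- order(-sims, candidates)
    pick <- ord[in_close[ord]][1L]
    close_adj <- candidates[pick]
    sim_close <- sims[pick]
  }

  in_distant <- sims >= bands$distant_min & sims <= bands$distant_max
  if (!is.na(close_adj)) in_distant <- in_distant & candidates != close_adj
  distant_adj <- NA_character_
  sim_distant <- NA_real_
  if (any(in_distant)) {
    mid <- (bands$distant_min + bands$distant_max) / 2
    ord <- order(abs(sims - mid), candidates)
    pick <- ord[in_distant[ord]][1L]
    distant_adj <- candidates[pick]
    sim_distant <- sims[pick]
  }

  missing <- c(if (is.na(close_adj)) "close", if (is.na(distant_adj)) "distant")
  if (length(missing)) {
    return(structure(list(noun = noun, missing = missing),
                     class = "triplet_not_found"))
  }
  structure(list(noun = noun, target_adj = target_adj, close_adj = close_adj,
                 distant_adj = distant_adj, sim_close = sim_close,
                 sim_distant = sim_distant),
            class = "triplet")
}

#' Select foil phrases
#'
#' Builds `n` foil phrases from nouns never used in triplets. An adjective
#' is admissible as a foil adjective only if its token-level cosine with
#' every target adjective stays below `bands$foil_adj_max`; each noun and
#' each adjective is used at most once. For each foil noun (in input
#' order) the admissible unused adjective with the highest token cosine to
#' that noun is chosen.
#'
#' @param space An [embedding_space()].
#' @param nouns Candidate foil nouns (disjoint from triplet nouns).
#' @param adjectives Candidate foil adjectives.
#' @param target_adjs Target adjectives of the triplets already built.
#' @param bands A [similarity_bands()].
#' @param n Number of foils required.
#' @return Tibble with columns `adjective`, `noun`.
#' @export
select_foils <- function(space, nouns, adjectives, target_adjs,
                         bands = similarity_bands(), n) {
  stopifnot(inherits(space, "embedding_space"), is_count(n))
  if (n == 0L) return(tibble::tibble(adjective = character(0), noun = character(0)))
  admissible <- adjectives
  if (length(target_adjs)) {
    tmat <- space$vectors[target_adjs, , drop = FALSE]
    tmat <- tmat / sqrt(rowSums(tmat^2))
    amat <- space$vectors[adjectives, , drop = FALSE]
    amat <- amat / sqrt(rowSums(amat^2))
    maxcos <- apply(amat %*% t(tmat), 1L, max)
    admissible <- adjectives[maxcos < bands$foil_adj_max]
  }
  achievable <- min(length(nouns), length(admissible))
  if (achievable < n) {
    abort_smst(
      sprintf("cannot build %d foils: at most %d achievable (%d nouns, %d admissible adjectives)",
              n, achievable, length(nouns), length(admissible)),
      "smst_infeasibility_error"
    )
  }
  out_adj <- character(n)
  out_noun <- nouns[seq_len(n)]
  free <- admissible
  for (i in seq_len(n)) {
    sims <- token_cosine_many(space, free, out_noun[[i]])
    pick <- order(-sims, free)[[1L]]
    out_adj[[i]] <- free[[pick]]
    free <- free[-pick]
  }
  tibble::tibble(adjective = out_adj, noun = out_noun)
}

#' Build a full sMST stimulus set
#'
#' Runs the whole stimulus-construction procedure on a lexicon and an
#' embedding: percentile/length/syllable filtering, the phonological-
#' neighbourhood cap, per-noun candidate ranking, triplet assembly from
#' the cosine bands, and foil selection. Human curation steps of the
#' original procedure (subjective meaningfulness choices, pragmatic-fit
#' vetoes) are replaced by deterministic rules: candidate rank stands in
#' for meaningfulness, and a greedy pass never reuses an adjective across
#' phrases, so all `3 * n_triplets + n_foils (+ n_fillers)` adjectives are
#' distinct.
#'
#' @param lexicon Lexicon data frame (see [validate_lexicon()]).
#' @param space An [embedding_space()] covering all lexicon tokens.
#' @param criteria A [filter_criteria()].
#' @param bands A [similarity_bands()].
#' @param n_triplets Number of target/close/distant triplets (paper design: 100).
#' @param n_foils Number of foils (paper design: 125).
#' @param n_fillers Number of dedicated encoding filler phrases to emit in
#'   addition (novel nouns, never tested at recognition; default 0).
#' @param k_meaningful Candidate-ranking depth per noun for the target
#'   adjective (default 10).
#' @param seed Integer seed; noun consideration order is shuffled from it.
#' @return An object of class `stimulus_set`: list with tibbles `triplets`
#'   (`noun`, `target_adj`, `close_adj`, `distant_adj`, `sim_close`,
#'   `sim_distant`), `foils` and `fillers` (`adjective`, `noun`), and a
#'   `provenance` record (criteria, bands, counts, seed).
#' @export
build_stimulus_set <- function(lexicon, space, criteria = filter_criteria(),
                               bands = similarity_bands(),
                               n_triplets = 100L, n_foils = 125L,
                               n_fillers = 0L, k_meaningful = 10L, seed = 1L) {
  stopifnot(inherits(space, "embedding_space"),
            is_count(n_triplets, 1L), is_count(n_foils), is_count(n_fillers),
            is_count(k_meaningful, 1L))
  lexicon <- validate_lexicon(lexicon)
  kept <- percentile_band_filter(lexicon, criteria)
  ncounts <- phonological_neighbor_counts(lexicon$token)
  names(ncounts) <- lexicon$token
  kept <- kept[ncounts[kept$token] <= criteria$max_phon_neighbors, , drop = FALSE]
  kept <- kept[kept$token %in% embedding_tokens(space), , drop = FALSE]

  nouns <- kept$token[kept$pos == "noun"]
  adjectives <- sort(kept$token[kept$pos == "adjective"])
  if (length(nouns) < n_triplets + n_foils + n_fillers) {
    abort_smst(
      sprintf("filtered lexicon has %d nouns; need %d (triplets + foils + fillers)",
              length(nouns), n_triplets + n_foils + n_fillers),
      "smst_infeasibility_error"
    )
  }
  nouns <- local_seed_eval(substream_seed(seed, "noun-order"), sample(nouns))

  free_adj <- adjectives
  trip <- vector("list", n_triplets)
  built <- 0L
  used_nouns <- character(0)
  for (noun in nouns) {
    if (built == n_triplets) break
    ranked <- rank_candidate_phrases(space, noun, free_adj, k = k_meaningful)
    if (nrow(ranked) == 0L) next
    target_adj <- ranked$adjective[[1L]]
    cand <- setdiff(free_adj, target_adj)
    res <- build_triplet(space, noun, target_adj, cand, bands)
    if (inherits(res, "triplet_not_found")) next
    built <- built + 1L
    trip[[built]] <- res
    used_nouns <- c(used_nouns, noun)
    free_adj <- setdiff(free_adj, c(res$target_adj, res$close_adj, res$distant_adj))
  }
  if (built < n_triplets) {
    abort_smst(
      sprintf("only %d of %d triplets feasible: lure bands empty for the remaining nouns",
              built, n_triplets),
      "smst_infeasibility_error"
    )
  }
  triplets <- tibble::tibble(
    noun = vapply(trip, `[[`, character(1L), "noun"),
    target_adj = vapply(trip, `[[`, character(1L), "target_adj"),
    close_adj = vapply(trip, `[[`, character(1L), "close_adj"),
    distant_adj = vapply(trip, `[[`, character(1L), "distant_adj"),
    sim_close = vapply(trip, `[[`, numeric(1L), "sim_close"),
    sim_distant = vapply(trip, `[[`, numeric(1L), "sim_distant")
  )

  foil_nouns <- setdiff(nouns, triplets$noun)
  foils <- select_foils(space, foil_nouns, free_adj, triplets$target_adj,
                        bands, n_foils)
  free_adj <- setdiff(free_adj, foils$adjective)

  fillers <- tibble::tibble(adjective = character(0), noun = character(0))
  if (n_fillers > 0L) {
    filler_nouns <- setdiff(foil_nouns, foils$noun)
    if (length(filler_nouns) < n_fillers || length(free_adj) < n_fillers) {
      abort_smst(
        sprintf("cannot build %d fillers: %d nouns and %d adjectives remain",
                n_fillers, length(filler_nouns), length(free_adj)),
        "smst_infeasibility_error"
      )
    }
    f_adj <- character(n_fillers)
    f_noun <- filler_nouns[seq_len(n_fillers)]
    pool <- free_adj
    for (i in seq_len(n_fillers)) {
      sims <- token_cosine_many(space, pool, f_noun[[i]])
      pick <- order(-sims, pool)[[1L]]
      f_adj[[i]] <- pool[[pick]]
      pool <- pool[-pick]
    }
    fillers <- tibble::tibble(adjective = f_adj, noun = f_noun)
  }

  structure(list(
    triplets = triplets, foils = foils, fillers = fillers,
    provenance = list(seed = as.integer(seed), criteria = unclass(criteria),
                      bands = unclass(bands),
                      n_triplets = n_triplets, n_foils = n_foils,
                      n_fillers = n_fillers)
  ), class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set: %d triplets, %d foils, %d fillers>\n",
              nrow(x$triplets), nrow(x$foils), nrow(x$fillers)))
  invisible(x)
}

#' Write / read a stimulus set as TSV tables
#'
#' `write_stimulus_set()` writes `triplets.tsv`
#' (`noun target_adj close_adj distant_adj sim_close sim_distant`),
#' `foils.tsv` and (when present) `fillers.tsv` under `dir`;
#' `read_stimulus_set()` reads them back.
#'
#' @param set A `stimulus_set` (see [build_stimulus_set()]).
#' @param dir Directory for the TSV files (created if needed).
#' @return `write_stimulus_set()` returns `dir` invisibly;
#'   `read_stimulus_set()` a `stimulus_set` (without provenance).
#' @export
write_stimulus_set <- function(set, dir) {
  stopifnot(inherits(set, "stimulus_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(set$triplets, file.path(dir, "triplets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(set$foils, file.path(dir, "foils.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(set$fillers)) {
    utils::write.table(set$fillers, file.path(dir, "fillers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(dir) {
  tf <- file.path(dir, "triplets.tsv")
  ff <- file.path(dir, "foils.tsv")
  if (!file.exists(tf) || !file.exists(ff)) {
    abort_smst(sprintf("'%s' lacks triplets.tsv/foils.tsv", dir),
               "smst_format_error")
  }
  rd <- function(p) tibble::as_tibble(
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = NA, quote = "")
  )
  fillers_path <- file.path(dir, "fillers.tsv")
  structure(list(
    triplets = rd(tf), foils = rd(ff),
    fillers = if (file.exists(fillers_path)) rd(fillers_path) else
      tibble::tibble(adjective = character(0), noun = character(0)),
    provenance = NULL
  ), class = "stimulus_set")
}
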