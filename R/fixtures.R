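# Synthetic-data generators: a clustered embedding space and a lexicon
# with realistic frequency / length / syllable marginals.

#' Configuration of the synthetic embedding and lexicon generator
#'
#' The generator emulates the two data sources the stimulus pipeline
#' needs: a word-embedding space in which thematically related words form
#' clusters (so that close and distant lure bands are both populated) and
#' a lexicon whose frequency, character-count and syllable-count marginals
#' span the filter bounds (so the percentile and length filters have real
#' work to do). Defaults are sized so that a paper-shaped stimulus build
#' (100 triplets, 125 foils, 100 fillers) is comfortably feasible after
#' filtering.
#'
#' @param n_nouns,n_adjectives Lexicon sizes before filtering
#'   (defaults 1000 and 2000).
#' @param dim Embedding dimensionality (default 64; must be >= 2).
#' @param n_clusters Number of semantic clusters (default 30; must not
#'   exceed `n_nouns`).
#' @param cluster_spread Gaussian spread of tokens around their unit-norm
#'   cluster centroid (default 0.8; smaller values tighten clusters and
#'   raise within-cluster cosines).
#' @param zipf_exponent Exponent of the Zipf rank-frequency law for corpus
#'   frequencies (default 1.1).
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `fixture_config`.
#' @export
fixture_config <- function(n_nouns = 1000L, n_adjectives = 2000L, dim = 64L,
                           n_clusters = 30L, cluster_spread = 0.8,
                           zipf_exponent = 1.1, seed = 1L) {
  stopifnot(is_count(n_nouns, 1L), is_count(n_adjectives, 1L),
            is_count(dim, 2L), is_count(n_clusters, 1L),
            is_scalar_number(cluster_spread), cluster_spread > 0,
            is_scalar_number(zipf_exponent), is_count(abs(seed)))
  if (n_clusters > n_nouns) {
    abort_smst("n_clusters must not exceed n_nouns", "smst_validation_error")
  }
  structure(list(n_nouns = as.integer(n_nouns),
                 n_adjectives = as.integer(n_adjectives),
                 dim = as.integer(dim), n_clusters = as.integer(n_clusters),
                 cluster_spread = cluster_spread,
                 zipf_exponent = zipf_exponent, seed = as.integer(seed)),
            class = "fixture_config")
}

# Pronounceable unique pseudo-tokens built from consonant-vowel syllables.
# Syllable counts are drawn to straddle the 2-6 filter band; character
# counts fall out of the syllable structure and straddle 7-13.
make_tokens <- function(n) {
  consonants <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n",
                  "p", "r", "s", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  tokens <- character(0)
  sylls <- integer(0)
  while (length(tokens) < n) {
    m <- n - length(tokens)
    ns <- sample(1:7, m, replace = TRUE,
                 prob = c(0.05, 0.1, 0.25, 0.3, 0.2, 0.07, 0.03))
    new <- vapply(ns, function(k) {
      paste(vapply(seq_len(k), function(i) {
        syl <- paste0(sample(consonants, 1L), sample(vowels, 1L))
        if (stats::runif(1) < 0.35) syl <- paste0(syl, sample(consonants, 1L))
        syl
      }, character(1L)), collapse = "")
    }, character(1L))
    keep <- !duplicated(new) & !new %in% tokens
    tokens <- c(tokens, new[keep])
    sylls <- c(sylls, ns[keep])
  }
  list(token = tokens, syllables = sylls)
}

#' Generate a synthetic embedding space and matching lexicon
#'
#' Tokens are assigned round-robin to `n_clusters` clusters; each cluster
#' has a random unit-norm centroid and each token's vector is the centroid
#' plus isotropic Gaussian noise of scale `cluster_spread / sqrt(dim)`, so
#' within-cluster cosine similarities stochastically exceed cross-cluster
#' ones (the clustered-neighbourhood structure of real embeddings).
#' Frequencies follow a Zipf law over a random rank permutation; character
#' and syllable counts come from the token generator and straddle the
#' default filter bounds.
#'
#' @param config A [fixture_config()].
#' @return List with `space` (an [embedding_space()]) and `lexicon`
#'   (a tibble passing [validate_lexicon()]).
#' @export
generate_fixture_embedding <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  local_seed_eval(substream_seed(config$seed, "fixture"), {
    pool <- make_tokens(config$n_nouns + config$n_adjectives)
    noun_idx <- seq_len(config$n_nouns)
    nouns <- list(token = pool$token[noun_idx],
                  syllables = pool$syllables[noun_idx])
    adjs <- list(token = pool$token[-noun_idx],
                 syllables = pool$syllables[-noun_idx])
    all_tokens <- pool$token
    n_total <- length(all_tokens)

    centroids <- matrix(stats::rnorm(config$n_clusters * config$dim),
                        config$n_clusters, config$dim)
    centroids <- centroids / sqrt(rowSums(centroids^2))
    cluster <- rep_len(seq_len(config$n_clusters), n_total)
    vectors <- centroids[cluster, , drop = FALSE] +
      matrix(stats::rnorm(n_total * config$dim,
                          sd = config$cluster_spread / sqrt(config$dim)),
             n_total, config$dim)
    rownames(vectors) <- all_tokens
    space <- embedding_space(vectors)

    freq <- function(n) {
      rank <- sample.int(n)
      round(1e6 * rank^(-config$zipf_exponent), 3)
    }
    lexicon <- tibble::tibble(
      token = all_tokens,
      pos = rep(c("noun", "adjective"), c(config$n_nouns, config$n_adjectives)),
      frequency = c(freq(config$n_nouns), freq(config$n_adjectives)),
      char_count = nchar(all_tokens),
      syllable_count = c(nouns$syllables, adjs$syllables)
    )
    list(space = space, lexicon = validate_lexicon(lexicon))
  })
}

#' Write / read a lexicon table as TSV
#'
#' Header `token pos frequency char_count syllable_count`.
#'
#' @param lexicon Lexicon tibble (see [validate_lexicon()]).
#' @param path TSV file path.
#' @return `write_lexicon()` returns `path` invisibly; `read_lexicon()`
#'   the validated tibble.
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(validate_lexicon(lexicon), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  validate_lexicon(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE, quote = ""))
}
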