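# Psycholinguistic lexicon handling: validation, percentile-band frequency
# filtering, and phonological neighbourhood counts.

#' Filter criteria for lexicon selection
#'
#' Bounds applied before stimulus construction: corpus-frequency percentile
#' band (computed within part-of-speech), character count, syllable count,
#' and a cap on phonological neighbourhood density. Defaults mirror the
#' sMST stimulus-selection procedure: frequency between the 35th and 90th
#' percentiles, 7-13 characters, 2-6 syllables, and at most 5 phonological
#' neighbours.
#'
#' @param freq_lo_pct,freq_hi_pct Frequency percentile band (inclusive).
#' @param min_chars,max_chars Character-count bounds (inclusive).
#' @param min_syll,max_syll Syllable-count bounds (inclusive).
#' @param max_phon_neighbors Maximum number of phonological neighbours
#'   (same length, exactly one substituted character).
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(freq_lo_pct = 35, freq_hi_pct = 90,
                            min_chars = 7L, max_chars = 13L,
                            min_syll = 2L, max_syll = 6L,
                            max_phon_neighbors = 5L) {
  stopifnot(is_scalar_number(freq_lo_pct), is_scalar_number(freq_hi_pct),
            is_count(min_chars, 1L), is_count(max_chars, 1L),
            is_count(min_syll, 1L), is_count(max_syll, 1L),
            is_count(max_phon_neighbors, 0L))
  if (freq_lo_pct > freq_hi_pct || min_chars > max_chars || min_syll > max_syll) {
    abort_smst("filter criteria lower bounds must not exceed upper bounds",
               "smst_validation_error")
  }
  if (freq_lo_pct < 0 || freq_hi_pct > 100) {
    abort_smst("frequency percentiles must lie in [0, 100]",
               "smst_validation_error")
  }
  structure(list(freq_lo_pct = freq_lo_pct, freq_hi_pct = freq_hi_pct,
                 min_chars = as.integer(min_chars), max_chars = as.integer(max_chars),
                 min_syll = as.integer(min_syll), max_syll = as.integer(max_syll),
                 max_phon_neighbors = as.integer(max_phon_neighbors)),
            class = "filter_criteria")
}

#' Validate a lexicon table
#'
#' A lexicon is a data frame with columns `token`, `pos` (`"adjective"` or
#' `"noun"`), `frequency` (non-negative corpus count or per-million rate),
#' `char_count` and `syllable_count`. `char_count` must equal the token's
#' character count and syllable counts must be at least 1.
#'
#' @param lexicon Data frame as described above.
#' @return The validated lexicon as a tibble (invisibly usable downstream).
#' @export
validate_lexicon <- function(lexicon) {
  needed <- c("token", "pos", "frequency", "char_count", "syllable_count")
  missing <- setdiff(needed, names(lexicon))
  if (length(missing)) {
    abort_smst(sprintf("lexicon lacks column(s): %s",
                       paste(missing, collapse = ", ")),
               "smst_validation_error")
  }
  lexicon <- tibble::as_tibble(lexicon)
  if (nrow(lexicon) == 0L) {
    abort_smst("lexicon is empty", "smst_validation_error")
  }
  if (!all(lexicon$pos %in% c("adjective", "noun"))) {
    abort_smst("lexicon pos must be 'adjective' or 'noun'",
               "smst_validation_error")
  }
  if (any(lexicon$frequency < 0)) {
    abort_smst("lexicon frequencies must be non-negative", "smst_validation_error")
  }
  if (any(lexicon$char_count != nchar(lexicon$token))) {
    bad <- lexicon$token[which(lexicon$char_count != nchar(lexicon$token))[1L]]
    abort_smst(sprintf("char_count disagrees with token length for '%s'", bad),
               "smst_validation_error")
  }
  if (any(lexicon$syllable_count < 1L)) {
    abort_smst("syllable counts must be >= 1", "smst_validation_error")
  }
  lexicon
}

# Nearest-rank percentile: value at rank ceiling(p/100 * n) of the sorted
# sample (rank 1 when p = 0).
nearest_rank_percentile <- function(x, p) {
  s <- sort(x)
  r <- max(1L, ceiling(p / 100 * length(s)))
  s[[min(r, length(s))]]
}

#' Filter a lexicon by frequency percentile band, length and syllables
#'
#' Keeps entries whose frequency lies within the inclusive
#' `[freq_lo_pct, freq_hi_pct]` percentile band of their own
#' part-of-speech (nearest-rank percentiles), whose character count lies
#' in `[min_chars, max_chars]`, and whose syllable count lies in
#' `[min_syll, max_syll]`. Input order is preserved. Phonological
#' neighbourhood is a separate criterion, applied by
#' [count_phonological_neighbors()] (see [build_stimulus_set()]).
#'
#' @param entries Lexicon data frame (see [validate_lexicon()]).
#' @param criteria A [filter_criteria()].
#' @return The retained rows, order preserved.
#' @export
percentile_band_filter <- function(entries, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  entries <- validate_lexicon(entries)
  keep <- rep(FALSE, nrow(entries))
  for (p in unique(entries$pos)) {
    idx <- which(entries$pos == p)
    f <- entries$frequency[idx]
    lo <- nearest_rank_percentile(f, criteria$freq_lo_pct)
    hi <- nearest_rank_percentile(f, criteria$freq_hi_pct)
    keep[idx] <- f >= lo & f <= hi
  }
  keep <- keep &
    entries$char_count >= criteria$min_chars &
    entries$char_count <= criteria$max_chars &
    entries$syllable_count >= criteria$min_syll &
    entries$syllable_count <= criteria$max_syll
  entries[keep, , drop = FALSE]
}

#' Count phonological neighbours of a word
#'
#' A phonological neighbour is a lexicon word of the same length that
#' differs from `word` in exactly one character position (Hamming distance
#' one; insertions and deletions are not counted). The word itself is never
#' counted.
#'
#' @param word Non-empty token.
#' @param lexicon Character vector of tokens to scan.
#' @return Non-negative integer count.
#' @examples
#' count_phonological_neighbors("alma", c("alfa", "alga", "al", "alma"))
#' @export
count_phonological_neighbors <- function(word, lexicon) {
  stopifnot(is.character(word), length(word) == 1L, nzchar(word))
  if (length(lexicon) == 0L) return(0L)
  cand <- lexicon[nchar(lexicon) == nchar(word) & lexicon != word]
  if (length(cand) == 0L) return(0L)
  w <- strsplit(word, "")[[1L]]
  sum(vapply(strsplit(cand, ""), function(ch) sum(ch != w) == 1L, logical(1L)))
}

# Phonological neighbour counts for every token at once (same rule as
# count_phonological_neighbors); used when screening whole lexica.
phonological_neighbor_counts <- function(tokens) {
  counts <- integer(length(tokens))
  names(counts) <- NULL
  by_len <- split(seq_along(tokens), nchar(tokens))
  for (idx in by_len) {
    n <- length(idx)
    if (n < 2L) next
    chars <- do.call(rbind, strsplit(tokens[idx], ""))
    d <- matrix(0L, n, n)
    for (j in seq_len(ncol(chars))) {
      d <- d + outer(chars[, j], chars[, j], `!=`)
    }
    # distance 0 with a distinct index means a duplicate token, not a neighbour
    counts[idx] <- rowSums(d == 1L)
  }
  counts
}
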