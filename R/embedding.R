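# Word-embedding container, word2vec I/O, and phrase-level cosine similarity.
#
# Phrases are represented throughout as length-2 character vectors
# c(adjective, noun); `phrase()` builds and validates one.

#' Construct an embedding space from a token-by-dimension matrix
#'
#' An `embedding_space` maps tokens to dense real vectors of a common
#' dimensionality and backs every similarity computation in the package.
#' Validation enforces the invariants that cosine similarity relies on:
#' unique non-empty tokens, finite components, and no (near-)zero vectors.
#'
#' @param vectors Numeric matrix, one row per token; rownames are the tokens.
#' @return An object of class `embedding_space`.
#' @examples
#' m <- rbind(sun = c(1, 0), moon = c(0.9, 0.1))
#' space <- embedding_space(m)
#' embedding_dim(space)
#' @export
embedding_space <- function(vectors) {
  if (!is.matrix(vectors) || !is.numeric(vectors)) {
    abort_smst("`vectors` must be a numeric matrix with tokens as rownames",
               "smst_validation_error")
  }
  tokens <- rownames(vectors)
  if (is.null(tokens) || any(!nzchar(tokens))) {
    abort_smst("every row must be named by a non-empty token",
               "smst_validation_error")
  }
  if (anyDuplicated(tokens)) {
    dup <- tokens[duplicated(tokens)][1L]
    abort_smst(sprintf("duplicate token '%s' in embedding", dup),
               "smst_duplicate_token_error")
  }
  if (!all(is.finite(vectors))) {
    abort_smst("embedding vectors must be finite", "smst_validation_error")
  }
  norms <- sqrt(rowSums(vectors^2))
  if (any(norms < 1e-12)) {
    bad <- tokens[which(norms < 1e-12)[1L]]
    abort_smst(
      sprintf("token '%s' has a (near-)zero vector; cosine similarity undefined", bad),
      "smst_validation_error"
    )
  }
  structure(list(vectors = vectors, dim = ncol(vectors)),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space: %d tokens, dim %d>\n",
              nrow(x$vectors), x$dim))
  invisible(x)
}

#' @rdname embedding_space
#' @param space An `embedding_space`.
#' @export
embedding_dim <- function(space) {
  stopifnot(inherits(space, "embedding_space"))
  space$dim
}

#' @rdname embedding_space
#' @export
embedding_tokens <- function(space) {
  stopifnot(inherits(space, "embedding_space"))
  rownames(space$vectors)
}

#' Look up the vector of one token
#'
#' @param space An `embedding_space`.
#' @param token Token to look up.
#' @return Numeric vector of length `embedding_dim(space)`.
#' @export
embedding_vector <- function(space, token) {
  stopifnot(inherits(space, "embedding_space"),
            is.character(token), length(token) == 1L)
  if (!token %in% rownames(space$vectors)) {
    abort_smst(sprintf("token '%s' not present in embedding", token),
               "smst_lookup_error")
  }
  space$vectors[token, ]
}

#' An adjective-noun phrase
#'
#' @param adjective,noun Non-empty tokens; must differ.
#' @return Length-2 named character vector `c(adjective=, noun=)`.
#' @examples
#' phrase("exotic", "zoo")
#' @export
phrase <- function(adjective, noun) {
  stopifnot(is.character(adjective), length(adjective) == 1L,
            is.character(noun), length(noun) == 1L)
  if (!nzchar(adjective) || !nzchar(noun)) {
    abort_smst("phrase tokens must be non-empty", "smst_validation_error")
  }
  if (identical(adjective, noun)) {
    abort_smst("phrase adjective and noun must differ", "smst_validation_error")
  }
  c(adjective = adjective, noun = noun)
}

#' Read word2vec embeddings
#'
#' Reads the two de-facto word2vec serialisations: the text dialect
#' (header line `"<count> <dim>"`, then one `"<token> <v1> ... <vdim>"`
#' line per token, whitespace-separated, UTF-8) and the binary dialect
#' (same ASCII header, then per token the token bytes terminated by a
#' space followed by `dim` little-endian 32-bit floats).
#'
#' @param path Path to the embedding file.
#' @param dialect `"text"` or `"binary"`.
#' @return An [embedding_space()].
#' @seealso [write_word2vec()]
#' @export
read_word2vec <- function(path, dialect = c("text", "binary")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_smst(sprintf("embedding file '%s' does not exist", path),
               "smst_format_error")
  }
  if (dialect == "text") read_word2vec_text(path) else read_word2vec_binary(path)
}

read_word2vec_text <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) {
    abort_smst("empty embedding file", "smst_format_error")
  }
  header <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  has_header <- length(header) == 2L &&
    !anyNA(suppressWarnings(as.numeric(header)))
  if (has_header) {
    n <- as.numeric(header[[1L]])
    dim <- as.numeric(header[[2L]])
    body <- lines[-1L]
    if (length(body) != n) {
      abort_smst(sprintf("header declares %d tokens but file has %d rows",
                         n, length(body)), "smst_format_error")
    }
  } else {
    body <- lines
    dim <- NA_real_
  }
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    abort_smst("embedding file has no vector rows", "smst_format_error")
  }
  fields <- strsplit(trimws(body), "[[:space:]]+")
  widths <- lengths(fields)
  if (is.na(dim)) dim <- widths[[1L]] - 1L
  if (dim < 1L) {
    abort_smst("malformed header: dimensionality must be positive",
               "smst_format_error")
  }
  bad <- which(widths != dim + 1L)
  if (length(bad)) {
    abort_smst(
      sprintf("line %d has %d components, expected %d",
              bad[[1L]] + as.integer(has_header), widths[[bad[[1L]]]] - 1L, dim),
      "smst_format_error"
    )
  }
  tokens <- vapply(fields, `[[`, character(1L), 1L)
  values <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(dim))
  )
  if (anyNA(values)) {
    abort_smst("non-numeric vector component in embedding file",
               "smst_format_error")
  }
  mat <- if (dim == 1L) matrix(values, ncol = 1L) else t(values)
  rownames(mat) <- tokens
  embedding_space(mat)
}

read_word2vec_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) abort_smst("truncated binary header", "smst_format_error")
    if (ch == "\n") break
    header <- c(header, ch)
  }
  header <- strsplit(trimws(paste(header, collapse = "")), "[[:space:]]+")[[1L]]
  if (length(header) != 2L || anyNA(suppressWarnings(as.numeric(header)))) {
    abort_smst("malformed binary header, expected '<count> <dim>'",
               "smst_format_error")
  }
  n <- as.integer(header[[1L]])
  dim <- as.integer(header[[2L]])
  if (n < 1L || dim < 1L) {
    abort_smst("malformed binary header: counts must be positive",
               "smst_format_error")
  }
  mat <- matrix(NA_real_, n, dim)
  tokens <- character(n)
  for (i in seq_len(n)) {
    tok <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0L) abort_smst("truncated binary record", "smst_format_error")
      if (b == as.raw(0x20)) break
      if (b == as.raw(0x0a) && length(tok) == 0L) next # skip record separator
      tok <- c(tok, b)
    }
    tokens[[i]] <- rawToChar(tok)
    v <- readBin(con, "numeric", n = dim, size = 4L, endian = "little")
    if (length(v) != dim) abort_smst("truncated binary record", "smst_format_error")
    mat[i, ] <- v
  }
  rownames(mat) <- tokens
  embedding_space(mat)
}

#' Write word2vec embeddings
#'
#' @inheritParams read_word2vec
#' @param space An [embedding_space()].
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(space, path, dialect = c("text", "binary")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(space, "embedding_space"))
  mat <- space$vectors
  if (dialect == "text") {
    rows <- vapply(seq_len(nrow(mat)), function(i) {
      paste(c(rownames(mat)[i], format(mat[i, ], digits = 17, trim = TRUE,
                                       scientific = FALSE)),
            collapse = " ")
    }, character(1L))
    writeLines(c(sprintf("%d %d", nrow(mat), ncol(mat)), rows), path,
               useBytes = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("%d %d\n", nrow(mat), ncol(mat)), con, eos = NULL)
    for (i in seq_len(nrow(mat))) {
      writeChar(paste0(rownames(mat)[i], " "), con, eos = NULL)
      writeBin(as.numeric(mat[i, ]), con, size = 4L, endian = "little")
      writeChar("\n", con, eos = NULL)
    }
  }
  invisible(path)
}

#' Cosine similarity of two vectors
#'
#' Returns `sum(a * b) / (||a|| ||b||)`, the cosine of the angle between
#' `a` and `b`; symmetric, invariant to positive rescaling, and bounded in
#' `[-1, 1]`.
#'
#' @param a,b Numeric vectors of equal length with non-zero norm.
#' @return A number in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 1), c(1, 0)) # 1/sqrt(2)
#' @export
cosine_similarity <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || !all(is.finite(a)) || !all(is.finite(b))) {
    abort_smst("cosine similarity requires finite numeric vectors",
               "smst_validation_error")
  }
  if (length(a) != length(b)) {
    abort_smst(sprintf("vector lengths differ (%d vs %d)", length(a), length(b)),
               "smst_dimension_error")
  }
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12) {
    abort_smst("cosine similarity undefined for zero-norm vectors",
               "smst_undefined_similarity_error")
  }
  sum(a * b) / (na * nb)
}

#' Compound vector of an adjective-noun phrase
#'
#' The phrase meaning is represented as the component-wise sum of the
#' adjective and noun vectors (no normalisation before summing).
#'
#' @param space An [embedding_space()].
#' @param phrase Length-2 character vector `c(adjective, noun)`; see [phrase()].
#' @return Numeric vector of length `embedding_dim(space)`.
#' @examples
#' m <- rbind(red = c(1, 0), car = c(0, 1))
#' compound_vector(embedding_space(m), phrase("red", "car"))
#' @export
compound_vector <- function(space, phrase) {
  stopifnot(is.character(phrase), length(phrase) == 2L)
  embedding_vector(space, phrase[[1L]]) + embedding_vector(space, phrase[[2L]])
}

#' Cosine similarity between two phrases
#'
#' Cosine similarity of the two phrases' compound vectors; this is the
#' semantic-similarity measure that defines the close/distant lure bands.
#'
#' @param space An [embedding_space()].
#' @param p1,p2 Phrases (length-2 character vectors, see [phrase()]).
#' @return A number in `[-1, 1]`.
#' @export
phrase_similarity <- function(space, p1, p2) {
  cosine_similarity(compound_vector(space, p1), compound_vector(space, p2))
}

# Vectorised phrase similarity of many (adjective, noun) rows against one
# reference compound vector. Internal fast path for stimulus construction.
phrase_similarity_many <- function(space, adjectives, noun, ref_compound) {
  mat <- space$vectors[adjectives, , drop = FALSE]
  comp <- sweep(mat, 2L, space$vectors[noun, ], `+`)
  num <- as.numeric(comp %*% ref_compound)
  den <- sqrt(rowSums(comp^2)) * sqrt(sum(ref_compound^2))
  unname(num / den)
}

# Vectorised token-token cosine: each of `tokens` against one `ref` token.
token_cosine_many <- function(space, tokens, ref) {
  mat <- space$vectors[tokens, , drop = FALSE]
  v <- space$vectors[ref, ]
  unname(as.numeric(mat %*% v) / (sqrt(rowSums(mat^2)) * sqrt(sum(v^2))))
}
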