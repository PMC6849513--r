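# Pseudopattern lexicon: phoneme inventory, word forms, visual referents,
# localist semantics, and the two distributional categories.

#' Build the phoneme inventory
#'
#' Enumerates all binary patterns of length 5 with exactly 2 active units.
#' There are exactly `choose(5, 2) = 10` such patterns, so the inventory is
#' the complete combination set, returned in randomized order (consuming the
#' current RNG stream).
#'
#' @return A 10 x 5 binary matrix, one phoneme per row; each row sums to 2.
#' @examples
#' set.seed(1)
#' inv <- phoneme_inventory()
#' rowSums(inv)  # all 2
#' @export
phoneme_inventory <- function() {
  pairs <- utils::combn(5L, 2L)
  inv <- matrix(0L, nrow = ncol(pairs), ncol = 5L)
  for (i in seq_len(ncol(pairs))) inv[i, pairs[, i]] <- 1L
  inv[sample.int(nrow(inv)), , drop = FALSE]
}

#' Sample one word form
#'
#' A word form is the concatenation of 4 phonemes drawn uniformly with
#' replacement from the inventory, giving a length-20 binary vector with
#' exactly 8 active units (2 per contiguous 5-unit block).
#'
#' @param inventory A phoneme inventory matrix from [phoneme_inventory()].
#' @return Integer vector of length 20 with 8 active entries.
#' @export
word_form <- function(inventory) {
  stopifnot(is.matrix(inventory), ncol(inventory) == 5L)
  idx <- sample.int(nrow(inventory), 4L, replace = TRUE)
  as.integer(t(inventory[idx, , drop = FALSE]))
}

#' Sample one visual referent pattern
#'
#' @return Integer vector of length 20 with exactly 8 active units, chosen
#'   uniformly among all 8-of-20 patterns.
#' @export
visual_pattern <- function() {
  v <- integer(20L)
  v[sample.int(20L, 8L)] <- 1L
  v
}

#' Generate a lexicon of pseudopattern words
#'
#' Each word has a phonological form (4 phonemes, 20 units, 8 active), a
#' visual referent (8-of-20 pattern) and a localist semantic index equal to
#' its position. Forms and referents are resampled on collision until all are
#' pairwise distinct. Half of the words are assigned to category `"A"` and
#' half to `"B"` by a random permutation; the categories ground the
#' distributional cue.
#'
#' @param n_words Even number of words (default 100).
#' @param seed Integer seed; the lexicon is a pure function of it.
#' @return An object of class `"lexicon"`: a list with `forms` and
#'   `referents` (`n_words` x 20 binary matrices), `category` (character
#'   vector of `"A"`/`"B"`), `inventory`, `n_words`, and `seed`.
#' @examples
#' lex <- build_lexicon(10, seed = 42)
#' table(lex$category)
#' @export
build_lexicon <- function(n_words = 100L, seed) {
  n_words <- as.integer(n_words)
  if (n_words < 2L || n_words %% 2L != 0L)
    stop("n_words must be an even integer >= 2")
  if (n_words > 10000L)  # 10^4 distinct 4-phoneme sequences
    stop("n_words exceeds the number of distinct word forms available")
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))

  inv <- phoneme_inventory()
  forms <- .sample_unique(n_words, function() word_form(inv))
  referents <- .sample_unique(n_words, visual_pattern)
  category <- rep("B", n_words)
  category[sample.int(n_words)[seq_len(n_words %/% 2L)]] <- "A"

  structure(
    list(forms = forms, referents = referents, category = category,
         inventory = inv, n_words = n_words, seed = as.integer(seed)),
    class = "lexicon")
}

# Draw n distinct length-20 patterns, resampling on collision.
.sample_unique <- function(n, draw, max_tries = 1000L * n) {
  out <- matrix(NA_integer_, nrow = n, ncol = 20L)
  keys <- character(n)
  i <- 1L
  tries <- 0L
  while (i <= n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not generate ", n, " distinct patterns")
    v <- draw()
    k <- paste(v, collapse = "")
    if (!k %in% keys[seq_len(i - 1L)]) {
      out[i, ] <- v
      keys[i] <- k
      i <- i + 1L
    }
  }
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Validate lexicon invariants
#'
#' Asserts every structural invariant of a lexicon: pattern shapes and
#' sparsity (8 active units per form and per referent, 2 per phoneme block),
#' pairwise distinctness of forms and of referents, and the exact 50/50
#' category split.
#'
#' @param lex A `"lexicon"` object.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_lexicon <- function(lex) {
  stopifnot(inherits(lex, "lexicon"))
  n <- lex$n_words
  if (nrow(lex$forms) != n || nrow(lex$referents) != n)
    stop("pattern matrices do not match n_words")
  if (!all(rowSums(lex$forms) == 8L))
    stop("every form must have exactly 8 active units")
  block <- rep(1:4, each = 5L)
  for (b in 1:4)
    if (!all(rowSums(lex$forms[, block == b, drop = FALSE]) == 2L))
      stop("every phoneme block must have exactly 2 active units")
  if (!all(rowSums(lex$referents) == 8L))
    stop("every referent must have exactly 8 active units")
  if (anyDuplicated(apply(lex$forms, 1L, paste, collapse = "")))
    stop("word forms must be pairwise distinct")
  if (anyDuplicated(apply(lex$referents, 1L, paste, collapse = "")))
    stop("referents must be pairwise distinct")
  if (sum(lex$category == "A") != n %/% 2L ||
      sum(lex$category == "B") != n %/% 2L)
    stop("categories must split the lexicon 50/50")
  if (nrow(lex$inventory) != 10L || !all(rowSums(lex$inventory) == 2L) ||
      anyDuplicated(apply(lex$inventory, 1L, paste, collapse = "")))
    stop("inventory must hold the 10 distinct 2-of-5 phonemes")
  invisible(TRUE)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("Lexicon: %d words (seed %d), %d/%d in categories A/B\n",
              x$n_words, x$seed,
              sum(x$category == "A"), sum(x$category == "B")))
  invisible(x)
}

#' Serialize a lexicon to JSON
#'
#' Writes the seed, the phoneme inventory, the active-unit indices of every
#' form and referent, and the category labels, so a run can be audited and
#' replayed.
#'
#' @param lex A `"lexicon"` object.
#' @param path File path to write; `NULL` returns the JSON string.
#' @return The path (or the JSON string), invisibly.
#' @export
lexicon_to_json <- function(lex, path = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  doc <- list(
    seed = lex$seed,
    n_words = lex$n_words,
    inventory = apply(lex$inventory, 1L, function(r) which(r == 1L),
                      simplify = FALSE),
    forms = apply(lex$forms, 1L, function(r) which(r == 1L),
                  simplify = FALSE),
    referents = apply(lex$referents, 1L, function(r) which(r == 1L),
                      simplify = FALSE),
    category = lex$category)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(txt)))
  writeLines(txt, path)
  invisible(path)
}

#' Read a lexicon back from its JSON serialization
#'
#' @param path Path to a file written by [lexicon_to_json()].
#' @return A `"lexicon"` object identical to the one serialized.
#' @export
lexicon_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  n <- doc$n_words
  unpack <- function(lst, ncol) {
    m <- matrix(0L, nrow = length(lst), ncol = ncol)
    for (i in seq_along(lst)) m[i, unlist(lst[[i]])] <- 1L
    m
  }
  structure(
    list(forms = unpack(doc$forms, 20L),
         referents = unpack(doc$referents, 20L),
         category = unlist(doc$category),
         inventory = unpack(doc$inventory, 5L),
         n_words = as.integer(n),
         seed = as.integer(doc$seed)),
    class = "lexicon")
}
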