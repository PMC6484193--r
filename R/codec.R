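#' Localist slot encoding of a spelling
#'
#' A word is represented as 4 positional slots; each non-blank slot
#' activates exactly one unit in its block of `n_letters` units, so the
#' input vector has `4 * n_letters` units (132 for the 33-letter alphabet).
#' Unit ordering is slot-major: unit `(s - 1) * n_letters + l` codes
#' letter `l` in slot `s` (1-based).  Blank slots leave their block at
#' zero; there is no dedicated blank unit.
#'
#' @param spelling Integer vector of length 4; letter indices in
#'   `1..n_letters`, `NA` for blank.  At least one slot must be non-blank.
#' @param n_letters Alphabet size (default 33).
#' @return Binary numeric vector of length `4 * n_letters`.
#' @export
encode_orthography <- function(spelling, n_letters = 33L) {
  .encode_slots(spelling, n_letters)
}

#' Localist slot encoding of a pronunciation
#'
#' Same scheme as [encode_orthography()] over the phoneme alphabet:
#' `4 * n_phonemes` units (112 for the 28-phoneme alphabet).
#'
#' @param pronunciation Integer vector of length 4; phoneme indices in
#'   `1..n_phonemes`, `NA` for blank.
#' @param n_phonemes Alphabet size (default 28).
#' @return Binary numeric vector of length `4 * n_phonemes`.
#' @export
encode_phonology <- function(pronunciation, n_phonemes = 28L) {
  .encode_slots(pronunciation, n_phonemes)
}

.encode_slots <- function(symbols, n_symbols) {
  if (length(symbols) != 4L)
    stop("a word has exactly 4 slots")
  if (all(is.na(symbols)))
    stop("at least one slot must be non-blank")
  if (any(symbols < 1L | symbols > n_symbols, na.rm = TRUE))
    stop("slot symbol outside alphabet range 1..", n_symbols)
  v <- numeric(4L * n_symbols)
  v[.active_units(symbols, n_symbols)] <- 1
  v
}

# 1-based unit indices of the active units (used by the training fast path)
.active_units <- function(symbols, n_symbols) {
  s <- which(!is.na(symbols))
  (s - 1L) * n_symbols + symbols[s]
}

#' Decode a phonological output vector
#'
#' Reads the network's real-valued output back into 4 slot phonemes: in
#' each block of `n_phonemes` units, a maximum activation below 0.5
#' decodes to blank (`NA`), otherwise to the argmax phoneme, ties broken
#' by the lowest index.  The 0.5 threshold matches the 0/1 logistic
#' targets.
#'
#' @param output Numeric vector whose length is a multiple of
#'   `n_phonemes` (4 blocks for a whole word).
#' @param n_phonemes Alphabet size (default 28).
#' @return Integer vector of one phoneme index (or `NA`) per block.
#' @export
decode_phonology <- function(output, n_phonemes = 28L) {
  if (length(output) %% n_phonemes != 0L)
    stop("output length must be a multiple of n_phonemes")
  n_slots <- length(output) %/% n_phonemes
  vapply(seq_len(n_slots), function(s) {
    block <- output[((s - 1L) * n_phonemes + 1L):(s * n_phonemes)]
    if (max(block) < 0.5) NA_integer_ else which.max(block)
  }, integer(1))
}

# Encode every lexicon item once: active input-unit indices per item plus
# the dense target matrix (items in rows).  Shared by training and scoring.
.encode_lexicon <- function(lexicon, n_letters, n_phonemes) {
  n <- nrow(lexicon)
  x_idx <- vector("list", n)
  targets <- matrix(0, nrow = n, ncol = 4L * n_phonemes)
  for (i in seq_len(n)) {
    sp <- item_spelling(lexicon, i)
    pr <- item_pronunciation(lexicon, i)
    if (all(is.na(sp)) || all(is.na(pr)))
      stop("item ", lexicon$word_id[i], " has no non-blank slots")
    if (any(sp > n_letters, na.rm = TRUE) || any(pr > n_phonemes, na.rm = TRUE))
      stop("item ", lexicon$word_id[i], " uses symbols outside the alphabets")
    x_idx[[i]] <- .active_units(sp, n_letters)
    targets[i, .active_units(pr, n_phonemes)] <- 1
  }
  list(x_idx = x_idx, targets = targets,
       n_in = 4L * n_letters, n_out = 4L * n_phonemes)
}
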