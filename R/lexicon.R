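#' Configuration for synthetic lexicon generation
#'
#' Describes an artificial lexicon with the statistical structure of a
#' graded primary-school vocabulary: words are grouped by the school grade
#' at which they first appear, carry an integer presentation frequency, and
#' map a 4-slot spelling onto a 4-slot pronunciation.
#'
#' Slots carry positional (onset/body/coda) semantics: slots 1-2 hold onset
#' letters (slot 2 may be blank), slot 3 the vowel/body (always present),
#' slot 4 an optional coda.  In `quasi_regular` mode each letter maps to a
#' phoneme through a per-slot rule table; a fraction `inconsistency_rate`
#' of items deviate from the rule in the body/rime slots (3-4), giving the
#' mostly-rule-governed-with-exceptions structure of a deep orthography.
#' In `arbitrary` mode pronunciations are drawn independently of spellings,
#' emulating the unstructured random pattern sets of earlier modelling work.
#'
#' @param group_sizes Named integer vector, grade label -> word count.
#'   Defaults to the five-grade design 82/62/56/49/78 (327 words).
#' @param n_letters Letter alphabet size (default 33).
#' @param n_phonemes Phoneme alphabet size (default 28).
#' @param mapping_mode `"quasi_regular"` or `"arbitrary"`.
#' @param inconsistency_rate Fraction in \[0,1\] of items whose body->rime
#'   mapping deviates from the rule table (quasi-regular mode only).
#' @param frequency_prob Success probability of the geometric frequency
#'   draw; frequency = 1 + Geom(p), so most words have frequency 1-3.
#'   The same distribution is used in every grade, keeping frequency and
#'   grade unconfounded by default.
#' @param onset2_prob Probability that slot 2 (second onset letter) is
#'   occupied.
#' @param coda_prob Probability that slot 4 (coda) is occupied.
#' @param seed Integer seed; the same config and seed reproduce the lexicon
#'   exactly.
#' @return An object of class `lexicon_config` (a named list).
#' @export
lexicon_config <- function(group_sizes = c("1" = 82, "2" = 62, "3" = 56,
                                           "4" = 49, "5" = 78),
                           n_letters = 33L,
                           n_phonemes = 28L,
                           mapping_mode = c("quasi_regular", "arbitrary"),
                           inconsistency_rate = 0.2,
                           frequency_prob = 0.5,
                           onset2_prob = 0.5,
                           coda_prob = 0.7,
                           seed = 1L) {
  mapping_mode <- match.arg(mapping_mode)
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes))))
    stop("group_sizes must be a named vector (names are grade labels)")
  if (any(group_sizes < 1))
    stop("group_sizes must all be >= 1")
  if (n_letters < 2L || n_phonemes < 2L)
    stop("alphabets need at least 2 symbols")
  if (inconsistency_rate < 0 || inconsistency_rate > 1)
    stop("inconsistency_rate must lie in [0, 1]")
  if (frequency_prob <= 0 || frequency_prob > 1)
    stop("frequency_prob must lie in (0, 1]")
  structure(list(group_sizes = as.integer(group_sizes) |>
                   stats::setNames(names(group_sizes)),
                 n_letters = as.integer(n_letters),
                 n_phonemes = as.integer(n_phonemes),
                 mapping_mode = mapping_mode,
                 inconsistency_rate = inconsistency_rate,
                 frequency_prob = frequency_prob,
                 onset2_prob = onset2_prob,
                 coda_prob = coda_prob,
                 seed = as.integer(seed)),
            class = "lexicon_config")
}

#' Generate a synthetic lexicon
#'
#' Draws `sum(config$group_sizes)` words with unique spellings, per-grade
#' counts exactly as configured, geometric-like integer frequencies, and
#' pronunciations that follow the per-slot rule table (quasi-regular mode)
#' or are independent of the spelling (arbitrary mode).  The neighbourhood
#' consistency column is filled by [compute_consistency()].
#'
#' @param config A [lexicon_config()].
#' @return A `data.frame` of class `aoa_lexicon` with columns `word_id`,
#'   `slot1`..`slot4` (letter indices 1..n_letters, `NA` = blank),
#'   `pslot1`..`pslot4` (phoneme indices, `NA` = blank), `grade`,
#'   `frequency`, `consistency`.  The per-slot letter->phoneme rule table
#'   is attached as attribute `rule_table` (4 x n_letters matrix) and the
#'   generating config as attribute `config`.
#' @export
generate_lexicon <- function(config = lexicon_config()) {
  stopifnot(inherits(config, "lexicon_config"))
  withr::with_seed(config$seed, .generate_lexicon_impl(config))
}

.generate_lexicon_impl <- function(config) {
  n_total <- sum(config$group_sizes)
  nl <- config$n_letters
  np <- config$n_phonemes

  # deterministic per-slot letter -> phoneme correspondence
  rule <- matrix(0L, nrow = 4L, ncol = nl)
  for (s in 1:4) rule[s, ] <- sample.int(np, nl, replace = TRUE)

  # draw unique spellings; capacity check guards tiny test alphabets
  spell <- matrix(NA_integer_, nrow = n_total, ncol = 4L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  capacity <- nl * (nl + 1) * nl * (nl + 1)
  if (n_total > capacity)
    stop("requested ", n_total, " words but the slot structure over ",
         nl, " letters admits at most ", capacity, " distinct spellings")
  tries <- 0L
  max_tries <- 1000L * n_total
  i <- 1L
  while (i <= n_total) {
    s1 <- sample.int(nl, 1L)
    s2 <- if (stats::runif(1) < config$onset2_prob) sample.int(nl, 1L) else NA_integer_
    s3 <- sample.int(nl, 1L)
    s4 <- if (stats::runif(1) < config$coda_prob) sample.int(nl, 1L) else NA_integer_
    key <- paste(s1, s2, s3, s4, sep = ".")
    tries <- tries + 1L
    if (tries > max_tries)
      stop("could not draw ", n_total,
           " unique spellings; alphabet capacity exhausted")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    spell[i, ] <- c(s1, s2, s3, s4)
    i <- i + 1L
  }

  # pronunciations
  pron <- matrix(NA_integer_, nrow = n_total, ncol = 4L)
  if (config$mapping_mode == "quasi_regular") {
    for (s in 1:4) {
      has <- !is.na(spell[, s])
      pron[has, s] <- rule[s, spell[has, s]]
    }
    exception <- stats::runif(n_total) < config$inconsistency_rate
    for (s in 3:4) {                      # deviation confined to body/rime
      idx <- which(exception & !is.na(spell[, s]))
      for (j in idx) {
        regular <- rule[s, spell[j, s]]
        pron[j, s] <- sample(setdiff(seq_len(np), regular), 1L)
      }
    }
  } else {
    for (s in 1:4) {
      has <- !is.na(spell[, s])
      pron[has, s] <- sample.int(np, sum(has), replace = TRUE)
    }
    exception <- rep(FALSE, n_total)
  }

  grade <- rep(names(config$group_sizes), times = config$group_sizes)
  frequency <- 1L + stats::rgeom(n_total, prob = config$frequency_prob)

  lex <- data.frame(
    word_id = sprintf("g%s_w%03d", grade,
                      unlist(lapply(config$group_sizes, seq_len))),
    slot1 = spell[, 1], slot2 = spell[, 2],
    slot3 = spell[, 3], slot4 = spell[, 4],
    pslot1 = pron[, 1], pslot2 = pron[, 2],
    pslot3 = pron[, 3], pslot4 = pron[, 4],
    grade = as.integer(grade),
    frequency = frequency,
    consistency = NA_integer_,
    stringsAsFactors = FALSE
  )
  lex$is_exception <- exception
  class(lex) <- c("aoa_lexicon", "data.frame")
  attr(lex, "rule_table") <- rule
  attr(lex, "config") <- config
  compute_consistency(lex)
}

#' Slot-level neighbourhood consistency (Coltheart-N analogue)
#'
#' For each word, counts the other words in the lexicon whose spelling
#' differs in exactly one slot (blank counts as a slot value).  The
#' relation is symmetric, so the column sums to an even number.
#'
#' @param lexicon An `aoa_lexicon`.
#' @return The lexicon with its `consistency` column recomputed.
#' @export
compute_consistency <- function(lexicon) {
  stopifnot(nrow(lexicon) >= 1L)
  s <- as.matrix(lexicon[, c("slot1", "slot2", "slot3", "slot4")])
  s[is.na(s)] <- 0L                       # blank treated as its own symbol
  n <- nrow(s)
  ndiff <- matrix(0L, n, n)
  for (k in 1:4) ndiff <- ndiff + outer(s[, k], s[, k], "!=")
  lexicon$consistency <- as.integer(rowSums(ndiff == 1L))
  lexicon
}

#' Write / read a lexicon as CSV
#'
#' Plain UTF-8 CSV with header `word_id,slot1..slot4,pslot1..pslot4,
#' grade,frequency,consistency`; blanks are written as `"-"`, letter and
#' phoneme indices are 1-based integers.
#'
#' @param lexicon An `aoa_lexicon`.
#' @param path File path.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon`
#'   returns an `aoa_lexicon`.
#' @export
write_lexicon <- function(lexicon, path) {
  cols <- c("word_id", paste0("slot", 1:4), paste0("pslot", 1:4),
            "grade", "frequency", "consistency")
  out <- lexicon[, cols]
  for (cl in c(paste0("slot", 1:4), paste0("pslot", 1:4))) {
    v <- as.character(out[[cl]])
    v[is.na(v)] <- "-"
    out[[cl]] <- v
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character",
                         fileEncoding = "UTF-8")
  for (cl in c(paste0("slot", 1:4), paste0("pslot", 1:4))) {
    v <- raw[[cl]]
    v[v == "-"] <- NA_character_
    raw[[cl]] <- as.integer(v)
  }
  raw$grade <- as.integer(raw$grade)
  raw$frequency <- as.integer(raw$frequency)
  raw$consistency <- as.integer(raw$consistency)
  class(raw) <- c("aoa_lexicon", "data.frame")
  raw
}

# spelling / pronunciation of row i as a length-4 integer vector (NA = blank)
item_spelling <- function(lexicon, i) {
  as.integer(lexicon[i, c("slot1", "slot2", "slot3", "slot4")])
}

item_pronunciation <- function(lexicon, i) {
  as.integer(lexicon[i, c("pslot1", "pslot2", "pslot3", "pslot4")])
}
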