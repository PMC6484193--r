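# Small fixtures built in code, shared across test files.

# a hand-specified lexicon; spellings/pronunciations given as length-4
# integer vectors with NA for blank slots
make_lexicon <- function(spellings, pronunciations,
                         grade = rep(1L, length(spellings)),
                         frequency = rep(1L, length(spellings)),
                         n_letters = 33L, n_phonemes = 28L) {
  sp <- do.call(rbind, spellings)
  pr <- do.call(rbind, pronunciations)
  lex <- data.frame(
    word_id = sprintf("w%03d", seq_along(spellings)),
    slot1 = sp[, 1], slot2 = sp[, 2], slot3 = sp[, 3], slot4 = sp[, 4],
    pslot1 = pr[, 1], pslot2 = pr[, 2], pslot3 = pr[, 3], pslot4 = pr[, 4],
    grade = as.integer(grade), frequency = as.integer(frequency),
    consistency = NA_integer_, stringsAsFactors = FALSE)
  class(lex) <- c("aoa_lexicon", "data.frame")
  attr(lex, "config") <- lexicon_config(
    group_sizes = stats::setNames(as.integer(table(grade)),
                                  names(table(grade))),
    n_letters = n_letters, n_phonemes = n_phonemes)
  compute_consistency(lex)
}

# a random small lexicon through the generator itself
small_lexicon <- function(n1 = 5L, n2 = 5L, seed = 1L, ...) {
  generate_lexicon(lexicon_config(group_sizes = c("1" = n1, "2" = n2),
                                  seed = seed, ...))
}

# random small network with arbitrary sizes
toy_net <- function(n_in = 3L, n_hidden = 4L, n_out = 2L, seed = 1L) {
  init_network(n_in, n_hidden, n_out, init_range = 0.5, seed = seed)
}

# central-difference gradient of E = 0.5 * sum((o - t)^2) wrt every
# weight and bias; independent of the backprop path
numeric_grads <- function(net, x, target, h = 1e-5) {
  E <- function(nn) 0.5 * sum((forward(nn, x)$output - target)^2)
  out <- list()
  for (nm in c("W_ih", "b_h", "W_ho", "b_o")) {
    gr <- net[[nm]]
    for (i in seq_along(gr)) {
      np <- net; np[[nm]][i] <- np[[nm]][i] + h
      nm2 <- net; nm2[[nm]][i] <- nm2[[nm]][i] - h
      gr[i] <- (E(np) - E(nm2)) / (2 * h)
    }
    out[[nm]] <- gr
  }
  out
}

# plug-in mutual information (bits) between two discrete vectors
plugin_mi <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / outer(pa, pb)[keep]))
}
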