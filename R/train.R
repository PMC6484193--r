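#' Build a staged training protocol
#'
#' Constructs one of the seven canonical simulation protocols over a
#' lexicon, or a custom protocol.  The canonical designs contrast words
#' acquired early (grade-1 group) with words acquired late (grade-2
#' group):
#'
#' * `sim1` - focused stage (early words, 150 epochs), then interleaved
#'   stage (early x1 + late x2, 150 epochs); lr 0.01, momentum 0.9.
#'   The late words are presented twice per epoch so that, over the whole
#'   protocol, every item totals 300 presentations (frequency
#'   equalisation).
#' * `sim2` - as `sim1` but the interleaved stage runs twice as long
#'   (300 epochs): persistence of the early advantage under continued
#'   interleaved training.
#' * `sim3` - order-reversal control: the late group is trained first and
#'   the early group is the newcomer (with multiplicity 2).
#' * `sim4` - `sim1` structure with doubled epochs (300 + 300) and
#'   lr 0.05.
#' * `sim5` - no-momentum control: momentum 0, lr 0.05, 1500 + 1500
#'   epochs.
#' * `sim6` - identical training to `sim1`; the lesioning experiment
#'   ([run_lesion_experiment()]) is applied to the trained network.
#' * `sim7` - `sim1` stages trained with the batch Quickprop optimiser.
#' * `custom` - stages supplied via `overrides$stages`.
#'
#' @param protocol_id One of `"sim1"`..`"sim7"`, `"custom"`.
#' @param lexicon An `aoa_lexicon` containing the grade groups the
#'   protocol references (grades 1 and 2 for the canonical designs).
#' @param overrides Named list of desk-scale overrides, recorded in the
#'   returned protocol: `early_n`, `late_n` (subset sizes), `epochs`
#'   (vector recycled over stages), `eval_every`, `n_hidden` (hidden
#'   layer size for networks initialised by [run_protocol()]; desk-scale
#'   protocols should scale capacity with the word count to keep the
#'   hidden-units-per-word ratio of the full design), `learning_rate`,
#'   `momentum`, `optimizer`, `quickprop_mu`, `stages` (custom only).
#' @param seed Master seed for the protocol; spawns independent streams
#'   for presentation shuffling and (if needed) network initialisation.
#' @return An `aoa_protocol` list: `stages` (each with `item_idx`,
#'   `multiplicity`, `epochs`), `hyperparams`, `eval_every`, `seed`,
#'   the embedded `lexicon` subset, `early_ids`/`late_ids`, and the
#'   recorded `overrides`.
#' @export
build_protocol <- function(protocol_id, lexicon, overrides = list(),
                           seed = 1L) {
  known <- c(paste0("sim", 1:7), "custom")
  if (!protocol_id %in% known)
    stop("unknown protocol_id '", protocol_id, "'")
  bad <- setdiff(names(overrides),
                 c("early_n", "late_n", "epochs", "eval_every", "n_hidden",
                   "learning_rate", "momentum", "optimizer",
                   "quickprop_mu", "quickprop_decay", "stages"))
  if (length(bad)) stop("unknown override key(s): ", paste(bad, collapse = ", "))

  cfg <- attr(lexicon, "config")
  n_letters <- if (!is.null(cfg)) cfg$n_letters else 33L
  n_phonemes <- if (!is.null(cfg)) cfg$n_phonemes else 28L

  take_grade <- function(g, n = NULL) {
    idx <- which(lexicon$grade == g)
    if (length(idx) == 0L)
      stop("lexicon has no grade-", g, " items required by ", protocol_id)
    if (!is.null(n)) {
      if (n > length(idx))
        stop("requested ", n, " grade-", g, " items but only ",
             length(idx), " exist")
      idx <- idx[seq_len(n)]
    }
    idx
  }

  if (protocol_id == "custom") {
    if (is.null(overrides$stages))
      stop("custom protocol requires overrides$stages")
    stages <- overrides$stages
    union_idx <- sort(unique(unlist(lapply(stages, `[[`, "item_idx"))))
    early_idx <- integer(0); late_idx <- integer(0)
  } else {
    early_idx <- take_grade(1L, overrides$early_n)
    late_idx <- take_grade(2L, overrides$late_n)
    union_idx <- c(early_idx, late_idx)

    base <- switch(protocol_id,
      sim1 = , sim6 = list(epochs = c(150L, 150L), lr = 0.01, mom = 0.9,
                           opt = "backprop", reversed = FALSE),
      sim2 = list(epochs = c(150L, 300L), lr = 0.01, mom = 0.9,
                  opt = "backprop", reversed = FALSE),
      sim3 = list(epochs = c(150L, 150L), lr = 0.01, mom = 0.9,
                  opt = "backprop", reversed = TRUE),
      sim4 = list(epochs = c(300L, 300L), lr = 0.05, mom = 0.9,
                  opt = "backprop", reversed = FALSE),
      sim5 = list(epochs = c(1500L, 1500L), lr = 0.05, mom = 0,
                  opt = "backprop", reversed = FALSE),
      sim7 = list(epochs = c(150L, 150L), lr = 0.01, mom = 0.9,
                  opt = "quickprop", reversed = FALSE))

    if (!is.null(overrides$epochs))
      base$epochs <- as.integer(rep_len(overrides$epochs, 2L))
    first <- if (base$reversed) late_idx else early_idx
    second <- if (base$reversed) early_idx else late_idx
    stages <- list(
      list(item_idx = first,
           multiplicity = rep(1L, length(first)),
           epochs = base$epochs[1]),
      # newcomer group presented twice per epoch: frequency equalisation
      list(item_idx = c(first, second),
           multiplicity = c(rep(1L, length(first)), rep(2L, length(second))),
           epochs = base$epochs[2])
    )
  }

  hp <- hyperparams(
    learning_rate = overrides$learning_rate %||%
      if (protocol_id == "custom") 0.01 else base$lr,
    momentum = overrides$momentum %||%
      if (protocol_id == "custom") 0.9 else base$mom,
    optimizer = overrides$optimizer %||%
      if (protocol_id == "custom") "backprop" else base$opt,
    quickprop_mu = overrides$quickprop_mu %||% 1.75,
    quickprop_decay = overrides$quickprop_decay %||% 1e-4)

  sub <- lexicon[union_idx, , drop = FALSE]
  remap <- match(union_idx, union_idx)        # identity; stages re-indexed
  reindex <- function(v) match(v, union_idx)
  stages <- lapply(stages, function(st) {
    st$item_idx <- reindex(st$item_idx); st
  })

  structure(list(
    protocol_id = protocol_id,
    stages = stages,
    hyperparams = hp,
    eval_every = as.integer(overrides$eval_every %||% 10L),
    n_hidden = as.integer(overrides$n_hidden %||% 100L),
    seed = as.integer(seed),
    lexicon = sub,
    n_letters = n_letters, n_phonemes = n_phonemes,
    early_ids = lexicon$word_id[early_idx],
    late_ids = lexicon$word_id[late_idx],
    overrides = overrides
  ), class = "aoa_protocol")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sub-seed derivation (stays below 2^31 - 1)
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed %% 2147483647L) * 48271 +
                stream * 1299709) %% 2147483647)
}

#' Run a training protocol
#'
#' Executes the protocol's stages in order.  With the online back-prop
#' optimiser, each epoch presents every stage item (repeated according to
#' its multiplicity) in a freshly shuffled order and applies one update
#' per presentation; with Quickprop, each epoch accumulates the gradient
#' over the full presentation list and applies one batch update.  At
#' epoch 0, every `eval_every` epochs, and at the final epoch, all items
#' in the union of the stages are scored with a clean forward pass
#' (per-item summed squared error and decoded whole-word correctness),
#' along with sigmoid-saturation statistics of the output layer.
#'
#' @param protocol An `aoa_protocol` from [build_protocol()].
#' @param net An `aoa_network`, or `NULL` to initialise one from the
#'   protocol's seed stream with the protocol's hidden size (default 100).
#' @return An `aoa_training` list: the final `net`, the `trajectory`
#'   data frame (`epoch`, `word_id`, `grade`, `sse`, `correct`), the
#'   `unit_stats` data frame (`epoch`, `mean_abs_net_output`,
#'   `mean_slope` over trained items), `total_presentations`, and the
#'   `protocol`.
#' @export
run_protocol <- function(protocol, net = NULL) {
  stopifnot(inherits(protocol, "aoa_protocol"))
  enc <- .encode_lexicon(protocol$lexicon, protocol$n_letters,
                         protocol$n_phonemes)
  if (is.null(net))
    net <- init_network(enc$n_in, protocol$n_hidden %||% 100L, enc$n_out,
                        init_range = protocol$hyperparams$init_range,
                        seed = derive_seed(protocol$seed, 17L))
  if (net$n_in != enc$n_in || net$n_out != enc$n_out)
    stop("network dimensions (", net$n_in, ", ", net$n_out,
         ") do not match the lexicon encoding (", enc$n_in, ", ",
         enc$n_out, ")")
  withr::with_seed(derive_seed(protocol$seed, 1L),
                   .run_protocol_impl(protocol, net, enc))
}

.run_protocol_impl <- function(protocol, net, enc) {
  hp <- protocol$hyperparams
  lex <- protocol$lexicon
  n_items <- nrow(lex)
  x_idx <- lapply(enc$x_idx, as.integer)
  targets <- enc$targets                      # items x n_out
  lr <- hp$learning_rate; mom <- hp$momentum
  quick <- hp$optimizer == "quickprop"

  # private copies: the compiled training loop updates these in place
  W_ih <- net$W_ih + 0; b_h <- net$b_h + 0
  W_ho <- net$W_ho + 0; b_o <- net$b_o + 0
  D_Wih <- net$mem_delta$W_ih + 0; D_bh <- net$mem_delta$b_h + 0
  D_Who <- net$mem_delta$W_ho + 0; D_bo <- net$mem_delta$b_o + 0
  G_Wih <- net$mem_grad$W_ih + 0; G_bh <- net$mem_grad$b_h + 0
  G_Who <- net$mem_grad$W_ho + 0; G_bo <- net$mem_grad$b_o + 0

  eval_all <- function(epoch) {
    H <- stats::plogis(W_ih %*% t(.dense_inputs(x_idx, enc$n_in)) + b_h)
    NetO <- W_ho %*% H + b_o
    O <- stats::plogis(NetO)                  # n_out x items
    sse <- colSums((O - t(targets))^2)
    correct <- vapply(seq_len(n_items), function(i) {
      dec <- decode_phonology(O[, i], protocol$n_phonemes)
      .same_slots(dec, item_pronunciation(lex, i))
    }, logical(1))
    list(traj = data.frame(epoch = epoch, word_id = lex$word_id,
                           grade = lex$grade, sse = sse,
                           correct = correct, stringsAsFactors = FALSE),
         units = data.frame(epoch = epoch,
                            mean_abs_net_output = mean(abs(NetO)),
                            mean_slope = mean(O * (1 - O))))
  }

  traj <- list(); units <- list()
  rec <- eval_all(0L); traj[[1]] <- rec$traj; units[[1]] <- rec$units
  epoch_global <- 0L
  total_epochs <- sum(vapply(protocol$stages, `[[`, integer(1), "epochs"))
  total_pres <- 0L

  for (stage in protocol$stages) {
    pres <- rep(stage$item_idx, times = stage$multiplicity)
    total_pres <- total_pres + stage$epochs * length(pres)
    # all shuffles for the stage drawn up front, one per epoch, in epoch
    # order (same RNG stream as drawing them lazily)
    orders <- matrix(0L, nrow = length(pres), ncol = stage$epochs)
    for (e in seq_len(stage$epochs))
      orders[, e] <- pres[sample.int(length(pres))]
    done <- 0L
    while (done < stage$epochs) {
      to_next_eval <- protocol$eval_every -
        epoch_global %% protocol$eval_every
      k <- min(to_next_eval, stage$epochs - done)
      chunk <- orders[, (done + 1L):(done + k), drop = FALSE]
      if (!quick) {
        bp_train_chunk(W_ih, b_h, W_ho, b_o,
                       D_Wih, D_bh, D_Who, D_bo,
                       x_idx, targets, chunk, lr, mom)
      } else {
        qp_train_chunk(W_ih, b_h, W_ho, b_o,
                       D_Wih, D_bh, D_Who, D_bo,
                       G_Wih, G_bh, G_Who, G_bo,
                       x_idx, targets, chunk, lr, hp$quickprop_mu,
                       hp$quickprop_decay %||% 0)
      }
      done <- done + k
      epoch_global <- epoch_global + k
      if (any(!is.finite(b_o)) || any(!is.finite(b_h)))
        stop("training diverged: non-finite weights at epoch ",
             epoch_global)
      if (epoch_global %% protocol$eval_every == 0L ||
          epoch_global == total_epochs) {
        rec <- eval_all(epoch_global)
        traj[[length(traj) + 1L]] <- rec$traj
        units[[length(units) + 1L]] <- rec$units
      }
    }
  }

  net$W_ih <- W_ih; net$b_h <- b_h; net$W_ho <- W_ho; net$b_o <- b_o
  net$mem_delta <- list(W_ih = D_Wih, b_h = D_bh, W_ho = D_Who, b_o = D_bo)
  net$mem_grad <- list(W_ih = G_Wih, b_h = G_bh, W_ho = G_Who, b_o = G_bo)

  traj <- do.call(rbind, traj)
  traj <- traj[!duplicated(traj[, c("epoch", "word_id")]), ]
  structure(list(net = net, trajectory = traj,
                 unit_stats = do.call(rbind, units)[!duplicated(
                   vapply(units, `[[`, integer(1), "epoch")), ],
                 total_presentations = total_pres,
                 protocol = protocol),
            class = "aoa_training")
}

.dense_inputs <- function(x_idx, n_in) {
  X <- matrix(0, nrow = length(x_idx), ncol = n_in)
  for (i in seq_along(x_idx)) X[i, x_idx[[i]]] <- 1
  X
}

.same_slots <- function(a, b) {
  identical(ifelse(is.na(a), -1L, as.integer(a)),
            ifelse(is.na(b), -1L, as.integer(b)))
}

#' Convenience wrapper: build and run one simulation
#'
#' @param lexicon An `aoa_lexicon`.
#' @param protocol_id See [build_protocol()].
#' @param seed Master seed (spawns the shuffle and init streams).
#' @param overrides See [build_protocol()].
#' @param net Optional pre-built network.
#' @return An `aoa_training` (see [run_protocol()]).
#' @export
run_sim <- function(lexicon, protocol_id = "sim1", seed = 1L,
                    overrides = list(), net = NULL) {
  run_protocol(build_protocol(protocol_id, lexicon, overrides, seed), net)
}

#' Per-item results at the final training epoch
#'
#' @param training An `aoa_training`.
#' @return Data frame `word_id`, `grade`, `frequency`, `consistency`,
#'   `sse`, `correct` at the last recorded epoch.
#' @export
final_results <- function(training) {
  stopifnot(inherits(training, "aoa_training"))
  tr <- training$trajectory
  last <- tr[tr$epoch == max(tr$epoch), ]
  lex <- training$protocol$lexicon
  m <- match(last$word_id, lex$word_id)
  data.frame(word_id = last$word_id, grade = last$grade,
             frequency = lex$frequency[m], consistency = lex$consistency[m],
             sse = last$sse, correct = last$correct,
             stringsAsFactors = FALSE)
}
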