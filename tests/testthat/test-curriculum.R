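test_that("sim1 locks the focused-then-interleaved structure", {
  lex <- small_lexicon(5L, 4L, seed = 1L)
  p <- build_protocol("sim1", lex, seed = 1L)
  expect_length(p$stages, 2L)
  expect_equal(vapply(p$stages, `[[`, integer(1), "epochs"), c(150L, 150L))
  expect_equal(p$hyperparams$learning_rate, 0.01)
  expect_equal(p$hyperparams$momentum, 0.9)
  # newcomer (late) items presented twice per epoch
  st2 <- p$stages[[2]]
  late_pos <- st2$item_idx %in% match(p$late_ids, p$lexicon$word_id)
  expect_true(all(st2$multiplicity[late_pos] == 2L))
  expect_true(all(st2$multiplicity[!late_pos] == 1L))
})

test_that("cumulative presentations are frequency-equalised in sim1", {
  lex <- small_lexicon(3L, 3L, seed = 2L)
  p <- build_protocol("sim1", lex, seed = 1L)
  pres <- stats::setNames(numeric(nrow(p$lexicon)), p$lexicon$word_id)
  for (st in p$stages)
    for (k in seq_along(st$item_idx)) {
      id <- p$lexicon$word_id[st$item_idx[k]]
      pres[id] <- pres[id] + st$epochs * st$multiplicity[k]
    }
  expect_true(all(pres[p$early_ids] == 300))
  expect_true(all(pres[p$late_ids] == 300))
})

test_that("sim3 reverses training order; sim5 drops momentum; sim7 uses quickprop", {
  lex <- small_lexicon(4L, 4L, seed = 3L)
  p1 <- build_protocol("sim1", lex, seed = 1L)
  p3 <- build_protocol("sim3", lex, seed = 1L)
  first3 <- p3$lexicon$word_id[p3$stages[[1]]$item_idx]
  expect_setequal(first3, p3$late_ids)
  p5 <- build_protocol("sim5", lex, seed = 1L)
  expect_equal(vapply(p5$stages, `[[`, integer(1), "epochs"),
               c(1500L, 1500L))
  expect_equal(p5$hyperparams$momentum, 0)
  expect_equal(p5$hyperparams$learning_rate, 0.05)
  p7 <- build_protocol("sim7", lex, seed = 1L)
  expect_equal(p7$hyperparams$optimizer, "quickprop")
  expect_equal(lapply(p7$stages, `[[`, "item_idx"),
               lapply(p1$stages, `[[`, "item_idx"))
  expect_error(build_protocol("sim9", lex), "unknown")
  expect_error(build_protocol("sim1", lex[lex$grade == 1, ]), "grade-2")
})

test_that("epoch accounting matches stages times multiplicities", {
  lex <- small_lexicon(3L, 2L, seed = 4L)
  tr <- run_sim(lex, "sim1", seed = 1L,
                overrides = list(epochs = c(4L, 5L), eval_every = 100L))
  expect_equal(tr$total_presentations, 4L * 3L + 5L * (3L + 2L * 2L))
})

test_that("training runs are reproducible from the protocol seed", {
  lex <- small_lexicon(4L, 4L, seed = 5L)
  ov <- list(epochs = c(5L, 5L), eval_every = 5L)
  a <- run_sim(lex, "sim1", seed = 9L, overrides = ov)
  b <- run_sim(lex, "sim1", seed = 9L, overrides = ov)
  expect_identical(a$trajectory, b$trajectory)
  expect_equal(a$net$W_ho, b$net$W_ho, tolerance = 1e-15)
  c <- run_sim(lex, "sim1", seed = 10L, overrides = ov)
  expect_false(identical(a$trajectory, c$trajectory))
})

test_that("the training loop equals sequential backprop_update calls", {
  lex <- small_lexicon(3L, 2L, seed = 6L)
  ov <- list(epochs = c(3L, 2L), eval_every = 100L)
  p <- build_protocol("sim1", lex, overrides = ov, seed = 31L)
  net0 <- init_network(132L, 10L, 112L, seed = 77L)
  got <- run_protocol(p, net0)

  # mirror: same shuffle stream, one backprop_update per presentation
  enc_x <- lapply(seq_len(nrow(p$lexicon)), function(i)
    encode_orthography(as.integer(p$lexicon[i, paste0("slot", 1:4)]), 33L))
  enc_t <- lapply(seq_len(nrow(p$lexicon)), function(i)
    encode_phonology(as.integer(p$lexicon[i, paste0("pslot", 1:4)]), 28L))
  net <- net0
  withr::with_seed(aoanet:::derive_seed(31L, 1L), {
    for (st in p$stages) {
      pres <- rep(st$item_idx, times = st$multiplicity)
      for (e in seq_len(st$epochs)) {
        ord <- pres[sample.int(length(pres))]
        for (i in ord)
          net <- backprop_update(net, enc_x[[i]], enc_t[[i]], p$hyperparams)
      }
    }
  })
  expect_equal(got$net$W_ih, net$W_ih, tolerance = 1e-8)
  expect_equal(got$net$W_ho, net$W_ho, tolerance = 1e-8)
  expect_equal(got$net$b_o, net$b_o, tolerance = 1e-8)
})

test_that("a single word trained alone is read perfectly", {
  lex <- small_lexicon(1L, 1L, seed = 8L)
  lex1 <- lex[lex$grade == 1, ]
  attr(lex1, "config") <- attr(lex, "config")
  p <- build_protocol("custom", lex1, seed = 2L, overrides = list(
    stages = list(list(item_idx = 1L, multiplicity = 1L, epochs = 100L)),
    learning_rate = 0.5, momentum = 0))
  tr <- run_protocol(p, init_network(132L, 20L, 112L, seed = 3L))
  out <- forward(tr$net, encode_orthography(
    as.integer(lex1[1, paste0("slot", 1:4)]), 33L))$output
  expect_identical(decode_phonology(out, 28L),
                   as.integer(lex1[1, paste0("pslot", 1:4)]))
  res <- final_results(tr)
  expect_true(res$correct[1])
})

test_that("trajectory records epoch 0 and the evaluation schedule", {
  lex <- small_lexicon(2L, 2L, seed = 9L)
  tr <- run_sim(lex, "sim1", seed = 1L,
                overrides = list(epochs = c(6L, 6L), eval_every = 4L))
  expect_setequal(unique(tr$trajectory$epoch), c(0L, 4L, 8L, 12L))
  expect_equal(sum(tr$trajectory$epoch == 0L), 4L)   # all items scored
  expect_setequal(tr$unit_stats$epoch, c(0L, 4L, 8L, 12L))
})
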