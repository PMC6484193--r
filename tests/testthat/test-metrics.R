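test_that("an all-zero network scores 28 on every item", {
  lex <- small_lexicon(3L, 3L, seed = 1L)
  net <- init_network(132L, 10L, 112L, seed = 1L)
  net$W_ih[] <- 0; net$b_h[] <- 0; net$W_ho[] <- 0; net$b_o[] <- 0
  res <- evaluate(net, lex)
  # every output unit sits at 0.5, so sse = 112 * 0.25 for binary targets
  expect_equal(res$sse, rep(28, 6), tolerance = 1e-12)
  expect_false(any(res$correct))
})

test_that("per-item sse matches a hand evaluation on a toy net", {
  lex <- make_lexicon(list(c(1L, NA, 2L, NA)), list(c(2L, NA, 1L, NA)),
                      n_letters = 2L, n_phonemes = 2L)
  net <- init_network(8L, 2L, 8L, seed = 1L)
  res <- evaluate(net, lex)
  x <- encode_orthography(c(1L, NA, 2L, NA), 2L)
  t <- encode_phonology(c(2L, NA, 1L, NA), 2L)
  expect_equal(res$sse, sum((forward(net, x)$output - t)^2),
               tolerance = 1e-12)
})

test_that("the AoA gap is the late-minus-early mean error", {
  res <- data.frame(word_id = c("a", "b", "c", "d"),
                    sse = c(0.25, 0.25, 1.0, 1.0))
  expect_equal(aoa_gap(res, c("a", "b"), c("c", "d")), 0.75)
  expect_equal(aoa_gap(res, c("a", "c"), c("b", "d")), 0)
  expect_error(aoa_gap(res, character(0), "c"), "nonempty")
  expect_error(aoa_gap(res, c("a", "b"), c("b", "c")), "disjoint")
})

test_that("group summaries give n, mean and sample SD with a totals row", {
  res <- data.frame(grade = c(1, 1, 2), sse = c(0, 1, 3))
  gs <- group_summary(res)
  expect_equal(gs$n, c(2L, 1L, 3L))
  expect_equal(gs$mean[1], 0.5)
  expect_equal(gs$sd[1], sqrt(0.5), tolerance = 1e-12)
  expect_equal(gs$grade[3], "Total")
  expect_equal(group_summary(data.frame(grade = 1, sse = c(2, 2, 2)))$sd[1], 0)
  lex <- generate_lexicon(lexicon_config())
  res2 <- data.frame(grade = lex$grade, sse = lex$consistency)
  expect_equal(group_summary(res2)$n, c(82L, 62L, 56L, 49L, 78L, 327L))
  expect_error(group_summary(res[0, ]), "no results")
})

test_that("covariance analysis reproduces the 5-group design dfs", {
  lex <- generate_lexicon(lexicon_config(seed = 3L))
  set.seed(1)
  rec <- data.frame(sse = rnorm(327, 1, 0.3), grade = lex$grade,
                    frequency = lex$frequency,
                    consistency = lex$consistency)
  a <- ancova(rec)
  expect_equal(a$table$df, c(1L, 1L, 4L, 320L))
  expect_equal(sum(a$table$df), 326L)            # N - 1
})

test_that("sequential SS agree with an independent projection oracle", {
  set.seed(7)
  n <- 60
  rec <- data.frame(sse = rnorm(n), grade = sample(1:4, n, replace = TRUE),
                    frequency = rpois(n, 3) + 1,
                    consistency = rpois(n, 2))
  a <- ancova(rec)
  # oracle: residual sums of squares of nested OLS fits via QR
  y <- rec$sse
  G <- stats::model.matrix(~ factor(rec$grade))
  rss <- function(X) sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  X0 <- matrix(1, n, 1)
  X1 <- cbind(X0, rec$frequency)
  X2 <- cbind(X1, rec$consistency)
  X3 <- cbind(X2, G[, -1])
  ss <- c(rss(X0) - rss(X1), rss(X1) - rss(X2), rss(X2) - rss(X3), rss(X3))
  expect_equal(a$table$SS, ss, tolerance = 1e-8)
  expect_equal(a$table$df, c(1L, 1L, 3L, n - 6L))
  ms_err <- ss[4] / (n - 6)
  expect_equal(a$table$F[3], (ss[3] / 3) / ms_err, tolerance = 1e-8)
})

test_that("total SS decomposes and F is scale-invariant", {
  set.seed(9)
  n <- 80
  rec <- data.frame(sse = rgamma(n, 2), grade = sample(1:5, n, TRUE),
                    frequency = rpois(n, 2) + 1, consistency = rpois(n, 3))
  a <- ancova(rec)
  total <- sum((rec$sse - mean(rec$sse))^2)
  expect_equal(sum(a$table$SS), total, tolerance = 1e-8 * total)
  b <- ancova(transform(rec, sse = 10 * sse))
  expect_equal(b$table$SS, 100 * a$table$SS, tolerance = 1e-8)
  expect_equal(b$table$F, a$table$F, tolerance = 1e-10)
  expect_equal(b$linear_trend$t, a$linear_trend$t, tolerance = 1e-10)
})

test_that("with two balanced groups and no covariates F equals t squared", {
  set.seed(11)
  y <- c(rnorm(15, 0), rnorm(15, 0.8))
  rec <- data.frame(sse = y, grade = rep(1:2, each = 15))
  a <- ancova(rec)
  tt <- stats::t.test(y[16:30], y[1:15], var.equal = TRUE)$statistic
  expect_equal(a$table$F[a$table$source == "AoA"], unname(tt^2),
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected with diagnostics", {
  rec <- data.frame(sse = rnorm(20), grade = rep(1:2, each = 10),
                    frequency = rep(1:2, each = 10),  # aliased with grade
                    consistency = rnorm(20))
  expect_error(ancova(rec), "rank-deficient")
  expect_error(ancova(data.frame(sse = rnorm(3), grade = c(1, 1, 1))),
               "2 levels")
})

test_that("saturation statistics move as training entrenches a mapping", {
  lex <- small_lexicon(5L, 5L, seed = 2L)
  tr <- run_sim(lex, "sim1", seed = 3L,
                overrides = list(epochs = c(30L, 1L), eval_every = 31L))
  before <- tr$unit_stats[tr$unit_stats$epoch == 0, ]
  after <- tr$unit_stats[tr$unit_stats$epoch == 31, ]
  expect_gt(after$mean_abs_net_output, before$mean_abs_net_output)
  expect_lt(after$mean_slope, before$mean_slope)
  ps <- plasticity_summary(tr$net, tr$protocol$lexicon)
  expect_equal(ps$mean_abs_net_input, after$mean_abs_net_output,
               tolerance = 1e-12)
})
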