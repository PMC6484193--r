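test_that("initialisation respects sizes, range and seed", {
  net <- init_network()
  expect_equal(dim(net$W_ih), c(100L, 132L))
  expect_equal(dim(net$W_ho), c(112L, 100L))
  expect_lte(max(abs(c(net$W_ih, net$b_h, net$W_ho, net$b_o))), 0.5)
  expect_identical(init_network(seed = 4L), init_network(seed = 4L))
  expect_false(identical(init_network(seed = 4L), init_network(seed = 5L)))
  expect_error(init_network(n_hidden = 0L), "sizes")
})

test_that("forward pass is the composed logistic map", {
  net <- toy_net()
  net$W_ih[] <- 0; net$b_h[] <- 0; net$W_ho[] <- 0; net$b_o[] <- 0
  f <- forward(net, c(1, 0, 1))
  expect_equal(f$hidden, rep(0.5, 4))
  expect_equal(f$output, rep(0.5, 2))

  # hand-built 2-2-1 network against an explicit closed form
  net2 <- init_network(2L, 2L, 1L, seed = 1L)
  net2$W_ih <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  net2$b_h <- c(0.1, -0.4)
  net2$W_ho <- matrix(c(0.7, -1.2), 1, 2)
  net2$b_o <- 0.25
  x <- c(1, 1)
  sig <- function(z) 1 / (1 + exp(-z))
  h1 <- sig(0.3 * 1 + 0.5 * 1 + 0.1)
  h2 <- sig(-0.2 * 1 + 0.1 * 1 - 0.4)
  expect_equal(forward(net2, x)$output,
               sig(0.7 * h1 - 1.2 * h2 + 0.25), tolerance = 1e-12)

  expect_error(forward(net, c(1, 0)), "n_in")
})

test_that("activations stay strictly inside (0,1) for finite weights", {
  net <- toy_net(seed = 3L)
  net$W_ih <- net$W_ih * 50          # push toward saturation
  f <- forward(net, c(1, 1, 1))
  expect_true(all(f$hidden > 0 & f$hidden < 1))
  expect_true(all(f$output > 0 & f$output < 1))
})

test_that("backprop gradient matches central finite differences", {
  hp <- hyperparams(learning_rate = 0.05, momentum = 0)
  for (s in 1:5) {
    net <- toy_net(3L, 4L, 2L, seed = s)
    x <- c(1, 0, 1); target <- c(1, 0)
    num <- numeric_grads(net, x, target)
    upd <- backprop_update(net, x, target, hp)
    for (nm in c("W_ih", "b_h", "W_ho", "b_o")) {
      applied <- upd[[nm]] - net[[nm]]
      expected <- -hp$learning_rate * num[[nm]]
      expect_lt(max(abs(applied - expected)) /
                  max(abs(expected), 1e-12), 1e-6)
    }
  }
})

test_that("momentum accumulates the previous applied update", {
  hp0 <- hyperparams(learning_rate = 0.1, momentum = 0)
  hp9 <- hyperparams(learning_rate = 0.1, momentum = 0.9)
  net <- toy_net(seed = 6L)
  x <- c(1, 1, 0); target <- c(0, 1)
  # first step identical with and without momentum (zero memory)
  a <- backprop_update(net, x, target, hp0)
  b <- backprop_update(net, x, target, hp9)
  expect_equal(a$W_ho, b$W_ho, tolerance = 1e-15)
  # second step adds 0.9 x previous update on top of the gradient step
  a2 <- backprop_update(a, x, target, hp0)
  b2 <- backprop_update(b, x, target, hp9)
  extra <- (b2$W_ho - b$W_ho) - (a2$W_ho - a$W_ho)
  expect_equal(extra, 0.9 * (b$W_ho - net$W_ho), tolerance = 1e-12)
})

test_that("zero output error leaves the state unchanged", {
  net <- toy_net(seed = 2L)
  x <- c(1, 0, 0)
  target <- forward(net, x)$output   # error exactly zero
  upd <- backprop_update(net, x, target, hyperparams(momentum = 0))
  expect_equal(upd$W_ih, net$W_ih, tolerance = 1e-15)
  expect_equal(upd$b_o, net$b_o, tolerance = 1e-15)
})

test_that("repeated single-pattern training monotonically reduces error", {
  net <- toy_net(3L, 4L, 2L, seed = 9L)
  hp <- hyperparams(learning_rate = 0.01, momentum = 0)
  x <- c(1, 1, 1); target <- c(1, 0)
  E <- function(nn) sum((forward(nn, x)$output - target)^2)
  errs <- numeric(101); errs[1] <- E(net)
  for (k in 1:100) {
    net <- backprop_update(net, x, target, hp)
    errs[k + 1] <- E(net)
  }
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[101], errs[1])
})

test_that("quickprop secant step jumps to a quadratic's vertex", {
  # E(w) = 0.5 * k (w - w*)^2 with k = 1; gradient g(w) = w - w*.
  # the bootstrap overshoots the minimum, so the next step is the pure
  # secant jump onto the vertex
  w_star <- 2; k <- 1; lr <- 1.5
  w0 <- 5
  g0 <- k * (w0 - w_star)
  s1 <- quickprop_step(g0, 0, 0, lr)            # bootstrap: plain gradient
  expect_equal(s1, -lr * g0)
  w1 <- w0 + s1
  g1 <- k * (w1 - w_star)
  expect_lt(g1 * g0, 0)                         # minimum was crossed
  s2 <- quickprop_step(g1, g0, s1, lr)
  expect_equal(w1 + s2, w_star, tolerance = 1e-12)
})

test_that("quickprop growth cap, gradient term and degenerate cases", {
  expect_equal(quickprop_step(0, 0, 0, 0.1), 0)           # zero gradient
  expect_equal(quickprop_step(0, 3, -1, 0.1), 0)          # flat slope, history
  # a vertex beyond mu x the previous step takes the maximum-growth step,
  # plus the additive gradient term while the slope keeps its sign
  prev <- -1; g_prev <- 10; g <- 10 * 10 / 11
  raw <- prev * g / (g_prev - g)                          # would be -10
  expect_equal(abs(raw), 10, tolerance = 1e-9)
  expect_equal(quickprop_step(g, g_prev, prev, 0.1, mu = 1.75),
               -1.75 - 0.1 * g)
  # slope sign flipped (minimum crossed): pure interpolating secant step
  expect_equal(quickprop_step(-1, 2, -1, 0.1), 1 / 3)
})

test_that("quickprop batch update accumulates gradients over the batch", {
  net <- toy_net(seed = 10L)
  hp <- hyperparams(learning_rate = 0.05, optimizer = "quickprop",
                    quickprop_decay = 0)
  p <- list(x = c(1, 0, 1), target = c(1, 0))
  one <- quickprop_update(net, list(p), hp)
  two <- quickprop_update(net, list(p, p), hp)
  # from zero memories both take the fallback -lr*g; doubling the batch
  # doubles the accumulated gradient and hence the step
  expect_equal(two$W_ho - net$W_ho, 2 * (one$W_ho - net$W_ho),
               tolerance = 1e-12)
  expect_error(quickprop_update(net, list(), hp), "nonempty")
})

test_that("network JSON round-trips weights and memories", {
  net <- toy_net(seed = 12L)
  net <- backprop_update(net, c(1, 0, 1), c(1, 0), hyperparams())
  path <- withr::local_tempfile(fileext = ".json")
  save_network(net, path)
  back <- load_network(path)
  expect_equal(back$W_ih, net$W_ih, tolerance = 1e-14)
  expect_equal(back$mem_delta$W_ho, net$mem_delta$W_ho, tolerance = 1e-14)
  expect_identical(back$n_hidden, net$n_hidden)
  expect_identical(back$seed, net$seed)
})
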