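#' Training hyperparameters
#'
#' @param learning_rate Positive step size. The staged-curriculum
#'   protocols use 0.01 (focused/interleaved/reversed) or 0.05.
#' @param momentum Fraction in \[0,1) of the previous update added to the
#'   current one; 0.9 by default, 0 in the no-momentum control.
#' @param optimizer `"backprop"` (online, per-pattern) or `"quickprop"`
#'   (batch, per-epoch secant updates).
#' @param quickprop_mu Maximum growth factor of a Quickprop step relative
#'   to the previous step (default 1.75).
#' @param quickprop_decay Small weight-decay term added to the Quickprop
#'   slope (`g + decay * w`, default 1e-4), the standard safeguard that
#'   keeps maximum-growth steps from escalating weights without bound.
#'   Quickprop only; back-propagation uses no decay.
#' @param init_range Half-width of the uniform weight initialisation
#'   (default 0.5, i.e. weights start in \[-0.5, +0.5\]).
#' @return A `hyperparams` list.
#' @export
hyperparams <- function(learning_rate = 0.01, momentum = 0.9,
                        optimizer = c("backprop", "quickprop"),
                        quickprop_mu = 1.75, quickprop_decay = 1e-4,
                        init_range = 0.5) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  if (quickprop_mu <= 0) stop("quickprop_mu must be > 0")
  if (quickprop_decay < 0) stop("quickprop_decay must be >= 0")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 optimizer = optimizer, quickprop_mu = quickprop_mu,
                 quickprop_decay = quickprop_decay,
                 init_range = init_range),
            class = "hyperparams")
}

#' Initialise a two-layer logistic network
#'
#' Builds the orthography-to-phonology network: `n_in` localist input
#' units, a logistic hidden layer, and `n_out` logistic output units
#' (132-100-112 for the default alphabets).  Every weight and bias is
#' drawn uniformly from \[-init_range, +init_range\]; the momentum and
#' Quickprop memories start at zero.
#'
#' @param n_in,n_hidden,n_out Layer sizes (defaults 132, 100, 112).
#' @param init_range Half-width of the uniform initial weight range.
#' @param seed Integer seed; the same seed reproduces the state exactly.
#' @return An `aoa_network` list with weight matrices `W_ih`
#'   (hidden x input), `W_ho` (output x hidden), biases `b_h`, `b_o`,
#'   and optimiser memories `mem_delta_*` (previous applied updates) and
#'   `mem_grad_*` (previous batch gradients).
#' @export
init_network <- function(n_in = 132L, n_hidden = 100L, n_out = 112L,
                         init_range = 0.5, seed = 1L) {
  if (n_in < 1L || n_hidden < 1L || n_out < 1L)
    stop("all layer sizes must be >= 1")
  withr::with_seed(seed, {
    net <- list(
      n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
      n_out = as.integer(n_out),
      W_ih = matrix(stats::runif(n_hidden * n_in, -init_range, init_range),
                    n_hidden, n_in),
      b_h = stats::runif(n_hidden, -init_range, init_range),
      W_ho = matrix(stats::runif(n_out * n_hidden, -init_range, init_range),
                    n_out, n_hidden),
      b_o = stats::runif(n_out, -init_range, init_range),
      seed = as.integer(seed)
    )
  })
  net$mem_delta <- .zero_like(net)
  net$mem_grad <- .zero_like(net)
  class(net) <- "aoa_network"
  net
}

.zero_like <- function(net) {
  list(W_ih = matrix(0, net$n_hidden, net$n_in),
       b_h = numeric(net$n_hidden),
       W_ho = matrix(0, net$n_out, net$n_hidden),
       b_o = numeric(net$n_out))
}

#' Forward pass
#'
#' Propagates an input vector through the network with the logistic
#' activation `sigma(z) = 1 / (1 + exp(-z))` at both layers.
#'
#' @param net An `aoa_network`.
#' @param x Numeric input vector of length `net$n_in`.
#' @return List with `hidden` and `output` activations (all in (0,1)) and
#'   the pre-activation net inputs `net_hidden`, `net_output`.
#' @export
forward <- function(net, x) {
  if (length(x) != net$n_in)
    stop("input length ", length(x), " does not match n_in = ", net$n_in)
  net_h <- as.vector(net$W_ih %*% x) + net$b_h
  h <- stats::plogis(net_h)
  net_o <- as.vector(net$W_ho %*% h) + net$b_o
  o <- stats::plogis(net_o)
  list(hidden = h, output = o, net_hidden = net_h, net_output = net_o)
}

# Delta-rule gradients for one pattern: E = 0.5 * sum((o - t)^2), so
# delta_o = (o - t) * o * (1 - o) with the logistic derivative a(1-a).
# (The per-item *scoring* metric sum((o - t)^2) is twice this E; only the
# training gradient uses the 1/2 convention.)
.sse_grads <- function(net, x, target, flat_spot = 0) {
  f <- forward(net, x)
  o <- f$output; h <- f$hidden
  delta_o <- (o - target) * (o * (1 - o) + flat_spot)
  delta_h <- as.vector(crossprod(net$W_ho, delta_o)) * h * (1 - h)
  list(W_ho = tcrossprod(delta_o, h), b_o = delta_o,
       W_ih = tcrossprod(delta_h, x), b_h = delta_h,
       output = o, sse = sum((o - target)^2))
}

#' One online back-propagation update
#'
#' Applies a single gradient-descent-with-momentum step on the
#' half-summed squared error `E = 0.5 * sum((o - t)^2)` of one pattern
#' (the classic delta rule, `delta_o = (o - t) * o * (1 - o)`):
#' `delta_w = -lr * dE/dw + momentum * delta_w_prev`.  The applied update
#' is stored as the new momentum memory.  Note the per-item error
#' *metric* reported by [evaluate()] is `sum((o - t)^2)`, without the
#' 1/2; the convention only affects the gradient scale.
#'
#' @param net An `aoa_network`.
#' @param x Input vector (length `n_in`).
#' @param target Target vector of 0/1 values (length `n_out`).
#' @param hp A [hyperparams()] with `optimizer = "backprop"`.
#' @return The updated network.
#' @export
backprop_update <- function(net, x, target, hp = hyperparams()) {
  if (hp$optimizer != "backprop")
    stop("backprop_update requires optimizer = 'backprop'")
  if (length(target) != net$n_out)
    stop("target length does not match n_out")
  g <- .sse_grads(net, x, target)
  for (nm in c("W_ih", "b_h", "W_ho", "b_o")) {
    if (any(!is.finite(g[[nm]])))
      stop("non-finite gradient in ", nm, "; training diverged")
    upd <- -hp$learning_rate * g[[nm]] + hp$momentum * net$mem_delta[[nm]]
    net[[nm]] <- net[[nm]] + upd
    net$mem_delta[[nm]] <- upd
  }
  net
}

#' Quickprop step for one parameter
#'
#' The per-weight rule of Fahlman's Quickprop: treat the error curve
#' along each weight as a parabola through the two most recent gradients
#' and jump toward its vertex with the secant step
#' `step = prev_step * g / (g_prev - g)`.  When the slope keeps its sign
#' and the implied vertex lies beyond `mu` times the previous step
#' (including wrong-curvature cases, `|g| >= mu/(1+mu) * |g_prev|`), the
#' maximum-growth step `mu * prev_step` is taken instead; and whenever
#' the slope sign is unchanged (the minimum has not been crossed) a
#' gradient-descent term `-lr * g` is added on top.  With no usable
#' history (`prev_step == 0`) a plain gradient step `-lr * g` bootstraps
#' the process.  Vectorised over its arguments.
#'
#' @param g Current gradient.
#' @param g_prev Gradient at the previous update.
#' @param prev_step Previously applied step.
#' @param lr Learning rate for the bootstrap/additive gradient term.
#' @param mu Maximum growth factor (default 1.75).
#' @return The step to add to the weight.
#' @export
quickprop_step <- function(g, g_prev, prev_step, lr, mu = 1.75) {
  step <- -lr * g                                 # bootstrap
  has_prev <- prev_step != 0
  same <- has_prev & g * g_prev > 0
  growth <- same & abs(g) >= (mu / (1 + mu)) * abs(g_prev)
  quad <- has_prev & !growth & g != 0
  step[quad] <- prev_step[quad] * g[quad] / (g_prev[quad] - g[quad])
  step[growth] <- mu * prev_step[growth]
  step[same] <- step[same] - lr * g[same]
  step
}

#' One batch Quickprop update
#'
#' Accumulates the error gradient over the whole batch (epoch-wise
#' updating) and applies [quickprop_step()] elementwise.  Following the
#' standard algorithm, the output-unit error derivative uses the
#' sigmoid-prime offset `o(1-o) + 0.1`, so saturated output units remain
#' trainable (flat-spot elimination) — this is what preserves the
#' network's flexibility relative to plain back-propagation.  A small
#' weight-decay term (`hp$quickprop_decay`) is folded into the slope to
#' keep maximum-growth steps bounded.  Gradient and step memories are
#' replaced by the batch slope and the applied step.
#'
#' @param net An `aoa_network`.
#' @param batch List of `list(x = , target = )` patterns.
#' @param hp A [hyperparams()] with `optimizer = "quickprop"`.
#' @return The updated network.
#' @export
quickprop_update <- function(net, batch, hp) {
  if (hp$optimizer != "quickprop")
    stop("quickprop_update requires optimizer = 'quickprop'")
  if (length(batch) == 0L) stop("batch must be nonempty")
  acc <- .zero_like(net)
  for (p in batch) {
    g <- .sse_grads(net, p$x, p$target, flat_spot = 0.1)
    for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  }
  decay <- hp$quickprop_decay %||% 0
  for (nm in names(acc)) {
    acc[[nm]] <- acc[[nm]] + decay * net[[nm]]
    if (any(!is.finite(acc[[nm]])))
      stop("non-finite gradient in ", nm, "; training diverged")
    step <- quickprop_step(acc[[nm]], net$mem_grad[[nm]],
                           net$mem_delta[[nm]],
                           hp$learning_rate, hp$quickprop_mu)
    net[[nm]] <- net[[nm]] + step
    net$mem_delta[[nm]] <- step
    net$mem_grad[[nm]] <- acc[[nm]]
  }
  net
}

#' Save / load a network as JSON
#'
#' A single self-describing plain-text file holding layer sizes, the
#' initialisation seed, and all weights, biases and optimiser memories at
#' full double precision.
#'
#' @param net An `aoa_network`.
#' @param path File path.
#' @return `save_network` returns `path` invisibly; `load_network`
#'   returns the restored `aoa_network`.
#' @export
save_network <- function(net, path) {
  payload <- list(
    format = "aoanet-network", format_version = 1L,
    n_in = net$n_in, n_hidden = net$n_hidden, n_out = net$n_out,
    seed = net$seed,
    W_ih = as.vector(net$W_ih), b_h = net$b_h,
    W_ho = as.vector(net$W_ho), b_o = net$b_o,
    mem_delta = lapply(net$mem_delta, as.vector),
    mem_grad = lapply(net$mem_grad, as.vector)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "aoanet-network")
    stop("not an aoanet network file: ", path)
  net <- list(n_in = as.integer(p$n_in), n_hidden = as.integer(p$n_hidden),
              n_out = as.integer(p$n_out),
              W_ih = matrix(p$W_ih, p$n_hidden, p$n_in),
              b_h = as.numeric(p$b_h),
              W_ho = matrix(p$W_ho, p$n_out, p$n_hidden),
              b_o = as.numeric(p$b_o),
              seed = as.integer(p$seed))
  net$mem_delta <- list(W_ih = matrix(p$mem_delta$W_ih, p$n_hidden, p$n_in),
                        b_h = as.numeric(p$mem_delta$b_h),
                        W_ho = matrix(p$mem_delta$W_ho, p$n_out, p$n_hidden),
                        b_o = as.numeric(p$mem_delta$b_o))
  net$mem_grad <- list(W_ih = matrix(p$mem_grad$W_ih, p$n_hidden, p$n_in),
                       b_h = as.numeric(p$mem_grad$b_h),
                       W_ho = matrix(p$mem_grad$W_ho, p$n_out, p$n_hidden),
                       b_o = as.numeric(p$mem_grad$b_o))
  class(net) <- "aoa_network"
  net
}
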