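#' Lesion a trained network
#'
#' Damages `round(severity * n_hidden)` distinct hidden units (round half
#' up), selected uniformly at random from a per-sample seed stream.
#' `zero_weights` removes each selected unit from the computation: all of
#' its incoming and outgoing weights and its bias are set to 0.
#' `add_noise` perturbs each selected unit with independent zero-mean
#' Gaussian noise of standard deviation `noise_sd` on every incoming and
#' outgoing weight and the bias (so the unit's net input, and hence its
#' activation, is disturbed rather than silenced).  The input network is
#' never modified.
#'
#' @param net A trained `aoa_network`.
#' @param severity Fraction of hidden units to damage, in \[0,1\].
#' @param method `"zero_weights"` or `"add_noise"`.
#' @param noise_sd Standard deviation of the Gaussian perturbation
#'   (default 0.5, the half-width of the initial weight range).
#' @param seed Base seed of the lesion experiment.
#' @param sample_index Replicate number; each index selects an
#'   independent unit subset under the seeded stream.
#' @return A new `aoa_network` with the damage applied; the selected
#'   units are attached as attribute `lesioned_units`.
#' @export
lesion_network <- function(net, severity, method = c("zero_weights", "add_noise"),
                           noise_sd = 0.5, seed = 1L, sample_index = 1L) {
  method <- match.arg(method)
  if (severity < 0 || severity > 1)
    stop("severity must lie in [0, 1]")
  n_lesion <- floor(severity * net$n_hidden + 0.5)   # round half up
  if (n_lesion > net$n_hidden)
    stop("severity selects more units than the hidden layer holds")
  if (n_lesion == 0L) {
    attr(net, "lesioned_units") <- integer(0)
    return(net)
  }
  withr::with_seed(derive_seed(seed, 1000L + sample_index), {
    units <- sample.int(net$n_hidden, n_lesion)
    if (method == "zero_weights") {
      net$W_ih[units, ] <- 0
      net$b_h[units] <- 0
      net$W_ho[, units] <- 0
    } else {
      net$W_ih[units, ] <- net$W_ih[units, ] +
        stats::rnorm(length(units) * net$n_in, sd = noise_sd)
      net$b_h[units] <- net$b_h[units] +
        stats::rnorm(length(units), sd = noise_sd)
      net$W_ho[, units] <- net$W_ho[, units] +
        stats::rnorm(net$n_out * length(units), sd = noise_sd)
    }
  })
  attr(net, "lesioned_units") <- sort(units)
  net
}

#' Graded lesioning experiment
#'
#' For every severity x method x replicate cell, damages a copy of the
#' trained network with [lesion_network()] and scores every lexicon item
#' on it, contrasting the early-acquired against the late-acquired group.
#' Severity 0 rows reproduce the intact network's evaluation exactly.
#'
#' @param net A trained `aoa_network` (typically the output of a
#'   focused-then-interleaved protocol).
#' @param lexicon The `aoa_lexicon` the network was trained on.
#' @param early_ids,late_ids Word ids of the early- and late-acquired
#'   groups.
#' @param severities Numeric vector of damage fractions
#'   (default `c(0.05, 0.10, 0.20)`).
#' @param methods Character vector of lesion methods.
#' @param n_samples Replicates per cell (default 20).
#' @param noise_sd Gaussian perturbation scale for `add_noise`.
#' @param seed Seed for the replicate unit-selection streams.
#' @return An `aoa_lesion_result` list: `results` (per sample x method x
#'   severity x item: `sse`, `correct`) and `summary` (per method x
#'   severity x group: mean error across samples, plus the late-early
#'   `gap` per method x severity).
#' @export
run_lesion_experiment <- function(net, lexicon, early_ids, late_ids,
                                  severities = c(0.05, 0.10, 0.20),
                                  methods = c("zero_weights", "add_noise"),
                                  n_samples = 20L, noise_sd = 0.5,
                                  seed = 1L) {
  if (any(severities < 0 | severities > 1))
    stop("severity values must lie in [0, 1]")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  group <- ifelse(lexicon$word_id %in% early_ids, "early",
                  ifelse(lexicon$word_id %in% late_ids, "late", "other"))
  rows <- list(); k <- 0L
  for (method in methods) {
    for (sev in severities) {
      for (smp in seq_len(n_samples)) {
        lesioned <- lesion_network(net, sev, method, noise_sd = noise_sd,
                                   seed = derive_seed(seed, match(method, methods) * 100000L) ,
                                   sample_index = smp)
        res <- evaluate(lesioned, lexicon)
        k <- k + 1L
        rows[[k]] <- data.frame(sample = smp, method = method,
                                severity = sev, word_id = res$word_id,
                                grade = res$grade, group = group,
                                sse = res$sse, correct = res$correct,
                                stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  keep <- results$group != "other"
  agg <- stats::aggregate(sse ~ method + severity + group,
                          data = results[keep, ], FUN = mean)
  wide <- stats::reshape(agg, idvar = c("method", "severity"),
                         timevar = "group", direction = "wide")
  names(wide) <- sub("^sse\\.", "", names(wide))
  wide$gap <- wide$late - wide$early
  structure(list(results = results,
                 summary = wide[order(wide$method, wide$severity), ]),
            class = "aoa_lesion_result")
}
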