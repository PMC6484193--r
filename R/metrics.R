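#' Score every lexicon item with a clean forward pass
#'
#' Computes, per item, the summed squared error over the output units
#' against the 0/1 phonological target and whether the decoded
#' pronunciation (argmax per slot block, 0.5 blank threshold) equals the
#' target pronunciation.  No learning occurs.
#'
#' @param net An `aoa_network`.
#' @param lexicon An `aoa_lexicon` whose encoding matches the network's
#'   layer sizes.
#' @return Data frame `word_id`, `grade`, `frequency`, `consistency`,
#'   `sse`, `correct`.
#' @export
evaluate <- function(net, lexicon) {
  cfg <- attr(lexicon, "config")
  n_phonemes <- if (!is.null(cfg)) cfg$n_phonemes else net$n_out %/% 4L
  n_letters <- if (!is.null(cfg)) cfg$n_letters else net$n_in %/% 4L
  enc <- .encode_lexicon(lexicon, n_letters, n_phonemes)
  if (net$n_in != enc$n_in || net$n_out != enc$n_out)
    stop("network layer sizes do not match the lexicon encoding")
  H <- stats::plogis(net$W_ih %*% t(.dense_inputs(enc$x_idx, enc$n_in)) +
                       net$b_h)
  O <- stats::plogis(net$W_ho %*% H + net$b_o)
  sse <- colSums((O - t(enc$targets))^2)
  correct <- vapply(seq_len(nrow(lexicon)), function(i) {
    .same_slots(decode_phonology(O[, i], n_phonemes),
                item_pronunciation(lexicon, i))
  }, logical(1))
  data.frame(word_id = lexicon$word_id, grade = lexicon$grade,
             frequency = lexicon$frequency,
             consistency = lexicon$consistency,
             sse = sse, correct = correct, stringsAsFactors = FALSE)
}

#' Age-of-acquisition error gap
#'
#' `mean(error of late items) - mean(error of early items)`; positive
#' values mean the early-acquired group is read better.
#'
#' @param results Data frame with `word_id` and an error column.
#' @param early_ids,late_ids Disjoint, nonempty sets of word ids.
#' @param metric Name of the error column (default `"sse"`).
#' @return A single number.
#' @export
aoa_gap <- function(results, early_ids, late_ids, metric = "sse") {
  if (length(early_ids) == 0L || length(late_ids) == 0L)
    stop("both groups must be nonempty")
  if (length(intersect(early_ids, late_ids)) > 0L)
    stop("early and late groups must be disjoint")
  e <- results[[metric]][results$word_id %in% early_ids]
  l <- results[[metric]][results$word_id %in% late_ids]
  if (length(e) == 0L || length(l) == 0L)
    stop("results do not cover both groups")
  mean(l) - mean(e)
}

#' Per-grade error summary
#'
#' Count, arithmetic mean and sample standard deviation (n-1) of an
#' error column within each grade group, plus a totals row.
#'
#' @param results Data frame with `grade` and an error column.
#' @param metric Name of the error column (default `"sse"`).
#' @return Data frame `grade` (character; `"Total"` last), `n`, `mean`,
#'   `sd`.
#' @export
group_summary <- function(results, metric = "sse") {
  if (nrow(results) == 0L) stop("no results to summarise")
  v <- results[[metric]]
  grades <- sort(unique(results$grade))
  rows <- lapply(grades, function(g) {
    x <- v[results$grade == g]
    data.frame(grade = as.character(g), n = length(x),
               mean = mean(x), sd = stats::sd(x))
  })
  rows[[length(rows) + 1L]] <- data.frame(grade = "Total", n = length(v),
                                          mean = mean(v), sd = stats::sd(v))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Analysis of covariance on per-item errors
#'
#' Ordinary-least-squares item analysis of an error measure on frequency
#' and consistency covariates plus the grade-of-acquisition factor, with
#' sequential (Type-I) sums of squares in the order frequency,
#' consistency, grade — the covariates absorb their variance before the
#' acquisition factor is tested.  Each row's F is tested against the
#' residual mean square.  A polynomial linear-trend contrast over the
#' covariate-adjusted grade means is also reported.
#'
#' @param records Data frame with columns `error` (or the column named by
#'   `metric`) and `grade`; covariate columns `frequency` and
#'   `consistency` are used when present (a design without covariates
#'   reduces to a one-way analysis whose two-group F equals the squared
#'   pooled t statistic).
#' @param metric Error column name (default `"sse"`).
#' @return An `aoa_ancova` list: `table` (one row per covariate, then
#'   AoA and Error, with `SS`, `df`, `MS`, `F`, `p`), `linear_trend`
#'   (estimate, se, t, df, p), and the underlying `fit`.
#' @export
ancova <- function(records, metric = "sse") {
  for (cl in c(metric, "grade"))
    if (is.null(records[[cl]])) stop("records lack column '", cl, "'")
  covs <- intersect(c("frequency", "consistency"), names(records))
  d <- data.frame(error = records[[metric]], grade = factor(records$grade))
  for (cl in covs) d[[cl]] <- as.numeric(records[[cl]])
  g <- nlevels(d$grade)
  if (g < 2L) stop("grade must have at least 2 levels")
  if (nrow(d) <= g + length(covs) + 1L)
    stop("too few items for the design (need N > g + c + 1)")
  fml <- stats::reformulate(c(covs, "grade"), response = "error")
  fit <- stats::lm(fml, data = d)
  if (fit$rank < g + length(covs))
    stop("rank-deficient design: covariates are confounded with grade")
  an <- stats::anova(fit)                 # sequential (Type-I) SS
  k <- length(covs) + 1L                  # tested rows: covariates + grade
  tab <- data.frame(
    source = c(vapply(covs, tools::toTitleCase, character(1),
                      USE.NAMES = FALSE), "AoA", "Error"),
    SS = an$`Sum Sq`, df = an$Df, MS = an$`Mean Sq`,
    F = c(an$`F value`[seq_len(k)], NA),
    p = c(an$`Pr(>F)`[seq_len(k)], NA),
    stringsAsFactors = FALSE)

  # linear trend across adjusted grade means: polynomial contrast on the
  # grade effects, covariates held at their observed means
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  eff <- c(0, cf[paste0("grade", levels(d$grade)[-1])])  # ref level = 0
  w <- stats::contr.poly(g)[, 1]
  L <- numeric(length(cf)); names(L) <- names(cf)
  L[paste0("grade", levels(d$grade)[-1])] <- w[-1]
  est <- sum(w * eff)
  se <- sqrt(as.numeric(t(L) %*% V %*% L))
  tt <- est / se
  df_err <- stats::df.residual(fit)
  structure(list(table = tab,
                 linear_trend = list(estimate = est, se = se, t = tt,
                                     df = df_err,
                                     p = 2 * stats::pt(-abs(tt), df_err)),
                 fit = fit),
            class = "aoa_ancova")
}

#' @export
print.aoa_ancova <- function(x, ...) {
  cat("Analysis of covariance (sequential SS)\n")
  print(x$table, row.names = FALSE, digits = 4)
  lt <- x$linear_trend
  cat(sprintf("Linear trend over grades: est %.4f (se %.4f), t(%d) = %.3f, p = %.4g\n",
              lt$estimate, lt$se, lt$df, lt$t, lt$p))
  invisible(x)
}

#' Sigmoid-saturation (plasticity) diagnostics
#'
#' Mean absolute net input of the output units and mean logistic slope
#' `o(1-o)` over a set of items.  As training entrenches a mapping, net
#' inputs drift away from 0, the slope falls from its 0.25 maximum, and
#' later-arriving items receive smaller weight updates.
#'
#' @param net An `aoa_network`.
#' @param lexicon An `aoa_lexicon`.
#' @return List with `mean_abs_net_input` and `mean_slope`.
#' @export
plasticity_summary <- function(net, lexicon) {
  cfg <- attr(lexicon, "config")
  n_phonemes <- if (!is.null(cfg)) cfg$n_phonemes else net$n_out %/% 4L
  n_letters <- if (!is.null(cfg)) cfg$n_letters else net$n_in %/% 4L
  enc <- .encode_lexicon(lexicon, n_letters, n_phonemes)
  H <- stats::plogis(net$W_ih %*% t(.dense_inputs(enc$x_idx, enc$n_in)) +
                       net$b_h)
  NetO <- net$W_ho %*% H + net$b_o
  O <- stats::plogis(NetO)
  list(mean_abs_net_input = mean(abs(NetO)),
       mean_slope = mean(O * (1 - O)))
}
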