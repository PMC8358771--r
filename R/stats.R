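# Vectorised Welch machinery shared by welch_t() and power_simulation():
# given group means, variances and sizes, returns t, Welch-Satterthwaite
# df and the two-sided p-value. Degenerate pairs (both variances zero) get
# p = 1 when the means agree and p = 0 otherwise.
welch_stats <- function(ma, va, na, mb, vb, nb) {
  sa <- va / na; sb <- vb / nb
  se <- sqrt(sa + sb)
  t <- (ma - mb) / se
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  p <- 2 * pt(-abs(t), df)
  degen <- se == 0 | !is.finite(df)
  if (any(degen)) {
    eq <- degen & (ma == mb)
    t[degen] <- 0; df[degen] <- na + nb - 2
    p[eq] <- 1; p[degen & !eq] <- 0
    t[degen & !eq] <- sign(ma - mb)[degen & !eq] * Inf
  }
  list(t = t, df = df, p = p)
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. When both samples have zero variance the
#' convention is p = 1 for equal means (no evidence of difference) and
#' p = 0 otherwise.
#'
#' @param a,b numeric samples with at least 2 values each; at least one
#'   sample must have positive variance for a regular test.
#' @return An object of class `"htest"` with the t statistic, degrees of
#'   freedom (`parameter`) and `p.value`.
#' @examples
#' welch_t(c(10, 11, 12), c(1, 2, 3))
#' @export
welch_t <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  w <- welch_stats(mean(a), var(a), length(a), mean(b), var(b), length(b))
  structure(list(statistic = c(t = w$t), parameter = c(df = w$df),
                 p.value = w$p,
                 estimate = c(`mean of x` = mean(a), `mean of y` = mean(b)),
                 method = "Welch two-sample t-test",
                 data.name = paste(deparse(substitute(a)), "and",
                                   deparse(substitute(b)))),
            class = "htest")
}

#' Random-subsampling power simulation
#'
#' Repeatedly draws `sample_size` values per group and applies [welch_t()],
#' tallying how often the difference is nonsignificant (`p > alpha`). This
#' emulates the question "had only n images per surface been collected,
#' would the density difference have been detected?". Groups given as
#' numeric vectors are subsampled without replacement within each
#' repetition (draws are independent across repetitions); groups given as
#' generator functions `function(n)` produce fresh values each repetition.
#'
#' @param group_a,group_b numeric vectors (finite datasets to resample) or
#'   functions of `n` returning `n` fresh draws.
#' @param sample_size images drawn per group per repetition.
#' @param reps number of repetitions.
#' @param alpha significance level; "nonsignificant" is strictly
#'   `p > alpha`.
#' @param seed integer seed; results are reproducible given the seed.
#' @return A list of class `"power_sim"`: `n_nonsignificant`,
#'   `fraction_nonsignificant`, `reps`, `sample_size`, `alpha`.
#' @export
power_simulation <- function(group_a, group_b, sample_size, reps = 10000L,
                             alpha = 0.05, seed = 1L) {
  stopifnot(sample_size >= 2, reps >= 1, alpha > 0, alpha < 1)
  draw_matrix <- function(g) {
    if (is.function(g)) {
      matrix(g(sample_size * reps), nrow = sample_size)
    } else {
      stopifnot(is.numeric(g), length(g) >= sample_size)
      vapply(seq_len(reps),
             function(i) g[sample.int(length(g), sample_size)],
             numeric(sample_size))
    }
  }
  set.seed(seed)
  A <- draw_matrix(group_a)
  B <- draw_matrix(group_b)
  n <- sample_size
  ma <- colMeans(A); mb <- colMeans(B)
  va <- (colSums(A^2) - n * ma^2) / (n - 1)
  vb <- (colSums(B^2) - n * mb^2) / (n - 1)
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  w <- welch_stats(ma, va, n, mb, vb, n)
  n_ns <- sum(w$p > alpha)
  structure(list(n_nonsignificant = n_ns,
                 fraction_nonsignificant = n_ns / reps,
                 reps = as.integer(reps),
                 sample_size = as.integer(sample_size),
                 alpha = alpha, seed = as.integer(seed)),
            class = "power_sim")
}

#' @export
print.power_sim <- function(x, ...) {
  cat(sprintf(paste0("power_sim: %d of %d reps nonsignificant (%.2f%%) at ",
                     "n = %d, alpha = %g\n"),
              x$n_nonsignificant, x$reps, 100 * x$fraction_nonsignificant,
              x$sample_size, x$alpha))
  invisible(x)
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with the usual t-based two-sided p-value on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return An object of class `"htest"` with `estimate` (r), `parameter`
#'   (df) and `p.value`.
#' @examples
#' pearson_test(1:10, (1:10) * 2 + 1)
#' @export
pearson_test <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    stop("pearson_test requires nonzero variance in both samples")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- min(max(r, -1), 1)
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(t), df)
  }
  structure(list(estimate = c(cor = r), parameter = c(df = df),
                 p.value = p, method = "Pearson's product-moment correlation",
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}
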