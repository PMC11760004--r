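#' Welch two-sample t test between fineness groups
#'
#' Unequal-variance (Welch) t test with Welch–Satterthwaite degrees of
#' freedom and a two-sided p value, via [stats::t.test()].  Degenerate
#' inputs are resolved explicitly: if both groups have zero variance and
#' equal means the test is an exact tie (p = 1); if both variances are zero
#' but the means differ, the statistic diverges and p = 0 is reported with
#' a `degenerate` flag.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance Student test instead.
#' @return a `comparison_result` list: `test`, `statistic`, `df`,
#'   `p_value`, `group_means`, `degenerate`.
#' @export
welch_t <- function(a, b, var_equal = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    mf_stop("insufficient_sample", "each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      res <- list(statistic = 0, df = NA_real_, p_value = 1, degenerate = TRUE)
    } else {
      res <- list(statistic = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                  p_value = 0, degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value, degenerate = FALSE)
  }
  structure(c(list(test = if (var_equal) "student_t" else "welch_t"),
              res,
              list(group_means = c(a = mean(a), b = mean(b)))),
            class = "comparison_result")
}

#' One-way ANOVA across fineness groups
#'
#' Classical fixed-effects decomposition `F = MSB / MSW` with degrees of
#' freedom `(k - 1, N - k)`, via [stats::lm()] / [stats::anova()].
#'
#' @param groups named list of numeric vectors (>= 2 groups, each of
#'   length >= 2, with positive pooled within-group variance).
#' @return a `comparison_result` with `test = "anova"`, `statistic` (F),
#'   `df` (length 2), `p_value` and `group_means`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L)
    mf_stop("insufficient_sample", "ANOVA needs >= 2 groups")
  if (any(lengths(groups) < 2L))
    mf_stop("insufficient_sample", "each group needs >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  if (ssw == 0) mf_stop("zero_within_variance",
                        "all within-group variances are zero")
  tab <- stats::anova(stats::lm(y ~ g))
  structure(list(test = "anova",
                 statistic = tab[["F value"]][1],
                 df = c(tab$Df[1], tab$Df[2]),
                 p_value = tab[["Pr(>F)"]][1],
                 group_means = vapply(groups, mean, 0),
                 degenerate = FALSE),
            class = "comparison_result")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p_value))
  invisible(x)
}

#' Bootstrap percentile confidence interval of the mean
#'
#' Nonparametric bootstrap: `B` resamples with replacement, 95 percent
#' percentile interval of the resampled means.  Fully reproducible for a
#' fixed seed; the caller's RNG stream is left untouched.
#'
#' @param values numeric vector of length >= 2.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return a `bootstrap_ci` list: `point` (the sample mean), `lo`, `hi`,
#'   `B`, `seed`.
#' @export
bootstrap_ci <- function(values, B = 1000, seed = 1) {
  n <- length(values)
  if (n < 2L) mf_stop("insufficient_sample", "need >= 2 values")
  if (B < 1L) mf_stop("config", "B must be >= 1")
  means <- with_seed(seed, {
    draws <- matrix(values[sample.int(n, n * B, replace = TRUE)], nrow = n)
    colMeans(draws)
  })
  q <- unname(stats::quantile(means, c(0.025, 0.975)))
  structure(list(point = mean(values), lo = q[1], hi = q[2],
                 B = as.integer(B), seed = as.integer(seed)),
            class = "bootstrap_ci")
}

#' Step-size sweep for the F7 tile grid
#'
#' For each candidate step size, computes F7 for every image and the Welch
#' p value of the fine-versus-coarse contrast; the optimal step is the one
#' with the smallest p (ties to the smaller, cheaper grid).  This is the
#' selection rule that fixes the default step of 70 tiles per axis.
#'
#' @param masks list of `marbling_mask` objects (or logical fat matrices).
#' @param rois list of logical ROI matrices, parallel to `masks` (a single
#'   matrix is recycled).
#' @param labels character vector of fineness labels per image; only
#'   `"fine"` and `"coarse"` enter the contrast.
#' @param steps integer vector of step sizes (default `seq(5, 95, by = 5)`).
#' @param min_coverage tile inclusion threshold.
#' @return a `sweep_result` data frame with columns `step`, `p_value`, and
#'   attribute `optimal_step`; `f7` matrix (images x steps) in attribute
#'   `f7`.
#' @export
step_size_sweep <- function(masks, rois, labels, steps = seq(5L, 95L, by = 5L),
                            min_coverage = 0.5) {
  stopifnot(length(masks) == length(labels))
  if (!is.list(rois)) rois <- rep(list(rois), length(masks))
  fine <- labels == "fine"; coarse <- labels == "coarse"
  if (sum(fine) < 2L || sum(coarse) < 2L)
    mf_stop("insufficient_sample", "need >= 2 fine and >= 2 coarse images")
  steps <- sort(unique(as.integer(steps)))
  f7 <- matrix(NA_real_, nrow = length(masks), ncol = length(steps),
               dimnames = list(NULL, steps))
  for (i in seq_along(masks)) {
    for (j in seq_along(steps)) {
      grid <- tryCatch(
        build_tile_grid(masks[[i]], rois[[i]], steps[j], min_coverage),
        mf_error_invalid_step_size = function(e) {
          mf_stop("invalid_step_size", "image %d: %s", i, conditionMessage(e))
        })
      f7[i, j] <- compute_f7(grid)
    }
  }
  p <- vapply(seq_along(steps), function(j)
    welch_t(f7[fine, j], f7[coarse, j])$p_value, 0)
  out <- data.frame(step = steps, p_value = p)
  structure(out,
            optimal_step = steps[which.min(p)],   # first min = smallest step
            f7 = f7,
            class = c("sweep_result", "data.frame"))
}
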