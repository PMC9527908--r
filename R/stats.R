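#' Normality screening
#'
#' Shapiro-Wilk or (Lilliefors-corrected) Kolmogorov-Smirnov test of the null
#' that the values are normally distributed.
#'
#' @param values numeric vector (n >= 3 for Shapiro-Wilk, n >= 5 for KS).
#' @param method `"shapiro"` (default) or `"ks"`.
#' @return List with `statistic` and `p_value`.
#' @export
test_normality <- function(values, method = c("shapiro", "ks")) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("need at least 3 finite values")
  if (var(values) == 0) stop("degenerate input: values are constant")
  ht <- if (method == "shapiro") {
    shapiro.test(if (length(values) > 5000) values[seq_len(5000)] else values)
  } else {
    nortest::lillie.test(values)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Choose a normalizing transform
#'
#' Identity if normality is not rejected at `alpha`; otherwise the first of
#' log10 and square root whose transformed values pass the normality test;
#' otherwise log10 with a warning. Non-positive values rule out the candidate
#' transforms, which is logged in the decision trace.
#'
#' @param values numeric vector.
#' @param alpha significance level for the normality screen (default 0.05).
#' @param method normality test, see [test_normality()].
#' @return `"identity"`, `"log10"` or `"sqrt"`, with attribute `"trace"`
#'   describing the decision path.
#' @export
choose_transform <- function(values, alpha = 0.05, method = "shapiro") {
  trace <- character()
  p0 <- test_normality(values, method)$p_value
  trace <- c(trace, sprintf("identity: normality p = %.4g", p0))
  if (p0 >= alpha)
    return(structure("identity", trace = trace))
  if (all(values > 0)) {
    for (tr in c("log10", "sqrt")) {
      tv <- if (tr == "log10") log10(values) else sqrt(values)
      p <- test_normality(tv, method)$p_value
      trace <- c(trace, sprintf("%s: normality p = %.4g", tr, p))
      if (p >= alpha) return(structure(tr, trace = trace))
    }
  } else {
    trace <- c(trace, "non-positive values: log10/sqrt candidates skipped")
  }
  warning("no transform normalizes the data; falling back to log10")
  trace <- c(trace, "fallback: log10")
  structure("log10", trace = trace)
}

apply_transform <- function(values, transform) {
  switch(transform,
         identity = values,
         log10 = { if (any(values <= 0)) stop("log10 transform needs positive values"); log10(values) },
         sqrt = { if (any(values < 0)) stop("sqrt transform needs non-negative values"); sqrt(values) },
         stop("unknown transform: ", transform))
}

#' Mean and standard error
#'
#' @param values numeric vector (n >= 1).
#' @return List with `mean` and `se` (`NA` for n = 1).
#' @export
summarize_mean_se <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1L) stop("no finite values to summarize")
  list(mean = mean(values),
       se = if (length(values) > 1L) sd(values) / sqrt(length(values)) else NA_real_)
}

#' Paired t-test
#'
#' Two-sided paired t-test; used for before/after comparisons such as
#' ejection fraction at baseline versus eight weeks post-infarct. The mean
#' difference is reported as `before - after` (a positive value is a
#' reduction).
#'
#' @param before,after numeric vectors of equal length (n >= 2).
#' @return List with `mean_difference`, `p_value`, `n`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) stop("before/after length mismatch")
  if (length(before) < 2L) stop("need at least 2 pairs")
  d <- before - after
  if (all(d == d[1])) {
    # constant differences: the t statistic is undefined (sd 0); for all-zero
    # differences there is no evidence against the null
    p <- if (d[1] == 0) 1 else 0
    return(list(mean_difference = d[1], p_value = p, n = length(d)))
  }
  ht <- t.test(before, after, paired = TRUE)
  list(mean_difference = unname(ht$estimate), p_value = ht$p.value,
       n = length(d))
}
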