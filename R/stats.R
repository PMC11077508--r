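#' Add-one-corrected empirical p-value
#'
#' Tail probability of an observed value against a finite null sample, with
#' the add-one correction `p = (1 + #extreme) / (1 + n_null)` so a finite
#' ensemble never reports p = 0; the attainable floor is `1 / (n_null + 1)`.
#' The two-sided p is twice the smaller tail, capped at 1.
#'
#' @param observed A single observed value.
#' @param null_values Numeric vector of null values (length >= 1).
#' @param direction `"two.sided"`, `"greater"` or `"less"`.
#' @return A p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed,
                        null_values,
                        direction = c("two.sided", "greater", "less")) {
  direction <- match.arg(direction)
  if (length(null_values) < 1) stop("empty null sample", call. = FALSE)
  n <- length(null_values)
  p_greater <- (1 + sum(null_values >= observed)) / (1 + n)
  p_less <- (1 + sum(null_values <= observed)) / (1 + n)
  switch(direction,
         greater = p_greater,
         less = p_less,
         two.sided = min(1, 2 * min(p_greater, p_less)))
}

#' Permutation-based paired t test
#'
#' Sign-flip permutation test of matched samples: the test statistic is the
#' paired t statistic of the differences, and the null distribution is built
#' by randomly flipping the sign of each difference. P-values carry the
#' add-one correction, so with 10,000 permutations the smallest attainable
#' two-sided p is 1/10,001. Set `exact = TRUE` to enumerate all `2^n` sign
#' patterns instead of sampling (feasible for small n).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param n_perm Number of random sign-flip permutations (default 10,000).
#' @param seed Optional seed.
#' @param exact Enumerate all sign patterns instead of sampling.
#' @return A one-row tibble: `statistic` (paired t), `p_value`, `n`,
#'   `n_perm`, `method`.
#' @export
permutation_paired_test <- function(x, y, n_perm = 10000, seed = NULL,
                                    exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  d <- x - y
  n <- length(d)
  t_of <- function(dd) {
    s <- stats::sd(dd)
    if (s == 0) 0 else mean(dd) / (s / sqrt(n))
  }
  t_obs <- t_of(d)
  if (all(d == 0)) {
    return(tibble::tibble(statistic = 0, p_value = 1, n = n,
                          n_perm = 0L, method = "degenerate (all ties)"))
  }
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_perm <- apply(signs, 1, function(s) t_of(d * s))
    # exact: observed pattern is one of the enumerated ones, no add-one
    p <- mean(abs(t_perm) >= abs(t_obs) - 1e-12)
    return(tibble::tibble(statistic = t_obs, p_value = p, n = n,
                          n_perm = nrow(signs),
                          method = "exact sign-flip enumeration"))
  }
  if (!is.null(seed)) set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
  flipped <- signs * rep(d, each = n_perm)
  means <- rowMeans(flipped)
  sds <- sqrt((rowSums(flipped^2) - n * means^2) / (n - 1))
  t_perm <- ifelse(sds == 0, 0, means / (sds / sqrt(n)))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  tibble::tibble(statistic = t_obs, p_value = p, n = n, n_perm = n_perm,
                 method = "sign-flip permutation")
}

#' Hedges' g effect size
#'
#' Standardized mean difference with pooled SD and the small-sample
#' correction factor `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return A single number; `NA` (with a warning) when the pooled variance
#'   is zero.
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each sample needs at least 2 values",
                             call. = FALSE)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) {
    warning("zero pooled variance; effect size undefined")
    return(NA_real_)
  }
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * (mean(x) - mean(y)) / sqrt(sp2)
}
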