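# Sub-organismal (within-host) selection estimators.
#
# The headline statistic is the per-generation shift Delta f = adult_f -
# parent_f, paired strictly within lineage (the isolation design exists to
# exclude organismal competition), regressed on the parental frequency.

#' Per-generation frequency shift from a lineage table
#'
#' @param table A `lineage_table` (see [simulate_lineages]) or data.frame
#'   with `parent_f` and `adult_f` columns.
#' @return data.frame with columns `parent_f`, `delta_f` (one row per
#'   lineage; rows with missing `adult_f` are skipped with a warning).
#' @examples
#' per_generation_shift(data.frame(parent_f = 0.60, adult_f = 0.65))$delta_f
#' @export
per_generation_shift <- function(table) {
  if (!all(c("parent_f", "adult_f") %in% names(table)))
    stop("table must have parent_f and adult_f columns", call. = FALSE)
  if (nrow(table) == 0) stop("table is empty", call. = FALSE)
  drop <- !is.finite(table$adult_f) | !is.finite(table$parent_f)
  if (any(drop)) {
    warning(sum(drop), " row(s) without adult_f skipped", call. = FALSE)
    table <- table[!drop, , drop = FALSE]
  }
  data.frame(parent_f = table$parent_f,
             delta_f = table$adult_f - table$parent_f)
}

# closed-form OLS of y on x; returns c(intercept, slope)
.ols <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(my - b * mx, b)
}

# vectorised bootstrap OLS over resampled row index matrix (n x n_boot)
.boot_ols <- function(x, y, n_boot, seed) {
  n <- length(x)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n); yb <- matrix(y[idx], nrow = n)
    mx <- colMeans(xb); my <- colMeans(yb)
    sxy <- colSums(xb * yb) - n * mx * my
    sxx <- colSums(xb * xb) - n * mx * mx
    b <- sxy / sxx
    cbind(a = my - b * mx, b = b)
  })
}

#' Fit the within-host shift function
#'
#' Ordinary least squares of the per-generation shift on parental frequency,
#' `Delta f = a + b f`, with percentile bootstrap confidence intervals
#' obtained by resampling whole lineages (the exchangeable unit). When the
#' slope is negative the within-host equilibrium `f* = -a / b` (the
#' frequency at which the proliferation advantage vanishes) is reported with
#' its bootstrap interval.
#'
#' @param pairs Output of [per_generation_shift] (or any data.frame with
#'   `parent_f`, `delta_f`).
#' @param n_boot Bootstrap replicates (default 2000).
#' @param seed Integer seed for the bootstrap.
#' @param level Confidence level (default 0.95).
#' @return A `shift_fit` object: `a_hat`, `b_hat`, `ci_a`, `ci_b`,
#'   `f_star`, `ci_f_star` (NULL when `b_hat >= 0`), `n`.
#' @examples
#' f <- seq(0.4, 0.8, length.out = 10)
#' fit <- fit_shift_function(data.frame(parent_f = f, delta_f = 0.155 - 0.2 * f))
#' c(fit$a_hat, fit$b_hat, fit$f_star)
#' @export
fit_shift_function <- function(pairs, n_boot = 2000, seed = 1, level = 0.95) {
  x <- pairs$parent_f; y <- pairs$delta_f
  if (length(x) < 3) stop("need at least 3 lineage pairs", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate design: parental frequencies are all identical",
         call. = FALSE)
  co <- .ols(x, y)
  bo <- .boot_ols(x, y, n_boot, seed)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  fit <- list(a_hat = co[1], b_hat = co[2],
              ci_a = unname(stats::quantile(bo[, "a"], probs, na.rm = TRUE)),
              ci_b = unname(stats::quantile(bo[, "b"], probs, na.rm = TRUE)),
              f_star = NULL, ci_f_star = NULL, n = length(x),
              n_boot = n_boot, level = level)
  if (co[2] < 0) {
    fit$f_star <- -co[1] / co[2]
    fs <- -bo[, "a"] / bo[, "b"]
    fs <- fs[bo[, "b"] < 0]
    if (length(fs) >= 2)
      fit$ci_f_star <- unname(stats::quantile(fs, probs, na.rm = TRUE))
  }
  structure(fit, class = "shift_fit")
}

#' @export
print.shift_fit <- function(x, ...) {
  cat("<shift_fit> n =", x$n, "\n")
  cat(sprintf("  intercept a = %.4f  [%.4f, %.4f]\n", x$a_hat, x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  slope     b = %.4f  [%.4f, %.4f]\n", x$b_hat, x$ci_b[1], x$ci_b[2]))
  if (!is.null(x$f_star))
    cat(sprintf("  equilibrium f* = %.4f%s\n", x$f_star,
                if (!is.null(x$ci_f_star))
                  sprintf("  [%.4f, %.4f]", x$ci_f_star[1], x$ci_f_star[2]) else ""))
  invisible(x)
}

#' Paired stage contrast with a sign-flip permutation test
#'
#' Mean within-lineage difference between two stage columns (e.g. the
#' parent-to-embryo purifying shift), with a two-sided p-value from random
#' sign flips of the paired differences. Exact-zero differences are flipped
#' like any other value.
#'
#' @param table A `lineage_table`.
#' @param stage_from,stage_to Column names among `parent_f`, `embryo_f`,
#'   `l4_f`, `adult_f`; the contrast is `stage_to - stage_from`.
#' @param n_perm Sign-flip permutations (>= 999).
#' @param seed Integer seed.
#' @return List with `mean_diff`, `p_value`, `n`.
#' @export
stage_contrast <- function(table, stage_from = "parent_f", stage_to = "embryo_f",
                           n_perm = 9999, seed = 1) {
  if (!all(c(stage_from, stage_to) %in% names(table)))
    stop("missing stage column(s)", call. = FALSE)
  if (n_perm < 999) stop("n_perm must be >= 999", call. = FALSE)
  d <- table[[stage_to]] - table[[stage_from]]
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 5) warning("fewer than 5 lineages: p-value has little resolution",
                     call. = FALSE)
  obs <- mean(d)
  perm <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n)
    colMeans(signs * d)
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-15)) / (n_perm + 1)
  list(mean_diff = obs, p_value = p, n = n)
}

#' Compare two shift fits by label permutation
#'
#' Permutation analogue of an analysis of covariance: the observed
#' difference in OLS intercept and slope between two sets of
#' (parent, shift) pairs is compared against a null built by permuting
#' condition labels across lineages.
#'
#' @param pairs_a,pairs_b Outputs of [per_generation_shift].
#' @param n_perm Label permutations.
#' @param seed Integer seed.
#' @return List with `d_intercept`, `d_slope` (A minus B), `p_intercept`,
#'   `p_slope` (two-sided).
#' @export
compare_shift_fits <- function(pairs_a, pairs_b, n_perm = 1999, seed = 1) {
  for (p in list(pairs_a, pairs_b))
    if (nrow(p) < 3 || stats::sd(p$parent_f) == 0)
      stop("degenerate set: need >= 3 pairs with varying parent_f", call. = FALSE)
  ca <- .ols(pairs_a$parent_f, pairs_a$delta_f)
  cb <- .ols(pairs_b$parent_f, pairs_b$delta_f)
  obs <- ca - cb
  na <- nrow(pairs_a)
  x <- c(pairs_a$parent_f, pairs_b$parent_f)
  y <- c(pairs_a$delta_f, pairs_b$delta_f)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      ia <- sample.int(length(x), na)
      pa <- .ols(x[ia], y[ia]); pb <- .ols(x[-ia], y[-ia])
      pa - pb
    }, numeric(2))
  })
  list(d_intercept = obs[1], d_slope = obs[2],
       p_intercept = (1 + sum(abs(perm[1, ]) >= abs(obs[1]) - 1e-15)) / (n_perm + 1),
       p_slope = (1 + sum(abs(perm[2, ]) >= abs(obs[2]) - 1e-15)) / (n_perm + 1))
}
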