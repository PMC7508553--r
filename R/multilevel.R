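# Integration of the two selection levels: equilibrium balance, forecast
# trajectories of non-competing populations, and condition ranking.

#' Equilibrium frequency balancing within-host gain and host-level costs
#'
#' Stationary mean of the deterministic mean-field recursion: parents are
#' spread around the population mean `m` (normal with sd `spread`, the
#' maintained between-sibling heteroplasmy dispersion), reproduce with
#' weight `brood_rate(f) * maturation_probability(f)`, and their offspring
#' gain `a + b f` within the host. With all costs switched off the recursion
#' is linear and the fixed point is the within-host equilibrium
#' `f* = -a / b` exactly; costs pull the balance below f*. Solved by fixed
#' point iteration (tolerance 1e-6, cap 1e4) with a dense-grid bisection
#' fallback; 0 is returned when no interior fixed point exists, `f_max`
#' when the gain is unopposed (`b >= 0`, `a > 0`).
#'
#' @param shift_fit A [fit_shift_function] result, or a list with `a_hat`,
#'   `b_hat`.
#' @param fecundity List with `base`, `theta`, `cost` (see
#'   [condition_preset]); `cost = 0` switches fecundity weighting off.
#' @param delay List with `slope`.
#' @param spread Between-individual sd of parent frequencies (default: the
#'   stationary sibling spread of the default generator).
#' @param f_max Heteroplasmy ceiling.
#' @param tol,max_iter Fixed-point tolerance and iteration cap.
#' @return The stationary mean frequency (scalar).
#' @examples
#' equilibrium_balance(list(a_hat = 0.155, b_hat = -0.2),
#'                     fecundity = list(cost = 0), delay = list(slope = 0))
#' @export
equilibrium_balance <- function(shift_fit,
                                fecundity = list(base = 6, theta = 0.60, cost = 0.94),
                                delay = list(slope = 0.5),
                                spread = 0.048, f_max = 0.90,
                                tol = 1e-6, max_iter = 1e4) {
  a <- shift_fit$a_hat; b <- shift_fit$b_hat
  stopifnot(is.finite(a), is.finite(b))
  cost <- fecundity$cost %||% 0
  dslope <- delay$slope %||% 0
  if (b >= 0) {
    if (a > 0) return(f_max)      # unopposed gain: ceiling reported
    if (a <= 0) return(0)
  }
  f_star <- -a / b
  no_costs <- (cost == 0 && dslope == 0)
  if (no_costs) return(clamp(f_star, 0, f_max))
  wp <- condition_preset("balance",
                         shift_a = a, shift_b = b,
                         fecundity_base = fecundity$base %||% 6,
                         fecundity_theta = fecundity$theta %||% 0.60,
                         fecundity_cost = cost, delay_slope = dslope,
                         f_max = f_max)
  grid <- seq(0, f_max, by = 1e-3)
  w <- .census_weight(grid, wp)
  gain <- a + b * grid
  Tmap <- function(m) {
    phi <- stats::dnorm(grid, m, spread) * w
    tot <- sum(phi)
    if (tot <= 0) return(0)
    clamp(sum(phi * (grid + gain)) / tot, 0, f_max)
  }
  m <- clamp(f_star, 0, f_max)
  for (i in seq_len(max_iter)) {
    m_new <- Tmap(m)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  # bisection fallback on h(m) = T(m) - m over a dense grid
  ms <- seq(0, f_max, by = 1e-3)
  h <- vapply(ms, function(x) Tmap(x) - x, numeric(1))
  sgn <- sign(h)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) {
    if (all(h <= 0)) return(0)
    stop("fixed-point iteration did not converge and no sign change found; ",
         "h range [", signif(min(h), 3), ", ", signif(max(h), 3), "]",
         call. = FALSE)
  }
  lo <- ms[flip[1]]; hi <- ms[flip[1] + 1]
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if ((Tmap(mid) - mid) * (Tmap(lo) - lo) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Predict the trajectory of non-competing populations under a preset
#'
#' Monte-Carlo mean frequency of non-competing (heteroplasmic-only)
#' replicate populations, normalised to the generation-0 mean so the
#' trajectory starts at exactly 1. The net per-generation selection under
#' the condition is the least-squares slope of the normalised means — the
#' net readout combining sub-organismal gain and host-level costs.
#'
#' @param preset A [condition_preset] or preset name.
#' @param generations Number of generations (>= 1).
#' @param n_rep Replicate populations.
#' @param seed Integer root seed.
#' @param carry_n Census size per replicate.
#' @return A `net_prediction`: `condition`, `trajectory` (data.frame
#'   `generation`, `mean_f`, `normalized`), `net_slope`.
#' @export
predict_trajectory <- function(preset, generations = 8, n_rep = 20, seed = 1,
                               carry_n = 200) {
  if (is.character(preset)) preset <- condition_presets(preset)
  stopifnot(inherits(preset, "condition_preset"), generations >= 1)
  sim <- simulate_competition(n_lines = n_rep, generations = generations,
                              carry_n = carry_n, preset = preset,
                              competed = FALSE, seed = seed)
  agg <- tapply(sim$pooled_f, sim$generation, mean)
  gen <- as.integer(names(agg))
  mean_f <- as.vector(agg)
  normalized <- mean_f / mean_f[gen == 0]
  slope <- .ols(gen, normalized)[2]
  structure(list(condition = preset$name,
                 trajectory = data.frame(generation = gen,
                                         mean_f = mean_f,
                                         normalized = normalized),
                 net_slope = slope),
            class = "net_prediction")
}

#' @export
print.net_prediction <- function(x, ...) {
  cat("<net_prediction>", x$condition,
      sprintf("net slope %.4f per generation over %d generations\n",
              x$net_slope, max(x$trajectory$generation)))
  invisible(x)
}

#' Rank conditions by net selection against the deletion genome
#'
#' Conditions sorted by net slope ascending, so rank 1 is the strongest net
#' selection against the mutant genome (most negative slope). Ties are
#' broken by the final-generation normalised mean, then by label.
#'
#' @param predictions List of [predict_trajectory] results on a common
#'   generation span.
#' @return data.frame `condition`, `net_slope`, `final_value`, `rank`
#'   (rank 1 = strongest selection against).
#' @export
rank_conditions <- function(predictions) {
  if (length(predictions) < 1) stop("need at least one prediction", call. = FALSE)
  stopifnot(all(vapply(predictions, inherits, TRUE, "net_prediction")))
  spans <- vapply(predictions, function(p) max(p$trajectory$generation), 0)
  if (length(unique(spans)) != 1)
    stop("predictions cover different generation spans", call. = FALSE)
  d <- data.frame(
    condition = vapply(predictions, `[[`, "", "condition"),
    net_slope = vapply(predictions, `[[`, 0, "net_slope"),
    final_value = vapply(predictions, function(p)
      p$trajectory$normalized[which.max(p$trajectory$generation)], 0))
  o <- order(d$net_slope, d$final_value, d$condition)
  d <- d[o, , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}
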