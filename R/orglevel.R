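# Organismal (between-host) selection estimators.
#
# The competition design isolates selection acting on whole animals: the
# pooled frequency of each competed line is normalised to the mean of the
# non-competed (heteroplasmic-only) lines at each generation, which removes
# the shared sub-organismal dynamics; whatever slope remains is attributable
# to the presence of homoplasmic-wildtype competitors.

#' Normalise competed lines to the non-competed reference
#'
#' @param competed,noncompeted `competition_table`s covering the same
#'   generation range; `noncompeted` must contribute at least one line per
#'   generation.
#' @param mode `"ratio"` (default) divides by the per-generation
#'   non-competed mean; `"difference"` subtracts it. Self-normalising the
#'   non-competed set yields a per-generation mean of exactly 1 (ratio) or 0
#'   (difference).
#' @return data.frame with `line_id`, `generation`, `value` (plus
#'   `mode` attribute). Terminated rows are carried through; lines
#'   contribute up to their last observed generation.
#' @examples
#' nc <- data.frame(line_id = 1, generation = 0:1, pooled_f = c(0.6, 0.6))
#' co <- data.frame(line_id = 1, generation = 0:1, pooled_f = c(0.30, 0.24))
#' normalize_to_noncompeted(co, nc)$value # 0.50, 0.40
#' @export
normalize_to_noncompeted <- function(competed, noncompeted,
                                     mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  for (tb in list(competed, noncompeted))
    if (!all(c("line_id", "generation", "pooled_f") %in% names(tb)))
      stop("tables need line_id, generation, pooled_f columns", call. = FALSE)
  gens <- sort(unique(competed$generation))
  if (!all(gens %in% noncompeted$generation))
    stop("non-competed table does not cover every generation", call. = FALSE)
  ref <- tapply(noncompeted$pooled_f, noncompeted$generation, mean)
  if (any(!is.finite(ref)) || any(ref == 0 & mode == "ratio"))
    stop("non-competed mean is zero or missing at some generation: cannot normalize",
         call. = FALSE)
  r <- ref[as.character(competed$generation)]
  value <- if (mode == "ratio") competed$pooled_f / r else competed$pooled_f - r
  out <- data.frame(line_id = competed$line_id,
                    generation = competed$generation, value = unname(value))
  structure(out, mode = mode)
}

#' Fit the organismal decline of normalised frequency
#'
#' Least-squares regression of the normalised value on generation, pooled
#' across replicate lines, with a bootstrap over lines for the slope
#' interval (bootstrap-t: slope +/- t_{L-1} x bootstrap sd, which calibrates
#' better than a percentile interval at the small numbers of replicate lines
#' used here). The organismal selection coefficient `s_org` is derived from
#' the fitted per-generation relative decline via a log-linear fit:
#' `s_org = 1 - exp(slope_log)`.
#'
#' @param trajectory Output of [normalize_to_noncompeted].
#' @param n_boot Bootstrap replicates over lines.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return An `org_fit` object: `slope_hat`, `ci`, `s_org`, `n_lines`,
#'   `trajectory`.
#' @export
fit_org_decline <- function(trajectory, n_boot = 2000, seed = 1, level = 0.95) {
  if (length(unique(trajectory$generation)) < 2)
    stop("need at least 2 generations", call. = FALSE)
  co <- .ols(trajectory$generation, trajectory$value)
  lines <- unique(trajectory$line_id)
  bslopes <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    pick <- sample(lines, length(lines), replace = TRUE)
    d <- do.call(rbind, lapply(pick, function(l)
      trajectory[trajectory$line_id == l, , drop = FALSE]))
    if (length(unique(d$generation)) < 2) return(NA_real_)
    .ols(d$generation, d$value)[2]
  }, numeric(1)))
  se <- stats::sd(bslopes, na.rm = TRUE)
  tq <- stats::qt(1 - (1 - level) / 2, df = max(length(lines) - 1, 1))
  pos <- trajectory$value > 0
  if (!all(pos)) warning(sum(!pos), " non-positive value(s) dropped from log-linear fit",
                         call. = FALSE)
  s_org <- if (sum(pos) >= 2 && length(unique(trajectory$generation[pos])) >= 2)
    1 - exp(.ols(trajectory$generation[pos], log(trajectory$value[pos]))[2])
  else NA_real_
  structure(list(slope_hat = co[2], intercept_hat = co[1],
                 ci = c(co[2] - tq * se, co[2] + tq * se),
                 s_org = s_org, n_lines = length(lines),
                 trajectory = trajectory, level = level),
            class = "org_fit")
}

#' @export
print.org_fit <- function(x, ...) {
  cat("<org_fit>", x$n_lines, "lines\n")
  cat(sprintf("  slope per generation = %.4f  [%.4f, %.4f]\n",
              x$slope_hat, x$ci[1], x$ci[2]))
  cat(sprintf("  s_org (log-linear)   = %.4f\n", x$s_org))
  invisible(x)
}

#' Heteroplasmic-fraction trajectories and endpoint contrast
#'
#' Per-line series of the fraction of deletion-carrying individuals in
#' competed lines. If a reference table is supplied, the endpoint contrast
#' (mean fraction at the common final generation divided by the reference
#' mean) is attached as attribute `endpoint_contrast` — the normalisation
#' used to compare conditions at a fixed generation.
#'
#' @param table Competed `competition_table`.
#' @param reference Optional competed `competition_table` of the reference
#'   condition.
#' @return data.frame `line_id`, `generation`, `het_fraction`; rows with
#'   zero genotyped individuals become `NA` with a warning.
#' @export
fraction_trajectory <- function(table, reference = NULL) {
  if (!all(c("line_id", "generation", "het_fraction", "n_genotyped") %in% names(table)))
    stop("not a competition table", call. = FALSE)
  if ("competed" %in% names(table) && !all(table$competed))
    stop("fraction trajectories are defined for competed tables only", call. = FALSE)
  out <- data.frame(line_id = table$line_id, generation = table$generation,
                    het_fraction = table$het_fraction)
  bad <- table$n_genotyped == 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with zero genotyped individuals set to NA", call. = FALSE)
    out$het_fraction[bad] <- NA_real_
  }
  if (!is.null(reference)) {
    g <- min(max(out$generation), max(reference$generation))
    num <- mean(out$het_fraction[out$generation == g], na.rm = TRUE)
    den <- mean(reference$het_fraction[reference$generation == g], na.rm = TRUE)
    attr(out, "endpoint_generation") <- g
    attr(out, "endpoint_contrast") <- num / den
  }
  out
}

#' Organismal selection coefficient from heteroplasmic-fraction series
#'
#' For each generation step the relative fitness of heteroplasmic animals is
#' the odds ratio `w_t = odds(p_{t+1}) / odds(p_t)` (haploid-selection
#' bookkeeping on whole animals); `s_org = 1 - geometric mean of w_t` across
#' all steps of all lines. Steps with `p` in `{0, 1}` are skipped (odds
#' undefined) with a log message. The confidence interval bootstraps lines.
#'
#' @param fractions Output of [fraction_trajectory] (or data.frame with
#'   `line_id`, `generation`, `het_fraction`).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return List: `s_org`, `ci`, `n_steps`, `n_skipped`.
#' @examples
#' fr <- data.frame(line_id = 1, generation = 0:1, het_fraction = c(0.5, 0.4))
#' estimate_s_org(fr)$s_org # 1/3
#' @export
estimate_s_org <- function(fractions, n_boot = 2000, seed = 1, level = 0.95) {
  step_logw <- function(d) {
    d <- d[order(d$generation), ]
    p0 <- d$het_fraction[-nrow(d)]; p1 <- d$het_fraction[-1]
    ok <- is.finite(p0) & is.finite(p1) & p0 > 0 & p0 < 1 & p1 > 0 & p1 < 1
    list(logw = log(p1[ok] / (1 - p1[ok])) - log(p0[ok] / (1 - p0[ok])),
         skipped = sum(!ok))
  }
  by_line <- split(fractions, fractions$line_id)
  steps <- lapply(by_line, step_logw)
  logw <- unlist(lapply(steps, `[[`, "logw"))
  n_skip <- sum(vapply(steps, `[[`, 0, "skipped"))
  if (n_skip > 0) ml_log(n_skip, " step(s) with p in {0,1} skipped")
  if (length(logw) < 1)
    stop("need fractions in (0,1) for at least 2 consecutive generations",
         call. = FALSE)
  s_hat <- 1 - exp(mean(logw))
  ids <- names(by_line)
  bo <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    pick <- sample(ids, length(ids), replace = TRUE)
    lw <- unlist(lapply(steps[pick], `[[`, "logw"))
    if (length(lw) < 1) return(NA_real_)
    1 - exp(mean(lw))
  }, numeric(1)))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  list(s_org = s_hat,
       ci = unname(stats::quantile(bo, probs, na.rm = TRUE)),
       n_steps = length(logw), n_skipped = n_skip)
}
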