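#' Draw a stock population of heteroplasmic adults
#'
#' Frequencies are drawn from a symmetric truncated normal on
#' `[mean_f - spread, mean_f + spread]` (sd `spread / 2`, so the support is a
#' +/- 2 sd window). Symmetric truncation keeps the distribution mean exactly
#' at `mean_f`. Defaults reproduce the laboratory stock that stably carries
#' the deletion genome in the 50-80% range with a population mean near 60%.
#'
#' @param n Number of individuals (>= 1).
#' @param mean_f Mean heteroplasmy frequency, in (0, 1).
#' @param spread Half-width of the support; the support must fit in `[0, 1]`.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Numeric vector of `n` frequencies.
#' @examples
#' f <- make_stock_population(1000, seed = 1)
#' abs(mean(f) - 0.60) < 0.02
#' @export
make_stock_population <- function(n, mean_f = 0.60, spread = 0.15, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (mean_f <= 0 || mean_f >= 1) stop("mean_f must lie in (0, 1)", call. = FALSE)
  if (spread < 0 || mean_f - spread < 0 || mean_f + spread > 1)
    stop("support [mean_f - spread, mean_f + spread] must fit in [0, 1]",
         call. = FALSE)
  n <- as.integer(n)
  if (spread == 0) return(rep(mean_f, n))
  lo <- mean_f - spread; hi <- mean_f + spread; sdv <- spread / 2
  with_seed(seed, {
    plo <- stats::pnorm(lo, mean_f, sdv)
    phi <- stats::pnorm(hi, mean_f, sdv)
    stats::qnorm(stats::runif(n, plo, phi), mean_f, sdv)
  })
}

#' Transmit heteroplasmy through the germline bottleneck
#'
#' The embryo inherits `X / B` where `X ~ Binomial(B, clamp(f_parent +
#' delta_embryo, 0, 1))`: a finite sample of `B` segregating mtDNA units,
#' after the deterministic purifying shift `delta_embryo` (non-positive on
#' plentiful diets, zero under diet restriction). `B = Inf` returns the
#' expectation (no drift), useful for deterministic propagation checks.
#'
#' @param f_parent Parental frequency (vectorised), each in `[0, 1]`.
#' @param B Bottleneck size (>= 1), or `Inf`.
#' @param delta_embryo Signed parent-to-embryo shift.
#' @param seed Optional integer seed.
#' @return Embryo frequencies, same length as `f_parent`.
#' @examples
#' transmit_bottleneck(0, B = 100)              # absorbing boundary
#' transmit_bottleneck(0.6, Inf, -0.03)         # expectation 0.57
#' @export
transmit_bottleneck <- function(f_parent, B = 800, delta_embryo = 0, seed = NULL) {
  if (any(f_parent < 0 | f_parent > 1)) stop("f_parent must lie in [0, 1]", call. = FALSE)
  if (length(B) != 1 || is.na(B) || B < 1) stop("B must be >= 1", call. = FALSE)
  p <- clamp(f_parent + delta_embryo)
  if (!is.finite(B)) return(p)
  B <- as.integer(round(B))
  with_seed(seed, stats::rbinom(length(p), B, p) / B)
}

#' Develop an embryo to a later stage within its host
#'
#' Across development the mutant genome proliferates with a frequency
#' dependent, affine expected gain: a full development to adulthood maps an
#' embryo at `f` to `clamp(f + a + b f + eps, 0, f_max)` with
#' `eps ~ Normal(0, shift_sd)` (between-individual noise). `stage_frac`
#' scales the accrued fraction of the developmental gain (and its noise
#' variance) for intermediate larval stages; `stage_frac = 1` is a mature
#' adult. A frequency of exactly 0 stays 0: there is no de novo mutation.
#'
#' @param f_embryo Embryo frequencies in `[0, 1]` (vectorised).
#' @param preset A [condition_preset] supplying `shift_a`, `shift_b`,
#'   `shift_sd` and `f_max`.
#' @param stage_frac Fraction of the developmental gain accrued, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return Frequencies after development, in `[0, f_max]`.
#' @examples
#' p <- condition_preset("x", shift_a = 0.155, shift_b = -0.20)
#' develop_within_host(0.50, p) # 0.555 (shift_sd = 0)
#' @export
develop_within_host <- function(f_embryo, preset, stage_frac = 1, seed = NULL) {
  stopifnot(inherits(preset, "condition_preset"))
  if (any(f_embryo < 0 | f_embryo > 1)) stop("f_embryo must lie in [0, 1]", call. = FALSE)
  stopifnot(stage_frac >= 0, stage_frac <= 1)
  with_seed(seed, {
    eps <- if (preset$shift_sd > 0)
      stats::rnorm(length(f_embryo), 0, preset$shift_sd * sqrt(stage_frac))
    else 0
    out <- clamp(f_embryo + stage_frac * (preset$shift_a + preset$shift_b * f_embryo) + eps,
                 0, preset$f_max)
    out[f_embryo == 0] <- 0
    out
  })
}

#' Fecundity as a function of heteroplasmy frequency
#'
#' Viable progeny per hour: constant at `fecundity_base` below
#' `fecundity_theta`, declining along a logistic ramp (width
#' `ramp_width`) to `fecundity_base * (1 - fecundity_cost)` above it, and 0
#' at or above the heteroplasmy ceiling `f_max`. Monotone non-increasing.
#'
#' @param f Frequencies in `[0, 1]` (vectorised).
#' @param preset A [condition_preset].
#' @param ramp_width Logistic ramp width in frequency units.
#' @return Progeny per hour (same length as `f`).
#' @export
brood_rate <- function(f, preset, ramp_width = 0.012) {
  stopifnot(inherits(preset, "condition_preset"))
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  ramp <- stats::plogis((f - preset$fecundity_theta) / ramp_width)
  out <- preset$fecundity_base * (1 - preset$fecundity_cost * ramp)
  out[f >= preset$f_max] <- 0
  out
}

#' Probability of reaching the adult-competent L4 stage by census time
#'
#' Development slows with mutant frequency; the probability that an embryo
#' laid at the start of a cycle is an adult-competent L4 by census declines
#' linearly with `delay_slope`, from 1 at frequency 0 (the wildtype
#' normalisation).
#'
#' @inheritParams brood_rate
#' @return Probabilities in `[0, 1]`.
#' @export
maturation_probability <- function(f, preset) {
  stopifnot(inherits(preset, "condition_preset"))
  if (any(f < 0 | f > 1)) stop("f must lie in [0, 1]", call. = FALSE)
  clamp(1 - preset$delay_slope * f)
}

#' Copy-number hitchhiking
#'
#' The host maintains the wildtype genome at its setpoint `W` regardless of
#' the mutant; mutant copies accumulate on top, so `n_mut = round(W f /
#' (1 - f))` and the implied total `W / (1 - f)` is strictly increasing in f.
#'
#' @param f Frequencies in `[0, 1)` (vectorised).
#' @param W Wildtype copy-number setpoint (> 0).
#' @return A data.frame with columns `n_wt`, `n_mut`.
#' @examples
#' copy_number(0.75, 100) # 100 wildtype + 300 mutant copies
#' @export
copy_number <- function(f, W) {
  if (any(f < 0 | f >= 1)) stop("f must lie in [0, 1): total copy number diverges at 1",
                                call. = FALSE)
  if (W <= 0) stop("W must be > 0", call. = FALSE)
  data.frame(n_wt = rep(round(W), length(f)), n_mut = round(W * f / (1 - f)))
}

# effective reproductive weight at census
.census_weight <- function(f, preset) {
  brood_rate(f, preset) * maturation_probability(f, preset)
}

#' Simulate isolated parent-progeny lineages
#'
#' Emulates the lineage-isolation design used to measure sub-organismal
#' selection with organismal competition excluded: each lineage is one parent
#' drawn from the stock model, whose progeny are sampled at three stages
#' (embryo, L4, day-2 adult). At each stage `pool_size` same-parent progeny
#' are pooled and the pool-mean frequency recorded, emulating a pooled
#' lysate. Lineages are statistically independent and seeded hierarchically,
#' so increasing `n_lineages` does not perturb existing lineages.
#'
#' @param n_lineages Number of lineages (>= 1).
#' @param preset A [condition_preset] (default `wt_live`).
#' @param pool_size Progeny pooled per stage lysate (default 3).
#' @param seed Integer root seed.
#' @param mean_f,spread Stock model parameters for the parents.
#' @param l4_frac Fraction of the developmental gain accrued by L4.
#' @param weighted_pool If `TRUE`, pool lysate values are weighted by total
#'   per-individual mtDNA copy number (template fraction of the mixed
#'   lysate) instead of the unweighted mean.
#' @return A `lineage_table`: data.frame with columns `lineage_id`,
#'   `parent_f`, `embryo_f`, `l4_f`, `adult_f`, with the preset name and
#'   pool size in attributes.
#' @export
simulate_lineages <- function(n_lineages, preset = condition_presets("wt_live"),
                              pool_size = 3, seed = 1,
                              mean_f = 0.60, spread = 0.15, l4_frac = 0.6,
                              weighted_pool = FALSE) {
  stopifnot(inherits(preset, "condition_preset"))
  if (n_lineages < 1) stop("n_lineages must be >= 1", call. = FALSE)
  if (pool_size < 1) stop("pool_size must be >= 1", call. = FALSE)
  pool_mean <- function(f) {
    if (!weighted_pool) return(mean(f))
    cn <- copy_number(pmin(f, preset$f_max), preset$wt_setpoint)
    tot <- cn$n_wt + cn$n_mut
    sum(f * tot) / sum(tot)
  }
  rows <- lapply(seq_len(n_lineages), function(i) {
    set.seed(child_seed(seed, i))
    parent_f <- make_stock_population(1, mean_f, spread)
    stage_pool <- function(stage_frac) {
      emb <- transmit_bottleneck(rep(parent_f, pool_size), preset$bottleneck,
                                 preset$delta_embryo)
      if (stage_frac == 0) return(pool_mean(emb))
      pool_mean(develop_within_host(emb, preset, stage_frac))
    }
    data.frame(lineage_id = i, parent_f = parent_f,
               embryo_f = stage_pool(0), l4_f = stage_pool(l4_frac),
               adult_f = stage_pool(1))
  })
  out <- do.call(rbind, rows)
  structure(out, preset = preset$name, pool_size = pool_size,
            class = c("lineage_table", "data.frame"))
}

#' Simulate a replicate competition (or non-competed control) line
#'
#' Emulates the experimental-evolution design used to measure organismal
#' selection: discrete, non-overlapping generations of a census of
#' `carry_n` animals. A competed line starts as a mix of heteroplasmic and
#' homoplasmic-wildtype animals (`init_het_fraction` heteroplasmic); a
#' non-competed line starts entirely heteroplasmic. Each generation, every
#' adult contributes offspring in proportion to `brood_rate(f) *
#' maturation_probability(f)`; `carry_n` offspring are sampled to found the
#' next generation, each inheriting frequency via [transmit_bottleneck] and
#' [develop_within_host]. Recorded per line and generation: the pooled
#' population frequency (individual-mean frequency, emulating the pooled
#' mixed-age lysate) and the heteroplasmic fraction among `genotype_sample`
#' randomly drawn adults.
#'
#' @param n_lines Number of replicate lines.
#' @param generations Number of propagation steps (rows cover generations
#'   `0:generations`).
#' @param carry_n Census size per generation (>= 10).
#' @param init_het_fraction Initial heteroplasmic fraction for competed
#'   lines; non-competed lines always start at 1.
#' @param preset A [condition_preset].
#' @param competed Logical flag.
#' @param genotype_sample Adults genotyped individually per census
#'   (default 48).
#' @param seed Integer root seed (hierarchically split per line).
#' @param mean_f,spread Stock model for the founding heteroplasmic animals.
#' @return A `competition_table`: data.frame with columns `line_id`,
#'   `generation`, `competed`, `pooled_f`, `het_fraction`, `n_genotyped`,
#'   `terminated`; preset name and `carry_n` in attributes. A line whose
#'   members all fail to reproduce is recorded as terminated from that
#'   generation on.
#' @export
simulate_competition <- function(n_lines = 8, generations = 10, carry_n = 500,
                                 init_het_fraction = 0.5,
                                 preset = condition_presets("wt_live"),
                                 competed = TRUE, genotype_sample = 48,
                                 seed = 1, mean_f = 0.60, spread = 0.15) {
  stopifnot(inherits(preset, "condition_preset"))
  if (carry_n < 10) stop("carry_n must be >= 10", call. = FALSE)
  if (generations < 1) stop("generations must be >= 1", call. = FALSE)
  if (init_het_fraction < 0 || init_het_fraction > 1)
    stop("init_het_fraction must lie in [0, 1]", call. = FALSE)
  rows <- lapply(seq_len(n_lines), function(l) {
    set.seed(child_seed(seed, l))
    n_het <- if (competed) round(carry_n * init_het_fraction) else carry_n
    f <- c(make_stock_population(n_het, mean_f, spread),
           rep(0, carry_n - n_het))
    rec <- vector("list", generations + 1L)
    terminated <- FALSE
    for (t in 0:generations) {
      k <- min(genotype_sample, length(f))
      geno <- if (k > 0) sample(f, k) else numeric(0)
      rec[[t + 1L]] <- data.frame(
        line_id = l, generation = t, competed = competed,
        pooled_f = mean(f),
        het_fraction = if (k > 0) mean(geno > 0) else NA_real_,
        n_genotyped = k, terminated = terminated)
      if (t == generations) break
      w <- .census_weight(f, preset)
      if (!any(w > 0)) {
        # all members fail to reproduce: line ends here, flagged
        ml_log("line ", l, " terminated at generation ", t)
        rec[[t + 1L]]$terminated <- TRUE
        terminated <- TRUE
        break
      }
      par_f <- f[sample.int(length(f), carry_n, replace = TRUE, prob = w)]
      emb <- transmit_bottleneck(par_f, preset$bottleneck, preset$delta_embryo)
      f <- develop_within_host(emb, preset)
    }
    do.call(rbind, rec)
  })
  out <- do.call(rbind, rows)
  structure(out, preset = preset$name, carry_n = carry_n,
            class = c("competition_table", "data.frame"))
}
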