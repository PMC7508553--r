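#' Droplet classification counts for one duplex ddPCR reaction
#'
#' @param n_neg,n_wt_only,n_mut_only,n_double Droplets containing neither
#'   template, wildtype only, mutant only, or both.
#' @return A `droplet_counts` object; the four classes partition `n_total`.
#' @export
droplet_counts <- function(n_neg, n_wt_only, n_mut_only, n_double) {
  counts <- c(n_neg = n_neg, n_wt_only = n_wt_only,
              n_mut_only = n_mut_only, n_double = n_double)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("droplet counts must be non-negative integers", call. = FALSE)
  n_total <- sum(counts)
  if (n_total < 1) stop("n_total must be >= 1", call. = FALSE)
  structure(as.list(c(n_total = n_total, counts)), class = "droplet_counts")
}

#' @export
print.droplet_counts <- function(x, ...) {
  cat("<droplet_counts> total:", x$n_total,
      "| neg:", x$n_neg, "wt:", x$n_wt_only,
      "mut:", x$n_mut_only, "double:", x$n_double, "\n")
  invisible(x)
}

#' Forward model: partition templates into droplets
#'
#' Wildtype and mutant template counts per droplet are independent
#' `Poisson(conc * droplet_vol)`; a droplet is positive for a channel when at
#' least one template of that channel is present, so the four class
#' probabilities are products of the independent presence probabilities
#' `1 - exp(-lambda)`. An optional per-channel misclassification rate flips
#' presence calls, for robustness analyses (0 by default: the forward model
#' replaces amplitude-cluster calling with exact class labels).
#'
#' @param conc_wt,conc_mut Template concentrations (copies/uL), >= 0.
#' @param n_droplets Accepted droplets (default 20000).
#' @param droplet_vol Droplet volume in uL (default 0.85 nL).
#' @param seed Optional integer seed.
#' @param misclass_rate Probability that a presence/absence call is flipped,
#'   per channel.
#' @return A [droplet_counts] object.
#' @examples
#' simulate_droplets(0, 0, 1000, seed = 1) # all negative
#' @export
simulate_droplets <- function(conc_wt, conc_mut, n_droplets = 20000,
                              droplet_vol = 0.00085, seed = NULL,
                              misclass_rate = 0) {
  if (conc_wt < 0 || conc_mut < 0) stop("concentrations must be >= 0", call. = FALSE)
  if (n_droplets < 1) stop("n_droplets must be >= 1", call. = FALSE)
  if (droplet_vol <= 0) stop("droplet_vol must be > 0", call. = FALSE)
  p_wt <- 1 - exp(-conc_wt * droplet_vol)
  p_mut <- 1 - exp(-conc_mut * droplet_vol)
  if (misclass_rate > 0) {
    p_wt <- p_wt * (1 - misclass_rate) + (1 - p_wt) * misclass_rate
    p_mut <- p_mut * (1 - misclass_rate) + (1 - p_mut) * misclass_rate
  }
  probs <- c((1 - p_wt) * (1 - p_mut), p_wt * (1 - p_mut),
             (1 - p_wt) * p_mut, p_wt * p_mut)
  cls <- with_seed(seed, stats::rmultinom(1, as.integer(n_droplets), probs))
  droplet_counts(cls[1], cls[2], cls[3], cls[4])
}

#' Poisson-corrected quantification of a duplex reaction
#'
#' Mean copies per droplet follow from the negative fraction of each
#' channel: `lambda_wt = -log((n_neg + n_mut_only) / n_total)` and
#' symmetrically for the mutant channel. The mutant frequency
#' `lambda_mut / (lambda_wt + lambda_mut)` is invariant to dilution and
#' volume bookkeeping. Per-individual copies account for the dilution
#' factor, lysis volume and number of individuals in the lysate.
#'
#' @param counts A [droplet_counts].
#' @param droplet_vol Droplet volume (uL).
#' @param dilution Lysate dilution factor (see [ddpcr_dilutions]).
#' @param lysis_vol Lysis volume (uL).
#' @param n_individuals Animals in the lysate.
#' @return A `quant_result` list: `lambda_wt`, `lambda_mut`, `freq`,
#'   `conc_wt`, `conc_mut` (copies/uL in the diluted reaction), and
#'   `copies_per_individual_wt` / `_mut`.
#' @examples
#' q <- quantify_droplets(droplet_counts(5000, 5000, 0, 0))
#' all.equal(q$lambda_wt, log(2))
#' @export
quantify_droplets <- function(counts, droplet_vol = 0.00085, dilution = 1,
                              lysis_vol = 1, n_individuals = 1) {
  stopifnot(inherits(counts, "droplet_counts"))
  n <- counts$n_total
  neg_wt <- counts$n_neg + counts$n_mut_only   # droplets without wildtype
  neg_mut <- counts$n_neg + counts$n_wt_only   # droplets without mutant
  if (neg_wt == 0 || neg_mut == 0)
    stop("saturated channel (no negative droplets): estimate unbounded",
         call. = FALSE)
  lambda_wt <- -log(neg_wt / n)
  lambda_mut <- -log(neg_mut / n)
  tot <- lambda_wt + lambda_mut
  scale <- dilution * lysis_vol / droplet_vol / n_individuals
  structure(list(
    lambda_wt = lambda_wt, lambda_mut = lambda_mut,
    freq = if (tot > 0) lambda_mut / tot else NA_real_,
    conc_wt = lambda_wt / droplet_vol, conc_mut = lambda_mut / droplet_vol,
    copies_per_individual_wt = lambda_wt * scale,
    copies_per_individual_mut = lambda_mut * scale),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result> lambda_wt:", signif(x$lambda_wt, 4),
      "lambda_mut:", signif(x$lambda_mut, 4),
      "freq:", signif(x$freq, 4), "\n")
  invisible(x)
}

#' Call an individually lysed animal heteroplasmic
#'
#' True when at least `min_mut_droplets` droplets contain mutant template.
#' The default threshold of 3 bounds the false-positive rate far below the
#' 1/48 resolution of the per-census genotyping sample.
#'
#' @param counts A [droplet_counts].
#' @param min_mut_droplets Minimum mutant-positive droplets (default 3).
#' @return Logical flag.
#' @export
call_heteroplasmic <- function(counts, min_mut_droplets = 3) {
  stopifnot(inherits(counts, "droplet_counts"))
  (counts$n_mut_only + counts$n_double) >= min_mut_droplets
}

#' Measure a frequency through the ddPCR forward model
#'
#' Convenience wrapper used by the pipeline's measurement layer: a true
#' frequency is converted to channel concentrations at a total mean
#' occupancy `lambda_total` copies/droplet, droplets are simulated, and the
#' Poisson-corrected frequency returned.
#'
#' @param f True mutant frequencies (vectorised).
#' @param n_droplets Droplets per reaction.
#' @param lambda_total Total mean copies per droplet (wildtype + mutant).
#' @param droplet_vol Droplet volume (uL).
#' @param seed Optional integer root seed (split per reaction).
#' @return Measured frequencies.
#' @export
measure_frequency <- function(f, n_droplets = 20000, lambda_total = 1,
                              droplet_vol = 0.00085, seed = NULL) {
  vapply(seq_along(f), function(i) {
    s <- if (is.null(seed)) NULL else child_seed(seed, i)
    cts <- simulate_droplets(lambda_total * (1 - f[i]) / droplet_vol,
                             lambda_total * f[i] / droplet_vol,
                             n_droplets, droplet_vol, seed = s)
    quantify_droplets(cts, droplet_vol)$freq
  }, numeric(1))
}
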