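# Shared fixtures, built in code.

# neutral dynamics: no purifying shift, (numerically) no frequency dependence,
# no noise, no fitness costs
neutral_preset <- function(bottleneck = 800, shift_sd = 0) {
  condition_preset("neutral", delta_embryo = 0, shift_a = 0, shift_b = -1e-9,
                   shift_sd = shift_sd, fecundity_cost = 0, delay_slope = 0,
                   bottleneck = bottleneck)
}

# flat organismal cost c for every heteroplasmic member: theta = 0.2 puts the
# whole logistic ramp below the frequencies visited, so the effective
# reproductive deficit of a heteroplasmic animal equals c exactly
flat_cost_preset <- function(cost, bottleneck = 800) {
  condition_preset("flat_cost", delta_embryo = 0, shift_a = 0, shift_b = -1e-9,
                   shift_sd = 0, fecundity_cost = cost, fecundity_theta = 0.2,
                   delay_slope = 0, bottleneck = bottleneck)
}

# deterministic preset: affine gain with no noise, infinite bottleneck
exact_preset <- function(a, b, delta = 0) {
  condition_preset("exact", delta_embryo = delta, shift_a = a, shift_b = b,
                   shift_sd = 0, bottleneck = Inf)
}

tiny_lineage_table <- function() {
  data.frame(lineage_id = 1:3,
             parent_f = c(0.50, 0.60, 0.70),
             embryo_f = c(0.47, 0.57, 0.67),
             l4_f = c(0.50, 0.59, 0.68),
             adult_f = c(0.56, 0.64, 0.71))
}
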