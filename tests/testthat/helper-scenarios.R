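# Test scenario builders shared across files.

# collapse every range of a parameter set to its degenerate midpoint [m, m]
degenerate_at_midpoints <- function(params) {
  out <- rapply(unclass(params), function(r) rep(mean(r), 2L), how = "replace")
  class(out) <- "ivf_parameters"
  out
}

# all stage events certain, ICSI share zero, every cost pinned at the
# reference midpoint: the one-path program costing 3505 in the myo-Ins arm
certain_success_midpoint_costs <- function() {
  degenerate_at_midpoints(degenerate_scenario("certain_success"))
}

# the hand-summed item total of the forced all-certain IVF path (myo-Ins arm):
# stimulation 1400 + other hormones 200 + monitoring 145 + consultations 130
# + pickup 1000 + pickup ultrasound 30 + IVF lab 450 + catheter 150
FORCED_IVF_PATH_COST <- 3505
# fixed pre-pickup items only (myo-Ins arm)
FORCED_PREPICKUP_COST <- 1875
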