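#' Connor-Stevens axon-hillock parameters
#'
#' The canonical published parameter set for the Connor-Stevens point
#' neuron (sodium, delayed-rectifier potassium and transient A-type
#' potassium channels), read from the versioned configuration file shipped
#' at `inst/params/connor_stevens.yaml`. The A-current gives the model its
#' type-I (continuous-from-zero) f-I curve, which is why it is the spike
#' generator of choice for all OSNs, PNs and LNs here.
#'
#' @param overrides named list of values replacing entries of the canonical
#'   set.
#' @return Named list of parameters (conductances mS/cm^2, potentials mV,
#'   capacitance uF/cm^2, spike detection threshold and lockout).
#' @export
connor_stevens_params <- function(overrides = list()) {
  path <- system.file("params", "connor_stevens.yaml", package = "antennalobe")
  p <- yaml::read_yaml(path)
  p[names(overrides)] <- overrides
  p
}

#' Model parameter set for circuit composition and simulation
#'
#' Collects every tunable constant of the executable model in one nested
#' list: the Connor-Stevens set (`cs`), the odorant transduction cascade
#' (`otp`), synapse kinetics and unit conductances (`syn`), and the
#' presynaptic terminal modulation (`presyn`).
#'
#' Units: time constants ms, conductances mS/cm^2, currents uA/cm^2,
#' potentials mV. `syn$g_unit` scales one synapse; an edge of `count`
#' synapses has peak conductance `g_unit * count`. Motif port edges use
#' per-partner default counts (`count_osn_port`, `count_pn_port`,
#' `count_ln3`): counts per partner are higher where partners are few, as
#' in glomerular innervation. `presyn$kappa_unit` likewise scales per
#' synapse, and the divisive terminal gain is `1 / (1 + kappa * s)` with
#' `s` the alpha-filtered LN spike train.
#'
#' @param overrides named list of nested overrides, e.g.
#'   `list(syn = list(g_unit = 1e-3))`.
#' @return Nested parameter list of class `al_params`.
#' @export
al_params <- function(overrides = list()) {
  p <- list(
    cs = connor_stevens_params(),
    otp = list(
      i_max = 120,      # uA/cm^2, ceiling of the transduction current
      k_half = 0.25,    # half-saturation of the current map
      gamma_adapt = 1.0,# adaptation gain on the bound fraction
      tau_act = 10,     # ms, fast activation low-pass
      tau_adapt = 500   # ms, slow adaptation state
    ),
    syn = list(
      tau_exc = 5,      # ms, excitatory alpha-synapse time-to-peak
      tau_inh = 10,     # ms, inhibitory alpha-synapse time-to-peak
      e_exc = 0,        # mV
      e_inh = -80,      # mV
      g_unit = 6e-4,        # mS/cm^2 peak conductance per synapse
      count_osn_port = 12,  # synapses per OSN partner at ports i/ii
      count_pn_port = 120,  # synapses per PN partner at ports iii/iv
      count_ln3 = 400       # synapses per LN partner on LN3 edges
    ),
    presyn = list(
      tau = 100,        # ms, alpha filter of the LN spike train
      kappa_unit = 0.02 # divisive strength per synapse
    )
  )
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(p[[nm]])) {
      p[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      p[[nm]] <- overrides[[nm]]
    }
  }
  class(p) <- "al_params"
  p
}
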