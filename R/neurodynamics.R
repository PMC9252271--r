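#' Odorant transduction process state
#'
#' The transduction cascade has three states per OSN: the bound-receptor
#' fraction `x` (exact first-order binding kinetics
#' `dx/dt = b*u*(1 - x) - d*x`), a fast activation low-pass `v` tracking
#' `x`, and a slow adaptation state `a` tracking `gamma * x`. The output
#' current is the saturating map
#' `I = i_max * v / (v + k_half * (1 + a))`, which is monotone increasing
#' and saturating in the concentration-modulated affinity `(b/d)*u`.
#'
#' @param x,v,a initial state values (all in `[0, 1]` for `x`; `v`, `a`
#'   nonnegative).
#' @return List of class `otp_state` with fields `x`, `v`, `a`, `current`.
#' @export
otp_state <- function(x = 0, v = 0, a = 0) {
  stopifnot(x >= 0, x <= 1, v >= 0, a >= 0)
  s <- list(x = x, v = v, a = a, current = 0)
  class(s) <- "otp_state"
  s
}

#' Advance the odorant transduction state by one time step
#'
#' The binding stage is advanced exactly (exponential update toward its
#' fixed point `b*u/(b*u + d)` at rate `b*u + d`, valid for `u` constant
#' over the step); the activation and adaptation low-passes use the
#' exponential-Euler update. `x` therefore stays in `[0, 1]` for any step
#' size.
#'
#' @param state an [otp_state()].
#' @param b binding rate (1/(concentration*s)).
#' @param d dissociation rate (1/s).
#' @param u odorant concentration over the step, `>= 0`.
#' @param dt time step in ms, `> 0`.
#' @param params the `otp` block of [al_params()].
#' @return The advanced `otp_state`, with `current` the output current
#'   (uA/cm^2).
#' @export
otp_step <- function(state, b, d, u, dt, params = al_params()$otp) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (u < 0) stop("concentration must be nonnegative", call. = FALSE)
  if (d <= 0) stop("dissociation rate must be positive", call. = FALSE)
  bu <- b * u / 1000  # per ms
  dd <- d / 1000
  rate <- bu + dd
  x_inf <- if (rate > 0) bu / rate else state$x
  x <- x_inf + (state$x - x_inf) * exp(-rate * dt)
  v <- state$x + (state$v - state$x) * exp(-dt / params$tau_act)
  a_inf <- params$gamma_adapt * state$x
  a <- a_inf + (state$a - a_inf) * exp(-dt / params$tau_adapt)
  out <- otp_state(x = x, v = v, a = a)
  out$current <- params$i_max * v / (v + params$k_half * (1 + a))
  out
}

#' Steady-state transduction current
#'
#' Closed-form fixed point of the transduction cascade under constant
#' concentration: the bound fraction settles at
#' `x* = b*u / (b*u + d) = A / (A + 1)` with affinity `A = (b/d)*u`, the
#' activation at `x*`, the adaptation at `gamma * x*`, giving
#' `I = i_max * x* / (x* * (1 + k_half * gamma) + k_half)` -- strictly
#' increasing in `A` and saturating at large `A`.
#'
#' @param b,d,u binding rate, dissociation rate (`> 0`), constant
#'   concentration (`>= 0`). Vectorized.
#' @param params the `otp` block of [al_params()].
#' @return Steady-state current (uA/cm^2).
#' @export
otp_steady_current <- function(b, d, u, params = al_params()$otp) {
  if (any(d <= 0)) stop("dissociation rate must be positive", call. = FALSE)
  A <- (b / d) * u
  x <- A / (A + 1)
  params$i_max * x / (x * (1 + params$k_half * params$gamma_adapt) +
                        params$k_half)
}

#' Integrate a Connor-Stevens neuron under a prescribed input current
#'
#' Fixed-step integration (exponential Euler on the membrane and on all
#' gating variables) of the Connor-Stevens point neuron. Spikes are
#' detected as upward crossings of the configured threshold (default 0 mV)
#' with a minimum inter-spike interval of 2 ms. The integration is fully
#' deterministic.
#'
#' @param current input current: a single number (constant), a function of
#'   time (ms), or a numeric vector sampled at `dt` steps.
#' @param dt step in ms, `> 0`.
#' @param duration total time in ms.
#' @param params [connor_stevens_params()].
#' @param record_v return the membrane trajectory (default `TRUE`).
#' @return List with `spike_times` (ms), and when recorded `t` and `v`.
#' @export
connor_stevens_integrate <- function(current, dt = 0.01, duration = 1000,
                                     params = connor_stevens_params(),
                                     record_v = TRUE) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  n_steps <- as.integer(round(duration / dt))
  if (is.function(current)) {
    ivec <- current((seq_len(n_steps) - 1) * dt)
  } else if (length(current) == 1L) {
    ivec <- rep(as.numeric(current), n_steps)
  } else {
    ivec <- as.numeric(current)
    if (length(ivec) < n_steps) stop("current vector too short", call. = FALSE)
    ivec <- ivec[seq_len(n_steps)]
  }
  res <- cs_integrate_cpp(ivec, dt, params, record_v)
  if (!record_v) res$v <- NULL else res$t <- (seq_len(n_steps) - 1) * dt
  res
}

#' Connor-Stevens f-I curve
#'
#' Steady-state firing rate as a function of constant input current,
#' measured over the trailing half of each run.
#'
#' @param currents numeric vector of constant currents (uA/cm^2).
#' @param dt,duration integration step and run length (ms).
#' @param params [connor_stevens_params()].
#' @return Data frame with `current` and `rate_hz`.
#' @export
connor_stevens_fi <- function(currents, dt = 0.01, duration = 2000,
                              params = connor_stevens_params()) {
  rate <- vapply(currents, function(I) {
    r <- connor_stevens_integrate(I, dt, duration, params, record_v = FALSE)
    steady_state_rate(r$spike_times / 1000, duration / 2000, duration / 1000)
  }, numeric(1))
  data.frame(current = currents, rate_hz = rate)
}

#' Alpha-synapse conductance waveform
#'
#' Sampled conductance of the alpha synapse: each presynaptic spike at
#' `t_s` contributes `g_max * ((t - t_s)/tau) * exp(1 - (t - t_s)/tau)` for
#' `t >= t_s`, so a single spike peaks exactly at `t_s + tau` with value
#' `g_max`, and overlapping spikes superpose linearly. The synaptic current
#' onto the postsynaptic neuron is `g(t) * (e_rev - V_post)`.
#'
#' @param spike_times sorted presynaptic spike times (ms).
#' @param t_grid increasing sample times (ms).
#' @param g_max peak conductance per spike, `>= 0`.
#' @param tau time-to-peak in ms, `> 0`.
#' @return Numeric conductance at each `t_grid` point.
#' @export
alpha_synapse_conductance <- function(spike_times, t_grid, g_max, tau) {
  if (is.unsorted(spike_times)) {
    stop("spike times must be sorted", call. = FALSE)
  }
  if (g_max < 0 || tau <= 0) stop("need g_max >= 0 and tau > 0", call. = FALSE)
  g <- numeric(length(t_grid))
  for (ts in spike_times) {
    dtau <- (t_grid - ts) / tau
    g <- g + ifelse(dtau >= 0, g_max * dtau * exp(1 - dtau), 0)
  }
  g
}

#' Divisive presynaptic gain at the OSN axon terminal
#'
#' LN spiking, low-pass filtered through an alpha kernel into the activity
#' variable `s`, divisively scales the OSN terminal's feedforward
#' conductance: `gain = 1 / (1 + kappa * s)`. The gain is 1 with no LN
#' activity or with modulation disabled (`kappa = 0`) and decreases
#' monotonically toward 0 as `s` grows.
#'
#' @param s_ln filtered LN activity, `>= 0` (vectorized).
#' @param kappa modulation strength, `>= 0`.
#' @return Gain in `(0, 1]`.
#' @export
presynaptic_gain <- function(s_ln, kappa) {
  if (any(s_ln < 0) || any(kappa < 0)) {
    stop("s_ln and kappa must be nonnegative", call. = FALSE)
  }
  1 / (1 + kappa * s_ln)
}
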