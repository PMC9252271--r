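#' Simulation configuration
#'
#' @param dt integration step in ms (default 0.01; all neurons share one
#'   global step).
#' @param duration run length in seconds (default 4).
#' @param window trailing steady-state window in seconds (default 1), must
#'   not exceed `duration`.
#' @param seed random seed recorded for reproducibility (the core engine
#'   is deterministic; the seed covers stochastic extensions).
#' @param record_v record membrane trajectories.
#' @param record_dt trace sampling interval in ms when recording.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.01, duration = 4, window = 1,
                              seed = NULL, record_v = FALSE,
                              record_dt = 1) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (window > duration) {
    stop("steady-state window must not exceed duration", call. = FALSE)
  }
  structure(list(dt = dt, duration = duration, window = window,
                 seed = seed, record_v = record_v, record_dt = record_dt),
            class = "simulation_config")
}

#' Steady-state firing rate of a spike train
#'
#' Spike count in the trailing window divided by the window length.
#'
#' @param spike_train spike times in seconds.
#' @param window trailing window length in seconds.
#' @param duration run duration in seconds, `>= window`.
#' @return Rate in Hz.
#' @export
steady_state_rate <- function(spike_train, window, duration) {
  if (window > duration) {
    stop("window must not exceed duration", call. = FALSE)
  }
  sum(spike_train > duration - window & spike_train <= duration) / window
}

# build per-OSN (b, d, u-waveform) drive arrays for the engine
resolve_drive <- function(circuit, env, stimulus, drive, config) {
  nn <- circuit$neurons
  n <- nrow(nn)
  b <- numeric(n); d <- rep(1, n)
  n_ms <- ceiling(config$duration * 1000) + 1L
  u <- matrix(0, n_ms, n)
  t_s <- (seq_len(n_ms) - 1) / 1000
  osn_idx <- which(nn$class == "OSN")
  if (!is.null(drive)) {
    for (i in osn_idx) {
      r <- nn$receptor[i]
      if (!r %in% names(drive)) next
      b[i] <- 1; d[i] <- 1
      u[, i] <- drive[[r]]  # b = d, so u equals the affinity value
    }
  } else if (!is.null(env) && !is.null(stimulus)) {
    target <- attr(stimulus, "target") %||%
      names(stimulus)[vapply(stimulus, function(w)
        any(sample_waveform(w, t_s) > 0), logical(1))][1L]
    if (is.na(target) || is.null(target)) target <- names(stimulus)[1L]
    receptors <- unique(nn$receptor[osn_idx])
    missing <- setdiff(receptors, env$receptor_labels)
    if (length(missing) > 0L) {
      stop("environment is missing receptor type(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    uvec <- sample_waveform(stimulus[[target]], t_s)
    for (i in osn_idx) {
      rates <- env_rates(env, nn$receptor[i], target)
      b[i] <- rates[["b"]]; d[i] <- rates[["d"]]
      u[, i] <- uvec
    }
  }
  list(b = b, d = d, u = u)
}

#' Run a circuit on an odorant stimulus
#'
#' Deterministic fixed-step co-integration of the odorant transduction
#' cascade, Connor-Stevens neurons, alpha synapses and divisive
#' presynaptic terminals. Identical inputs give bitwise-identical outputs.
#'
#' The stimulus can be given in two equivalent forms: an
#' [odorant_environment()] plus a [pure_odorant_waveform()] stimulus, or a
#' `drive` -- a named vector of constant concentration-modulated affinity
#' values per receptor type (the form all sweeps use). With neither, the
#' circuit runs without odorant input.
#'
#' @param circuit an [al_circuit()].
#' @param env an [odorant_environment()] (with `stimulus`), or `NULL`.
#' @param stimulus a [pure_odorant_waveform()] list, or `NULL`.
#' @param config a [simulation_config()].
#' @param drive named numeric vector of affinity values per receptor.
#' @return A `simulation_result`: named spike trains (seconds), per-neuron
#'   steady-state rates (Hz), the mean feedforward OSN->PN conductance and
#'   mean OSN terminal gain over the steady-state window, and optional
#'   membrane traces.
#' @export
run_circuit <- function(circuit, env = NULL, stimulus = NULL,
                        config = simulation_config(), drive = NULL) {
  stopifnot(inherits(circuit, "al_circuit"))
  nn <- circuit$neurons
  dr <- resolve_drive(circuit, env, stimulus, drive, config)
  idx <- stats::setNames(seq_len(nrow(nn)) - 1L, nn$id)
  e <- circuit$edges
  res <- run_network_cpp(
    class_code = match(nn$class, c("OSN", "PN", "LN")) - 1L,
    i_ext = nn$i_ext,
    osn_b = dr$b, osn_d = dr$d, u_samples = dr$u, u_dt_ms = 1,
    e_pre = unname(idx[e$pre]), e_post = unname(idx[e$post]),
    e_gbar = e$gbar, e_tau = e$tau,
    e_erev = ifelse(is.na(e$erev), 0, e$erev),
    e_presyn = as.integer(e$type == "presyn"),
    e_kappa = ifelse(is.na(e$kappa), 0, e$kappa),
    cs = circuit$params$cs, otp = circuit$params$otp,
    dt = config$dt, duration_s = config$duration,
    window_s = config$window,
    record_v = isTRUE(config$record_v), record_dt = config$record_dt)
  spikes <- lapply(res$spikes_ms, function(s) s / 1000)
  names(spikes) <- nn$id
  rates <- vapply(spikes, steady_state_rate, numeric(1),
                  window = config$window, duration = config$duration)
  out <- list(spikes = spikes, rates = rates, neurons = nn,
              config = config,
              ff_conductance_mean = res$ff_conductance_mean,
              osn_gain_mean = res$osn_gain_mean)
  if (isTRUE(config$record_v)) {
    out$v <- res$v
    colnames(out$v) <- nn$id
    out$v_t <- res$v_t_ms / 1000
  }
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("Simulation result:", length(x$spikes), "neurons,",
      x$config$duration, "s at dt =", x$config$dt, "ms\n")
  pn <- x$neurons$class == "PN"
  if (any(pn)) {
    cat("  PN steady-state rates (Hz):\n")
    print(round(x$rates[pn], 2))
  }
  invisible(x)
}

#' Inject a constant external current into one neuron
#'
#' Adds a constant current (model units uA/cm^2 with unit membrane area)
#' to the neuron's input for the whole run. With a `config`, the circuit
#' is run immediately and the [run_circuit()] result returned; without
#' one, the modified circuit is returned for later use.
#'
#' @param circuit an [al_circuit()].
#' @param neuron_id id of a neuron in the circuit.
#' @param amplitude current amplitude.
#' @param config optional [simulation_config()] triggering an immediate
#'   run.
#' @param ... passed to [run_circuit()] when running.
#' @return A modified circuit, or a `simulation_result` when `config` is
#'   given.
#' @export
inject_current <- function(circuit, neuron_id, amplitude, config = NULL,
                           ...) {
  stopifnot(inherits(circuit, "al_circuit"))
  i <- match(neuron_id, circuit$neurons$id)
  if (is.na(i)) stop("unknown neuron id '", neuron_id, "'", call. = FALSE)
  circuit$neurons$i_ext[i] <- circuit$neurons$i_ext[i] + amplitude
  if (is.null(config)) return(circuit)
  run_circuit(circuit, config = config, ...)
}

#' Steady-state PN response over an affinity sweep
#'
#' Runs the circuit once per grid value with a constant stimulus scaled so
#' the concentration-modulated affinity of the driven receptor(s) equals
#' the grid value, and records every neuron's steady-state rate.
#'
#' @param circuit an [al_circuit()].
#' @param values sorted affinity grid (see [affinity_sweep_values()]),
#'   at least 2 points.
#' @param config a [simulation_config()].
#' @param receptors receptor types to drive (default: all receptors in the
#'   circuit, all at the grid value).
#' @return A `sweep_result` with the grid, a `values x neurons` rate
#'   matrix, and per-run feedforward conductance means.
#' @export
sweep_affinity <- function(circuit, values = affinity_sweep_values(1e-2, 1e2),
                           config = simulation_config(),
                           receptors = NULL) {
  if (length(values) < 2L) stop("need at least 2 grid values", call. = FALSE)
  if (is.unsorted(values)) stop("values must be sorted", call. = FALSE)
  if (is.null(receptors)) {
    receptors <- unique(stats::na.omit(circuit$neurons$receptor))
  }
  rates <- NULL; ff <- numeric(length(values)); gain <- numeric(length(values))
  for (k in seq_along(values)) {
    r <- run_circuit(circuit, config = config,
                     drive = stats::setNames(rep(values[k],
                                                 length(receptors)),
                                             receptors))
    if (is.null(rates)) {
      rates <- matrix(0, length(values), length(r$rates),
                      dimnames = list(NULL, names(r$rates)))
    }
    rates[k, ] <- r$rates
    ff[k] <- r$ff_conductance_mean
    gain[k] <- r$osn_gain_mean
  }
  structure(list(values = values, rates = rates,
                 pn_ids = circuit$neurons$id[circuit$neurons$class == "PN"],
                 ff_conductance_mean = ff, osn_gain_mean = gain,
                 config = config),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Affinity sweep:", length(x$values), "grid points in [",
      format(min(x$values)), ",", format(max(x$values)), "]\n")
  cat("  PN steady-state rates (Hz):\n")
  m <- cbind(affinity = x$values,
             round(x$rates[, x$pn_ids, drop = FALSE], 2))
  print(utils::head(as.data.frame(m), 25))
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, neurons = x$pn_ids, log = "x", ...) {
  graphics::matplot(x$values, x$rates[, neurons, drop = FALSE],
                    type = "l", lty = 1, log = log,
                    xlab = "concentration-modulated affinity (b/d)u",
                    ylab = "steady-state rate (Hz)", ...)
  graphics::legend("topleft", legend = neurons, lty = 1,
                   col = seq_along(neurons), bty = "n", cex = 0.8)
  invisible(x)
}

#' Steady-state PN response mesh over a two-receptor affinity grid
#'
#' Sweeps constant inputs on a grid of concentration-modulated affinity
#' values, one axis per receptor (hence per glomerulus), and records every
#' PN's steady-state rate at each grid point.
#'
#' @param circuit an [al_circuit()].
#' @param values_x,values_y sorted affinity grids for the two receptors.
#' @param receptor_x,receptor_y the receptor driven by each axis.
#' @param config a [simulation_config()].
#' @return A `sweep_grid_result` holding a `length(values_x) x
#'   length(values_y) x n_pn` rate array.
#' @export
sweep_affinity_grid <- function(circuit, values_x, values_y,
                                receptor_x, receptor_y,
                                config = simulation_config()) {
  if (is.unsorted(values_x) || is.unsorted(values_y)) {
    stop("grid axes must be sorted", call. = FALSE)
  }
  receptors <- unique(stats::na.omit(circuit$neurons$receptor))
  for (r in c(receptor_x, receptor_y)) {
    if (!r %in% receptors) {
      stop("receptor '", r, "' does not drive any glomerulus in the circuit",
           call. = FALSE)
    }
  }
  pn_ids <- circuit$neurons$id[circuit$neurons$class == "PN"]
  mesh <- array(0, c(length(values_x), length(values_y), length(pn_ids)),
                dimnames = list(NULL, NULL, pn_ids))
  for (i in seq_along(values_x)) {
    for (j in seq_along(values_y)) {
      r <- run_circuit(circuit, config = config,
                       drive = stats::setNames(c(values_x[i], values_y[j]),
                                               c(receptor_x, receptor_y)))
      mesh[i, j, ] <- r$rates[pn_ids]
    }
  }
  structure(list(values_x = values_x, values_y = values_y,
                 receptor_x = receptor_x, receptor_y = receptor_y,
                 rates = mesh, pn_ids = pn_ids, config = config),
            class = "sweep_grid_result")
}

#' @export
print.sweep_grid_result <- function(x, ...) {
  cat("Affinity grid sweep:", length(x$values_x), "x", length(x$values_y),
      "points,", length(x$pn_ids), "PN(s)\n")
  for (pn in x$pn_ids) {
    cat("  ", pn, ": rate range [",
        round(min(x$rates[, , pn]), 2), ",",
        round(max(x$rates[, , pn]), 2), "] Hz\n")
  }
  invisible(x)
}

#' @export
plot.sweep_grid_result <- function(x, pn = x$pn_ids[1L], ...) {
  graphics::image(log10(x$values_x), log10(x$values_y), x$rates[, , pn],
                  xlab = paste0("log10 affinity (", x$receptor_x, ")"),
                  ylab = paste0("log10 affinity (", x$receptor_y, ")"),
                  main = paste(pn, "steady-state rate (Hz)"),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Write spike trains as two-column text
#'
#' @param result a `simulation_result`.
#' @param path output file (columns: neuron id, spike time in s).
#' @return `path`, invisibly.
#' @export
write_spikes <- function(result, path) {
  n <- vapply(result$spikes, length, integer(1))
  df <- data.frame(neuron_id = rep(names(result$spikes), n),
                   spike_time_s = unlist(result$spikes, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
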