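#' Receptor-centric odorant environment
#'
#' An odorant environment describes stimulus identity through a pair of
#' 3-axis rate arrays: per-(receptor, odorant, neuron) binding rates `b`
#' (units 1/(concentration*s)) and dissociation rates `d` (units 1/s).
#' Concentration waveforms are attached separately (see
#' [pure_odorant_waveform()]). When `share_across_neurons` is `TRUE`
#' (the default, and the common simplification), `b` and `d` are constant
#' along the neuron axis and may be supplied as R x O matrices.
#'
#' @param binding_rates numeric array `[R, O, N]` (or `R x O` matrix when
#'   shared across neurons) of binding rates, all `>= 0`.
#' @param dissociation_rates numeric array with the same shape, all `> 0`.
#' @param receptor_labels,odorant_labels character vectors naming the first
#'   two axes.
#' @param n_neurons number of neurons per receptor type when matrices are
#'   supplied; ignored for 3-axis input.
#' @param share_across_neurons logical; if `TRUE` the rates do not vary
#'   along the neuron axis.
#' @return An object of class `odorant_environment`.
#' @examples
#' env <- odorant_environment(
#'   binding_rates      = matrix(c(10, 2, 1, 20), 2, 2),
#'   dissociation_rates = matrix(10, 2, 2),
#'   receptor_labels    = c("Or59b", "Or7a"),
#'   odorant_labels     = c("methyl butyrate", "E2-hexenal")
#' )
#' print(env)
#' @export
odorant_environment <- function(binding_rates, dissociation_rates,
                                receptor_labels, odorant_labels,
                                n_neurons = 1L,
                                share_across_neurons = TRUE) {
  if (is.matrix(binding_rates)) {
    binding_rates <- array(binding_rates,
                           c(nrow(binding_rates), ncol(binding_rates), n_neurons))
  }
  if (is.matrix(dissociation_rates)) {
    dissociation_rates <- array(dissociation_rates,
                                c(dim(binding_rates)[1], dim(binding_rates)[2], n_neurons))
  }
  env <- structure(
    list(
      b = binding_rates,
      d = dissociation_rates,
      receptor_labels = as.character(receptor_labels),
      odorant_labels  = as.character(odorant_labels),
      share_across_neurons = isTRUE(share_across_neurons)
    ),
    class = "odorant_environment"
  )
  problems <- validate_environment(env)
  if (length(problems) > 0L) {
    stop("invalid odorant environment: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  env
}

#' Validate an odorant environment
#'
#' Checks the structural invariants of an environment and reports every
#' violation rather than stopping at the first: `b` entries nonnegative,
#' `d` entries strictly positive, identical `b`/`d` shapes, and label list
#' lengths matching the array axes.
#'
#' @param env an [odorant_environment()].
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_environment <- function(env) {
  problems <- character()
  if (!is.array(env$b) || length(dim(env$b)) != 3L) {
    problems <- c(problems, "binding rates must be a 3-axis array")
  }
  if (!is.array(env$d) || length(dim(env$d)) != 3L) {
    problems <- c(problems, "dissociation rates must be a 3-axis array")
  }
  if (length(problems) == 0L && !identical(dim(env$b), dim(env$d))) {
    problems <- c(problems, "binding/dissociation shape mismatch")
  }
  if (any(env$b < 0, na.rm = TRUE) || anyNA(env$b)) {
    problems <- c(problems, "binding rates must be nonnegative and finite")
  }
  if (any(env$d <= 0, na.rm = TRUE) || anyNA(env$d)) {
    problems <- c(problems, "dissociation must be positive")
  }
  if (length(problems) == 0L) {
    if (dim(env$b)[1] != length(env$receptor_labels)) {
      problems <- c(problems, "receptor label count does not match array shape")
    }
    if (dim(env$b)[2] != length(env$odorant_labels)) {
      problems <- c(problems, "odorant label count does not match array shape")
    }
  }
  problems
}

#' @export
print.odorant_environment <- function(x, ...) {
  cat("Odorant environment:",
      length(x$receptor_labels), "receptor type(s) x",
      length(x$odorant_labels), "odorant(s) x",
      dim(x$b)[3], "neuron(s)\n")
  cat("  receptors:", paste(x$receptor_labels, collapse = ", "), "\n")
  cat("  odorants: ", paste(x$odorant_labels, collapse = ", "), "\n")
  cat("  rates shared across neurons:", x$share_across_neurons, "\n")
  invisible(x)
}

#' Concentration waveforms
#'
#' Waveforms are stored as a named generator plus parameters and sampled on
#' the simulator's time grid at run time, so an environment is independent
#' of any particular integration step. Supported generators:
#' `constant` (`amplitude`), `step` (`amplitude`, `on`, `off`),
#' `ramp` (`from`, `to`), and `pwl` (piecewise-linear interpolation of
#' `times`/`values` samples).
#'
#' @param kind generator name.
#' @param duration waveform duration in seconds.
#' @param ... generator parameters (see Details).
#' @return An object of class `concentration_waveform`.
#' @export
concentration_waveform <- function(kind = c("constant", "step", "ramp", "pwl"),
                                   duration, ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be positive", call. = FALSE)
  }
  wf <- structure(list(kind = kind, duration = duration, pars = pars),
                  class = "concentration_waveform")
  # reject negative concentrations up front
  if (any(sample_waveform(wf, seq(0, duration, length.out = 33L)) < 0)) {
    stop("concentration waveform must be nonnegative", call. = FALSE)
  }
  wf
}

#' Sample a concentration waveform on a time grid
#'
#' @param wf a [concentration_waveform()].
#' @param times numeric vector of times (s) within `[0, duration]`.
#' @return Numeric vector of concentrations, same length as `times`.
#' @export
sample_waveform <- function(wf, times) {
  stopifnot(inherits(wf, "concentration_waveform"))
  p <- wf$pars
  switch(wf$kind,
    constant = rep(p$amplitude, length(times)),
    step = ifelse(times >= p$on & times < p$off, p$amplitude, 0),
    ramp = p$from + (p$to - p$from) * pmin(pmax(times / wf$duration, 0), 1),
    pwl  = stats::approx(p$times, p$values, xout = times, rule = 2)$y
  )
}

#' Pure-odorant stimulus
#'
#' A pure odorant drives exactly one odorant channel: the returned waveform
#' set is constant at `amplitude` on the named odorant and identically zero
#' on every other odorant in the environment.
#'
#' @param env an [odorant_environment()].
#' @param odorant_label which odorant is present.
#' @param amplitude constant concentration, `>= 0`.
#' @param duration stimulus duration in seconds.
#' @return A named list of [concentration_waveform()] objects, one per
#'   odorant in `env`, carrying class `pure_odorant`.
#' @export
pure_odorant_waveform <- function(env, odorant_label, amplitude, duration) {
  stopifnot(inherits(env, "odorant_environment"))
  if (!odorant_label %in% env$odorant_labels) {
    stop("unknown odorant label: '", odorant_label, "'", call. = FALSE)
  }
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("amplitude must be nonnegative", call. = FALSE)
  }
  wfs <- lapply(env$odorant_labels, function(o) {
    concentration_waveform("constant", duration = duration,
                           amplitude = if (o == odorant_label) amplitude else 0)
  })
  names(wfs) <- env$odorant_labels
  structure(wfs, class = c("pure_odorant", "list"), target = odorant_label)
}

#' Concentration-modulated affinity
#'
#' The dimensionless product (b/d)*u summarizing the drive an odorant at
#' concentration `u` delivers to a receptor with binding rate `b` and
#' dissociation rate `d`. This is the sweep variable of all steady-state
#' input/output characterizations in the package.
#'
#' @param b binding rate, `>= 0` (1/(concentration*s)).
#' @param d dissociation rate, `> 0` (1/s).
#' @param u concentration, `>= 0`.
#' @return Numeric affinity value(s), `>= 0`. Vectorized over its arguments.
#' @examples
#' concentration_modulated_affinity(2, 4, 10) # 5
#' @export
concentration_modulated_affinity <- function(b, d, u) {
  if (any(d <= 0)) stop("dissociation rate must be positive", call. = FALSE)
  if (any(b < 0)) stop("binding rate must be nonnegative", call. = FALSE)
  if (any(u < 0)) stop("concentration must be nonnegative", call. = FALSE)
  (b / d) * u
}

#' Affinity sweep grids
#'
#' Builds the sorted grid of concentration-modulated affinity values an
#' input/output sweep runs over, under linear or logarithmic spacing.
#'
#' @param min,max grid end points, `0 <= min < max` (`min > 0` for log
#'   spacing).
#' @param count number of grid points, `>= 2`.
#' @param spacing `"linear"` or `"log"`.
#' @return Sorted numeric vector of length `count` spanning `[min, max]`.
#' @export
affinity_sweep_values <- function(min, max, count = 20L,
                                  spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!(min >= 0 && min < max)) {
    stop("need 0 <= min < max", call. = FALSE)
  }
  if (count < 2L) stop("count must be at least 2", call. = FALSE)
  if (spacing == "linear") {
    seq(min, max, length.out = count)
  } else {
    if (min <= 0) stop("log spacing requires min > 0", call. = FALSE)
    exp(seq(log(min), log(max), length.out = count))
  }
}

#' Read / write odorant-environment configuration files
#'
#' Environments are serialized as YAML with fields `receptors`, `odorants`,
#' `binding_rates` and `dissociation_rates` (R x O matrices stored row-wise,
#' broadcast along the neuron axis when `share_across_neurons`), and an
#' optional `waveforms` block of generator specs.
#'
#' @param path file path.
#' @param env an [odorant_environment()].
#' @return `read_environment` returns an `odorant_environment`;
#'   `write_environment` returns `path` invisibly.
#' @export
read_environment <- function(path) {
  cfg <- yaml::read_yaml(path)
  R <- length(cfg$receptors); O <- length(cfg$odorants)
  b <- matrix(unlist(cfg$binding_rates), R, O, byrow = TRUE)
  d <- matrix(unlist(cfg$dissociation_rates), R, O, byrow = TRUE)
  odorant_environment(b, d, cfg$receptors, cfg$odorants,
                      n_neurons = cfg$n_neurons %||% 1L,
                      share_across_neurons = cfg$share_across_neurons %||% TRUE)
}

#' @rdname read_environment
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "odorant_environment"))
  b <- env$b[, , 1L, drop = FALSE]; dim(b) <- dim(env$b)[1:2]
  d <- env$d[, , 1L, drop = FALSE]; dim(d) <- dim(env$d)[1:2]
  cfg <- list(
    receptors = env$receptor_labels,
    odorants = env$odorant_labels,
    n_neurons = dim(env$b)[3],
    share_across_neurons = env$share_across_neurons,
    binding_rates = lapply(seq_len(nrow(b)), function(i) as.numeric(b[i, ])),
    dissociation_rates = lapply(seq_len(nrow(d)), function(i) as.numeric(d[i, ]))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rate lookup for one receptor/odorant pair (first neuron when shared)
env_rates <- function(env, receptor, odorant) {
  r <- match(receptor, env$receptor_labels)
  o <- match(odorant, env$odorant_labels)
  if (is.na(r)) stop("unknown receptor label: '", receptor, "'", call. = FALSE)
  if (is.na(o)) stop("unknown odorant label: '", odorant, "'", call. = FALSE)
  c(b = env$b[r, o, 1L], d = env$d[r, o, 1L])
}
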