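#' Define a glomerulus model
#'
#' A glomerulus is the feedforward unit of the antennal lobe: a group of
#' OSNs expressing one receptor type, their target PNs, a feedforward
#' synapse-count matrix, and four open ports through which LNs connect
#' (LN->OSN presynaptic terminals, LN<-OSN, LN->PN, LN<-PN).
#'
#' @param name glomerulus label (e.g. `"DM4"`).
#' @param n_osn,n_pn neuron counts, both `>= 1`.
#' @param ff_counts `n_osn x n_pn` matrix of nonnegative integer synapse
#'   counts (a scalar is recycled).
#' @param receptor receptor type expressed by the OSNs.
#' @return A list of class `glomerulus_model`.
#' @export
build_glomerulus <- function(name, n_osn, n_pn, ff_counts,
                             receptor = paste0("Or-", name)) {
  if (n_osn < 1 || n_pn < 1) {
    stop("a glomerulus needs at least 1 OSN and 1 PN", call. = FALSE)
  }
  if (length(ff_counts) == 1L) ff_counts <- matrix(ff_counts, n_osn, n_pn)
  ff_counts <- as.matrix(ff_counts)
  if (!all(dim(ff_counts) == c(n_osn, n_pn))) {
    stop("ff_counts must be an n_osn x n_pn matrix", call. = FALSE)
  }
  if (any(ff_counts < 0) || any(ff_counts != round(ff_counts))) {
    stop("ff_counts must be nonnegative integers", call. = FALSE)
  }
  if (all(ff_counts == 0)) {
    warning("glomerulus '", name, "' has an all-zero feedforward matrix ",
            "(disconnected feedforward)", call. = FALSE)
  }
  structure(list(name = name, n_osn = n_osn, n_pn = n_pn,
                 ff_counts = ff_counts, receptor = receptor),
            class = "glomerulus_model")
}

#' @export
print.glomerulus_model <- function(x, ...) {
  cat("Glomerulus", x$name, "-", x$n_osn, "OSN(s) [", x$receptor, "],",
      x$n_pn, "PN(s),", sum(x$ff_counts), "feedforward synapses\n")
  invisible(x)
}

#' Define a feedback motif
#'
#' A feedback motif is an abstract LN with a port connectivity pattern per
#' attached glomerulus. `LN1` carries pattern `"1100"` in every attached
#' glomerulus (it presynaptically inhibits OSN terminals and reads the
#' OSNs); `LN2` carries `"0011"` (it loops with the PNs; its output sign is
#' configurable and defaults to excitatory); `LN3` has no glomerular ports
#' and connects only to other motifs (see [add_ln3()]); `custom` motifs
#' take an explicit per-glomerulus pattern map.
#'
#' @param kind one of `"LN1"`, `"LN2"`, `"LN3"`, `"custom"`.
#' @param glomeruli glomerulus labels the motif attaches to (ignored for
#'   `LN3`; for `custom`, defaults to `names(patterns)`).
#' @param sign output sign at chemical ports, `"excitatory"` or
#'   `"inhibitory"`.
#' @param patterns named character vector of port patterns for `custom`
#'   motifs.
#' @param id motif identifier (auto-generated when attached if `NULL`).
#' @param multiplicity number of identical LN neurons realizing the motif.
#' @return A list of class `feedback_motif`.
#' @export
feedback_motif <- function(kind = c("LN1", "LN2", "LN3", "custom"),
                           glomeruli = NULL, sign = NULL, patterns = NULL,
                           id = NULL, multiplicity = 1L) {
  kind <- match.arg(kind)
  if (kind == "LN3") {
    patterns <- character()
    sign <- sign %||% "inhibitory"
  } else if (kind == "custom") {
    if (is.null(patterns) || is.null(names(patterns))) {
      stop("custom motifs need a named `patterns` map", call. = FALSE)
    }
    stopifnot(all(grepl("^[01]{4}$", patterns)))
    glomeruli <- names(patterns)
    sign <- sign %||% "inhibitory"
  } else {
    if (is.null(glomeruli)) {
      stop(kind, " motifs need the glomeruli they attach to", call. = FALSE)
    }
    base <- if (kind == "LN1") "1100" else "0011"
    patterns <- stats::setNames(rep(base, length(glomeruli)), glomeruli)
    sign <- sign %||% if (kind == "LN1") "inhibitory" else "excitatory"
  }
  sign <- match.arg(sign, c("excitatory", "inhibitory"))
  structure(list(kind = kind, patterns = patterns, sign = sign, id = id,
                 multiplicity = as.integer(multiplicity)),
            class = "feedback_motif")
}

empty_edges <- function() {
  data.frame(pre = character(), post = character(), count = integer(),
             type = character(), tau = numeric(), gbar = numeric(),
             erev = numeric(), kappa = numeric(), motif = character(),
             glomerulus = character(), port = integer(),
             stringsAsFactors = FALSE)
}

#' Assemble an executable antennal-lobe circuit
#'
#' Creates the neurons and feedforward alpha-synapse edges for a set of
#' glomeruli. Feedback motifs are attached afterwards with
#' [attach_motif()] and [add_ln3()]. Every OSN is an odorant-transduction
#' unit feeding a Connor-Stevens axon hillock; PNs and LNs are
#' Connor-Stevens neurons; an edge of `count` synapses has peak conductance
#' `count * syn$g_unit`.
#'
#' @param glomeruli a `glomerulus_model` or list of them.
#' @param params an [al_params()] set.
#' @return An object of class `al_circuit`.
#' @export
al_circuit <- function(glomeruli, params = al_params()) {
  if (inherits(glomeruli, "glomerulus_model")) glomeruli <- list(glomeruli)
  names(glomeruli) <- vapply(glomeruli, `[[`, character(1), "name")
  if (anyDuplicated(names(glomeruli))) {
    stop("duplicate glomerulus names", call. = FALSE)
  }
  neurons <- list(); edges <- list(); gl_info <- list()
  for (g in glomeruli) {
    osn_ids <- sprintf("%s-OSN-%d", g$name, seq_len(g$n_osn))
    pn_ids <- sprintf("%s-PN-%d", g$name, seq_len(g$n_pn))
    neurons[[length(neurons) + 1L]] <- data.frame(
      id = c(osn_ids, pn_ids),
      class = c(rep("OSN", g$n_osn), rep("PN", g$n_pn)),
      glomerulus = g$name,
      receptor = c(rep(g$receptor, g$n_osn), rep(NA_character_, g$n_pn)),
      motif = NA_character_, i_ext = 0,
      stringsAsFactors = FALSE)
    idx <- which(g$ff_counts > 0, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      edges[[length(edges) + 1L]] <- data.frame(
        pre = osn_ids[idx[, 1L]], post = pn_ids[idx[, 2L]],
        count = g$ff_counts[idx], type = "alpha",
        tau = params$syn$tau_exc,
        gbar = g$ff_counts[idx] * params$syn$g_unit,
        erev = params$syn$e_exc, kappa = 0,
        motif = NA_character_, glomerulus = g$name, port = NA_integer_,
        stringsAsFactors = FALSE)
    }
    gl_info[[g$name]] <- list(name = g$name, receptor = g$receptor,
                              osn_ids = osn_ids, pn_ids = pn_ids)
  }
  structure(list(
    neurons = do.call(rbind, neurons),
    edges = if (length(edges) > 0L) do.call(rbind, edges) else empty_edges(),
    glomeruli = gl_info,
    motifs = list(),
    ablated = list(),
    params = params
  ), class = "al_circuit")
}

#' @export
print.al_circuit <- function(x, ...) {
  cls <- table(x$neurons$class)
  cat("Antennal-lobe circuit:", length(x$glomeruli), "glomerulus/i,",
      nrow(x$neurons), "neurons (",
      paste(names(cls), as.integer(cls), collapse = ", "), "),",
      nrow(x$edges), "edges,", length(x$motifs), "motif(s)\n")
  if (length(x$ablated) > 0L) {
    cat("  ablated motifs:", paste(names(x$ablated), collapse = ", "), "\n")
  }
  invisible(x)
}

motif_edges_for <- function(circuit, ln_id, glom_name, pattern, sign,
                            motif_id) {
  p <- circuit$params
  gl <- circuit$glomeruli[[glom_name]]
  digits <- as.integer(strsplit(pattern, "")[[1L]])
  c_osn <- p$syn$count_osn_port
  c_pn <- p$syn$count_pn_port
  rows <- list()
  mk <- function(pre, post, count, type, tau, gbar, erev, kappa, port) {
    data.frame(pre = pre, post = post, count = count, type = type,
               tau = tau, gbar = gbar, erev = erev, kappa = kappa,
               motif = motif_id, glomerulus = glom_name, port = port,
               stringsAsFactors = FALSE)
  }
  exc <- list(tau = p$syn$tau_exc, erev = p$syn$e_exc)
  out_syn <- if (sign == "excitatory") exc else
    list(tau = p$syn$tau_inh, erev = p$syn$e_inh)
  if (digits[1L] == 1L) {  # LN -> OSN: divisive presynaptic terminal
    rows[[length(rows) + 1L]] <- mk(ln_id, gl$osn_ids, c_osn, "presyn",
                                    p$presyn$tau, 1, NA_real_,
                                    c_osn * p$presyn$kappa_unit, 1L)
  }
  if (digits[2L] == 1L) {  # OSN -> LN, excitatory
    rows[[length(rows) + 1L]] <- mk(gl$osn_ids, ln_id, c_osn, "alpha",
                                    exc$tau, c_osn * p$syn$g_unit,
                                    exc$erev, 0, 2L)
  }
  if (digits[3L] == 1L) {  # LN -> PN, motif sign
    rows[[length(rows) + 1L]] <- mk(ln_id, gl$pn_ids, c_pn, "alpha",
                                    out_syn$tau, c_pn * p$syn$g_unit,
                                    out_syn$erev, 0, 3L)
  }
  if (digits[4L] == 1L) {  # PN -> LN, excitatory
    rows[[length(rows) + 1L]] <- mk(gl$pn_ids, ln_id, c_pn, "alpha",
                                    exc$tau, c_pn * p$syn$g_unit,
                                    exc$erev, 0, 4L)
  }
  if (length(rows) == 0L) return(empty_edges())
  do.call(rbind, rows)
}

#' Attach a feedback motif to a circuit
#'
#' Adds one LN neuron per unit of the motif's multiplicity and creates
#' edges exactly at the ports licensed by the motif's pattern in each
#' attached glomerulus: a `1` in digit 1 creates divisive presynaptic
#' terminals on every OSN, digit 2 excitatory OSN->LN synapses, digit 3
#' LN->PN synapses with the motif's sign, digit 4 excitatory PN->LN
#' synapses.
#'
#' @param circuit an [al_circuit()].
#' @param motif a [feedback_motif()] of kind other than `LN3` (use
#'   [add_ln3()] for LN3).
#' @param glomeruli optional subset of the motif's glomeruli to attach to.
#' @return The extended circuit.
#' @export
attach_motif <- function(circuit, motif, glomeruli = NULL) {
  stopifnot(inherits(circuit, "al_circuit"), inherits(motif, "feedback_motif"))
  if (motif$kind == "LN3") {
    stop("LN3 connects only to other motifs; use add_ln3()", call. = FALSE)
  }
  patterns <- motif$patterns
  if (!is.null(glomeruli)) patterns <- patterns[glomeruli]
  unknown <- setdiff(names(patterns), names(circuit$glomeruli))
  if (length(unknown) > 0L) {
    stop("unknown glomerulus: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  motif_id <- motif$id %||% sprintf("%s_%d", motif$kind,
                                    length(circuit$motifs) + 1L)
  if (motif_id %in% names(circuit$motifs)) {
    stop("motif id '", motif_id, "' already in circuit", call. = FALSE)
  }
  ln_ids <- if (motif$multiplicity == 1L) motif_id else
    sprintf("%s.%d", motif_id, seq_len(motif$multiplicity))
  circuit$neurons <- rbind(circuit$neurons, data.frame(
    id = ln_ids, class = "LN", glomerulus = NA_character_,
    receptor = NA_character_, motif = motif_id, i_ext = 0,
    stringsAsFactors = FALSE))
  n_new <- 0L
  for (ln in ln_ids) {
    for (g in names(patterns)) {
      e <- motif_edges_for(circuit, ln, g, patterns[[g]], motif$sign,
                           motif_id)
      n_new <- n_new + nrow(e)
      circuit$edges <- rbind(circuit$edges, e)
    }
  }
  if (n_new == 0L) {
    warning("motif '", motif_id, "' has all-zero patterns: no edges created",
            call. = FALSE)
  }
  circuit$motifs[[motif_id]] <- list(id = motif_id, kind = motif$kind,
                                     sign = motif$sign, patterns = patterns,
                                     neuron_ids = ln_ids, targets = NULL)
  circuit
}

#' Add an LN3 motif connecting other feedback motifs
#'
#' LN3 has no glomerular ports: it exchanges synapses only with other
#' motifs, bidirectionally with every target. Inputs to LN3 are excitatory
#' and its output is inhibitory by default.
#'
#' @param circuit an [al_circuit()].
#' @param targets motif ids to connect to (default: every LN1/LN2/custom
#'   motif in the circuit). Must be non-LN3 motifs.
#' @param id motif id (default `"LN3"`).
#' @param output_sign sign of LN3's output synapses.
#' @return The extended circuit.
#' @export
add_ln3 <- function(circuit, targets = NULL, id = "LN3",
                    output_sign = "inhibitory") {
  stopifnot(inherits(circuit, "al_circuit"))
  if (is.null(targets)) {
    targets <- names(circuit$motifs)[vapply(circuit$motifs, function(m)
      m$kind != "LN3", logical(1))]
  }
  if (length(targets) == 0L) {
    stop("LN3 needs at least one target motif", call. = FALSE)
  }
  bad <- setdiff(targets, names(circuit$motifs))
  if (length(bad) > 0L) {
    stop("unknown target motif: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(vapply(circuit$motifs[targets], function(m) m$kind == "LN3",
                 logical(1)))) {
    stop("LN3 targets must be LN1/LN2/custom motifs", call. = FALSE)
  }
  output_sign <- match.arg(output_sign, c("inhibitory", "excitatory"))
  if (id %in% names(circuit$motifs)) {
    stop("motif id '", id, "' already in circuit", call. = FALSE)
  }
  p <- circuit$params
  count <- p$syn$count_ln3
  circuit$neurons <- rbind(circuit$neurons, data.frame(
    id = id, class = "LN", glomerulus = NA_character_,
    receptor = NA_character_, motif = id, i_ext = 0,
    stringsAsFactors = FALSE))
  out_syn <- if (output_sign == "inhibitory") {
    list(tau = p$syn$tau_inh, erev = p$syn$e_inh)
  } else {
    list(tau = p$syn$tau_exc, erev = p$syn$e_exc)
  }
  for (tg in targets) {
    for (ln in circuit$motifs[[tg]]$neuron_ids) {
      circuit$edges <- rbind(circuit$edges, data.frame(
        pre = c(ln, id), post = c(id, ln), count = count, type = "alpha",
        tau = c(p$syn$tau_exc, out_syn$tau),
        gbar = count * p$syn$g_unit,
        erev = c(p$syn$e_exc, out_syn$erev), kappa = 0,
        motif = id, glomerulus = NA_character_, port = NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
  circuit$motifs[[id]] <- list(id = id, kind = "LN3", sign = output_sign,
                               patterns = character(), neuron_ids = id,
                               targets = targets)
  circuit
}

#' Default five-motif specification for a glomerulus pair
#'
#' One LN1 and one LN2 per glomerulus plus one LN3 bidirectionally
#' connected to all four.
#'
#' @param ln1,ln2,ln3 logical switches for each motif type.
#' @param ln2_sign output sign of the LN2 motifs.
#' @param shared_ln2 if `TRUE`, a single LN2 spans both glomeruli instead
#'   of one per glomerulus.
#' @return A list consumed by [interconnect_pair()].
#' @export
pair_motif_spec <- function(ln1 = TRUE, ln2 = TRUE, ln3 = TRUE,
                            ln2_sign = "excitatory", shared_ln2 = FALSE) {
  list(ln1 = ln1, ln2 = ln2, ln3 = ln3, ln2_sign = ln2_sign,
       shared_ln2 = shared_ln2)
}

#' Interconnect a pair of glomeruli through feedback motifs
#'
#' Builds the two glomeruli and composes the feedback motifs of the spec:
#' by default one LN1 and one LN2 per glomerulus (five motif neurons with
#' LN3), with LN3 bridging the two glomerular loops -- the only
#' cross-glomerular pathway.
#'
#' @param glom_a,glom_b two [build_glomerulus()] models with distinct
#'   names.
#' @param motif_spec a [pair_motif_spec()].
#' @param params an [al_params()] set.
#' @return An [al_circuit()].
#' @export
interconnect_pair <- function(glom_a, glom_b,
                              motif_spec = pair_motif_spec(),
                              params = al_params()) {
  if (identical(glom_a$name, glom_b$name)) {
    stop("duplicate glomerulus names", call. = FALSE)
  }
  circuit <- al_circuit(list(glom_a, glom_b), params)
  for (g in c(glom_a$name, glom_b$name)) {
    if (isTRUE(motif_spec$ln1)) {
      circuit <- attach_motif(circuit, feedback_motif(
        "LN1", glomeruli = g, id = paste0("LN1_", g)))
    }
    if (isTRUE(motif_spec$ln2) && !isTRUE(motif_spec$shared_ln2)) {
      circuit <- attach_motif(circuit, feedback_motif(
        "LN2", glomeruli = g, sign = motif_spec$ln2_sign,
        id = paste0("LN2_", g)))
    }
  }
  if (isTRUE(motif_spec$ln2) && isTRUE(motif_spec$shared_ln2)) {
    circuit <- attach_motif(circuit, feedback_motif(
      "LN2", glomeruli = c(glom_a$name, glom_b$name),
      sign = motif_spec$ln2_sign, id = "LN2_shared"))
  }
  if (isTRUE(motif_spec$ln3)) circuit <- add_ln3(circuit)
  circuit
}

#' Build the full-AL hierarchical crossbar
#'
#' Connects every LN (matrix row) to the ports of every glomerulus (matrix
#' column) its port connectivity pattern licenses: each `1` digit becomes a
#' port connection; `"0000"` entries create nothing. Each row is realized
#' as one custom motif.
#'
#' @param glomeruli list of [build_glomerulus()] models.
#' @param ln_pattern_matrix character matrix of 4-digit patterns with LN
#'   ids as row names and glomerulus names as column names.
#' @param ln_sign output sign of the crossbar LNs.
#' @param params an [al_params()] set.
#' @return An [al_circuit()].
#' @export
build_crossbar <- function(glomeruli, ln_pattern_matrix,
                           ln_sign = "inhibitory", params = al_params()) {
  circuit <- al_circuit(glomeruli, params)
  if (is.null(colnames(ln_pattern_matrix))) {
    stop("ln_pattern_matrix needs glomerulus column names", call. = FALSE)
  }
  unknown <- setdiff(colnames(ln_pattern_matrix), names(circuit$glomeruli))
  if (length(unknown) > 0L) {
    stop("pattern for unknown glomerulus: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ln_ids <- rownames(ln_pattern_matrix) %||%
    sprintf("LN-%d", seq_len(nrow(ln_pattern_matrix)))
  for (i in seq_len(nrow(ln_pattern_matrix))) {
    pat <- ln_pattern_matrix[i, ]
    pat <- pat[pat != "0000"]
    if (length(pat) == 0L) {
      warning("LN '", ln_ids[i], "' has all-zero patterns; no edges",
              call. = FALSE)
      next
    }
    circuit <- attach_motif(circuit, feedback_motif(
      "custom", patterns = pat, sign = ln_sign, id = ln_ids[i]))
  }
  circuit
}

#' Ablate / restore a feedback motif
#'
#' Ablation removes every edge of the motif (the neuron itself remains,
#' disconnected) and logs them so the operation is invertible; ablating an
#' already-ablated motif is a no-op. `restore_motif` puts the logged edges
#' back.
#'
#' @param circuit an [al_circuit()].
#' @param motif_id id of a motif in the circuit.
#' @return The modified circuit.
#' @export
ablate <- function(circuit, motif_id) {
  stopifnot(inherits(circuit, "al_circuit"))
  if (!motif_id %in% names(circuit$motifs)) {
    stop("unknown motif id '", motif_id, "'", call. = FALSE)
  }
  if (motif_id %in% names(circuit$ablated)) return(circuit)
  sel <- !is.na(circuit$edges$motif) & circuit$edges$motif == motif_id
  circuit$ablated[[motif_id]] <- circuit$edges[sel, , drop = FALSE]
  circuit$edges <- circuit$edges[!sel, , drop = FALSE]
  circuit
}

#' @rdname ablate
#' @export
restore_motif <- function(circuit, motif_id) {
  stopifnot(inherits(circuit, "al_circuit"))
  if (!motif_id %in% names(circuit$ablated)) return(circuit)
  circuit$edges <- rbind(circuit$edges, circuit$ablated[[motif_id]])
  circuit$ablated[[motif_id]] <- NULL
  circuit
}

#' Audit port licensing
#'
#' Checks the structural invariant that every motif edge in the circuit is
#' licensed by a `1` in the corresponding digit of the owning motif's port
#' pattern for that glomerulus.
#'
#' @param circuit an [al_circuit()].
#' @return `TRUE` when the audit passes; otherwise a data frame of
#'   violating edges.
#' @export
audit_port_licensing <- function(circuit) {
  e <- circuit$edges
  e <- e[!is.na(e$motif) & !is.na(e$port), , drop = FALSE]
  bad <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    pat <- circuit$motifs[[e$motif[i]]]$patterns[[e$glomerulus[i]]]
    bad[i] <- substr(pat, e$port[i], e$port[i]) != "1"
  }
  if (!any(bad)) TRUE else e[bad, , drop = FALSE]
}

#' Serialize a circuit as synapse and neuron annotation tables
#'
#' Expands every edge into `count` synapse rows (site confidences set to
#' `confidence`), producing tables in the schema [read_tables()] consumes.
#' Port edges carry their glomerulus label; motif-to-motif edges carry an
#' empty label. Running the extraction pipeline on these tables recovers
#' the composing port patterns.
#'
#' @param circuit an [al_circuit()].
#' @param confidence synapse site confidence to record.
#' @return List with `synapses` and `neurons` data frames.
#' @export
circuit_to_synapse_table <- function(circuit, confidence = 0.95) {
  nn <- circuit$neurons
  neurons <- data.frame(
    neuron_id = nn$id, cell_class = nn$class,
    receptor_type = ifelse(is.na(nn$receptor), "", nn$receptor),
    pn_subtype = ifelse(nn$class == "PN", "uPN-adPN", "none"),
    glomeruli = ifelse(is.na(nn$glomerulus), "", nn$glomerulus),
    stringsAsFactors = FALSE)
  e <- circuit$edges
  if (nrow(e) == 0L) {
    synapses <- data.frame(pre_id = character(), post_id = character(),
                           pre_conf = numeric(), post_conf = numeric(),
                           glomerulus = character(),
                           stringsAsFactors = FALSE)
  } else {
    rep_i <- rep(seq_len(nrow(e)), e$count)
    synapses <- data.frame(
      pre_id = e$pre[rep_i], post_id = e$post[rep_i],
      pre_conf = confidence, post_conf = confidence,
      glomerulus = ifelse(is.na(e$glomerulus[rep_i]), "",
                          e$glomerulus[rep_i]),
      stringsAsFactors = FALSE)
  }
  list(synapses = synapses, neurons = neurons)
}

#' Write / read a circuit as JSON
#'
#' The serialization records neurons, edges, glomeruli, motifs, ablation
#' log and the full parameter set.
#'
#' @param circuit an [al_circuit()].
#' @param path file path.
#' @return `write_circuit` returns `path` invisibly; `read_circuit`
#'   returns the `al_circuit`.
#' @export
write_circuit <- function(circuit, path) {
  obj <- unclass(circuit)
  obj$params <- unclass(obj$params)
  # keep glomerulus names on patterns (a named length-1 vector would
  # otherwise unbox to a bare scalar)
  obj$motifs <- lapply(obj$motifs, function(m) {
    m$patterns <- as.list(m$patterns)
    m
  })
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  circuit <- list(
    neurons = as.data.frame(obj$neurons, stringsAsFactors = FALSE),
    edges = if (length(obj$edges$pre) > 0L)
      as.data.frame(obj$edges, stringsAsFactors = FALSE) else empty_edges(),
    glomeruli = lapply(obj$glomeruli, function(g) {
      g$osn_ids <- unlist(g$osn_ids); g$pn_ids <- unlist(g$pn_ids); g
    }),
    motifs = lapply(obj$motifs, function(m) {
      m$patterns <- unlist(m$patterns) %||% character(0)
      m$neuron_ids <- unlist(m$neuron_ids)
      m$targets <- if (length(m$targets) > 0L) unlist(m$targets) else NULL
      m
    }),
    ablated = lapply(obj$ablated, function(a)
      as.data.frame(a, stringsAsFactors = FALSE)),
    params = structure(obj$params, class = "al_params")
  )
  class(circuit) <- "al_circuit"
  circuit
}
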