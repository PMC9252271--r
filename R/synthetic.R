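#' Specification for a synthetic connectome with planted port patterns
#'
#' The generator emulates the per-synapse tables a connectome release
#' provides, with ground truth planted by construction: every `1` digit of
#' a planted pattern receives a synapse count drawn from the
#' super-threshold range (default 8..15, strictly above the digit
#' threshold of 5), every `0` digit from the sub-threshold range (default
#' 0..3, strictly below), so pattern recovery is exact outside the
#' ambiguous band. Each LN is guaranteed at least two `1` digits overall
#' so its antennal-lobe total clears the LN inclusion threshold.
#'
#' @param n_glomeruli number of glomeruli.
#' @param n_ln number of local neurons.
#' @param osn_per_glom,pn_per_glom neurons per glomerulus.
#' @param super_range integer range for counts behind `1` digits; its
#'   minimum must exceed the digit threshold.
#' @param sub_range integer range for counts behind `0` digits; its
#'   maximum must stay below the digit threshold.
#' @param attach_prob probability an LN innervates a given glomerulus.
#' @param low_conf_fraction fraction of additional decoy synapse rows
#'   whose confidences fall below the 0.70 filter.
#' @param seed RNG seed; a fixed seed gives identical output.
#' @param cfg an [extraction_config()] supplying the thresholds the ranges
#'   are validated against.
#' @return A list of class `planted_spec`.
#' @export
planted_spec <- function(n_glomeruli = 10, n_ln = 200,
                         osn_per_glom = 5, pn_per_glom = 2,
                         super_range = c(8L, 15L), sub_range = c(0L, 3L),
                         attach_prob = 0.3, low_conf_fraction = 0.1,
                         seed = 1L, cfg = extraction_config()) {
  if (super_range[1L] <= cfg$digit_threshold) {
    stop("super-threshold range must lie strictly above the digit threshold",
         call. = FALSE)
  }
  if (sub_range[2L] >= cfg$digit_threshold) {
    stop("sub-threshold range overlaps the digit threshold", call. = FALSE)
  }
  structure(list(n_glomeruli = n_glomeruli, n_ln = n_ln,
                 osn_per_glom = osn_per_glom, pn_per_glom = pn_per_glom,
                 super_range = as.integer(super_range),
                 sub_range = as.integer(sub_range),
                 attach_prob = attach_prob,
                 low_conf_fraction = low_conf_fraction,
                 seed = as.integer(seed), cfg = cfg),
            class = "planted_spec")
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Generate a synthetic connectome with planted ground truth
#'
#' Produces synapse and neuron annotation tables in the
#' [read_tables()] schema, together with the planted truth: the port
#' pattern of every (LN, glomerulus) pair and each LN's feedback-loop
#' class computed from the planted directed totals. Planted rows carry
#' confidences above the 0.70 filter; an extra `low_conf_fraction` of
#' decoy rows falls below it and must be removed by
#' [filter_by_confidence()] before counting.
#'
#' @param spec a [planted_spec()].
#' @return List with `synapses`, `neurons`, and `truth` (a list holding
#'   the `patterns` data frame and the `loop_classes` data frame).
#' @export
generate_connectome <- function(spec) {
  stopifnot(inherits(spec, "planted_spec"))
  with_local_seed(spec$seed, {
    gloms <- sprintf("G%02d", seq_len(spec$n_glomeruli))
    all_patterns <- enumerate_port_patterns()
    osn_ids <- pn_ids <- list()
    neurons <- list()
    for (g in gloms) {
      osn_ids[[g]] <- sprintf("%s-OSN-%d", g, seq_len(spec$osn_per_glom))
      pn_ids[[g]] <- sprintf("%s-PN-%d", g, seq_len(spec$pn_per_glom))
      neurons[[length(neurons) + 1L]] <- data.frame(
        neuron_id = c(osn_ids[[g]], pn_ids[[g]]),
        cell_class = c(rep("OSN", spec$osn_per_glom),
                       rep("PN", spec$pn_per_glom)),
        receptor_type = c(rep(paste0("Or-", g), spec$osn_per_glom),
                          rep("", spec$pn_per_glom)),
        pn_subtype = c(rep("none", spec$osn_per_glom),
                       rep("uPN-adPN", spec$pn_per_glom)),
        glomeruli = g, stringsAsFactors = FALSE)
    }
    ln_ids <- sprintf("LN-%03d", seq_len(spec$n_ln))
    neurons[[length(neurons) + 1L]] <- data.frame(
      neuron_id = ln_ids, cell_class = "LN", receptor_type = "",
      pn_subtype = "none", glomeruli = "", stringsAsFactors = FALSE)
    neurons <- do.call(rbind, neurons)

    # plant patterns; resample until each LN has >= 2 one-digits overall,
    # which guarantees its AL synapse total clears the inclusion threshold
    plant <- matrix("0000", spec$n_ln, spec$n_glomeruli,
                    dimnames = list(ln_ids, gloms))
    for (i in seq_len(spec$n_ln)) {
      repeat {
        attached <- stats::runif(spec$n_glomeruli) < spec$attach_prob
        pats <- ifelse(attached, sample(all_patterns, spec$n_glomeruli,
                                        replace = TRUE), "0000")
        ones <- sum(as.integer(unlist(strsplit(pats, ""))))
        if (ones >= 2L) break
      }
      plant[i, ] <- pats
    }

    rint <- function(n, range) {
      if (range[1L] == range[2L]) rep(range[1L], n) else
        sample(seq(range[1L], range[2L]), n, replace = TRUE)
    }
    hi_conf <- function(n) stats::runif(n, 0.75, 1)

    rows <- vector("list", 4096L); nr <- 0L
    tot <- matrix(0L, spec$n_ln, 4L,
                  dimnames = list(ln_ids,
                                  c("from_osn", "to_osn",
                                    "from_pn", "to_pn")))
    for (i in seq_len(spec$n_ln)) {
      for (j in seq_len(spec$n_glomeruli)) {
        pat <- plant[i, j]
        if (pat == "0000") next
        digits <- as.integer(strsplit(pat, "")[[1L]])
        g <- gloms[j]
        for (k in 1:4) {
          cnt <- rint(1L, if (digits[k] == 1L) spec$super_range else
            spec$sub_range)
          if (cnt == 0L) next
          partners <- if (k <= 2L) osn_ids[[g]] else pn_ids[[g]]
          other <- sample(partners, cnt, replace = TRUE)
          pre <- if (k %in% c(1L, 3L)) ln_ids[i] else other
          post <- if (k %in% c(1L, 3L)) other else ln_ids[i]
          nr <- nr + 1L
          rows[[nr]] <- data.frame(pre_id = pre, post_id = post,
                                   pre_conf = hi_conf(cnt),
                                   post_conf = hi_conf(cnt),
                                   glomerulus = g, stringsAsFactors = FALSE)
          tot[i, k_to_total(k)] <- tot[i, k_to_total(k)] + cnt
        }
      }
    }
    synapses <- do.call(rbind, rows[seq_len(nr)])

    # decoy rows dropped by the confidence filter
    n_decoy <- ceiling(spec$low_conf_fraction * nrow(synapses))
    if (n_decoy > 0L) {
      pick <- sample(nrow(synapses), n_decoy, replace = TRUE)
      decoys <- synapses[pick, , drop = FALSE]
      which_low <- sample(3L, n_decoy, replace = TRUE)  # pre, post or both
      decoys$pre_conf <- ifelse(which_low != 2L,
                                stats::runif(n_decoy, 0, 0.70),
                                decoys$pre_conf)
      decoys$post_conf <- ifelse(which_low != 1L,
                                 stats::runif(n_decoy, 0, 0.70),
                                 decoys$post_conf)
      synapses <- rbind(synapses, decoys)
    }
    rownames(synapses) <- NULL

    # planted loop class from the planted directed totals (rule applied
    # directly to known counts, independent of the extraction code path)
    hi <- spec$cfg$loop_high; lo <- spec$cfg$loop_low
    loop_class <- apply(tot, 1L, function(x) {
      if (x[1L] > hi && x[2L] > hi && (x[3L] + x[4L]) < lo) "OSN-LN-OSN"
      else if (x[3L] > hi && x[4L] > hi && (x[1L] + x[2L]) < lo) "PN-LN-PN"
      else if (all(x > hi)) "OSN/PN-LN-OSN/PN"
      else "none"
    })
    n_rules <- apply(tot, 1L, function(x) {
      (x[1L] > hi && x[2L] > hi && (x[3L] + x[4L]) < lo) +
        (x[3L] > hi && x[4L] > hi && (x[1L] + x[2L]) < lo) +
        all(x > hi)
    })

    truth <- list(
      patterns = data.frame(
        ln_id = rep(ln_ids, spec$n_glomeruli),
        glomerulus = rep(gloms, each = spec$n_ln),
        pattern = as.vector(plant), stringsAsFactors = FALSE),
      loop_classes = data.frame(
        ln_id = ln_ids, loop_class = unname(loop_class),
        n_rules_satisfied = as.integer(n_rules),
        from_osn = tot[, 1L], to_osn = tot[, 2L],
        from_pn = tot[, 3L], to_pn = tot[, 4L],
        stringsAsFactors = FALSE),
      seed = spec$seed)
    list(synapses = synapses, neurons = neurons, truth = truth)
  })
}

# port index -> directed-total column: 1 LN->OSN, 2 OSN->LN, 3 LN->PN,
# 4 PN->LN
k_to_total <- function(k) c("to_osn", "from_osn", "to_pn", "from_pn")[k]

#' Ready-made fixtures for single- and two-glomerulus characterization
#'
#' `make_pair_fixture` returns two glomeruli in the structure used for
#' two-glomerulus interconnection studies -- the second with exactly one
#' PN -- plus the default five-motif spec (one LN1 and one LN2 per
#' glomerulus, one shared LN3). `make_single_fixture` returns one larger
#' glomerulus for single-glomerulus input/output characterization.
#' Feedforward counts are deterministic (a fixed cyclic ramp), so fixtures
#' are identical across calls.
#'
#' @param style fixture layout; currently `"DM4-DL5"`.
#' @return `make_pair_fixture`: list with `glom_a`, `glom_b`,
#'   `motif_spec`; `make_single_fixture`: a `glomerulus_model`.
#' @export
make_pair_fixture <- function(style = "DM4-DL5") {
  style <- match.arg(style)
  ff <- function(n_osn, n_pn) {
    outer(seq_len(n_osn), seq_len(n_pn),
          function(i, j) 10L + ((i + j) %% 6L) * 2L)
  }
  list(
    glom_a = build_glomerulus("DM4", n_osn = 20, n_pn = 2,
                              ff_counts = ff(20, 2), receptor = "Or59b"),
    glom_b = build_glomerulus("DL5", n_osn = 20, n_pn = 1,
                              ff_counts = ff(20, 1), receptor = "Or7a"),
    motif_spec = pair_motif_spec()
  )
}

#' @rdname make_pair_fixture
#' @param n_osn,n_pn neuron counts for the single-glomerulus fixture.
#' @export
make_single_fixture <- function(n_osn = 40, n_pn = 2) {
  ff <- outer(seq_len(n_osn), seq_len(n_pn),
              function(i, j) 10L + ((i + j) %% 6L) * 2L)
  build_glomerulus("DM4", n_osn = n_osn, n_pn = n_pn, ff_counts = ff,
                   receptor = "Or59b")
}

#' Inject one defect into fixture tables
#'
#' Negative-path helper: corrupts a valid table pair with exactly one
#' defect so parser validation can be exercised.
#'
#' @param tables list with `synapses` and `neurons`.
#' @param mode `"dangling_id"` (synapse referencing an unknown neuron),
#'   `"bad_confidence"` (confidence outside `[0, 1]`), or
#'   `"missing_column"` (drops the `glomerulus` column).
#' @return The corrupted tables.
#' @export
corrupt_fixture <- function(tables,
                            mode = c("dangling_id", "bad_confidence",
                                     "missing_column")) {
  mode <- match.arg(mode)
  s <- tables$synapses
  if (mode == "dangling_id") {
    s$post_id[1L] <- "no-such-neuron"
  } else if (mode == "bad_confidence") {
    s$pre_conf[1L] <- 1.2
  } else {
    s$glomerulus <- NULL
  }
  tables$synapses <- s
  tables
}

#' Write synthetic connectome tables to disk
#'
#' Writes the synapse table, the neuron table and a JSON manifest
#' recording the generation seed.
#'
#' @param tables output of [generate_connectome()].
#' @param dir output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_connectome <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(synapses = file.path(dir, "synapses.csv"),
             neurons = file.path(dir, "neurons.csv"),
             manifest = file.path(dir, "manifest.json"))
  utils::write.csv(tables$synapses, paths[["synapses"]], row.names = FALSE)
  utils::write.csv(tables$neurons, paths[["neurons"]], row.names = FALSE)
  jsonlite::write_json(list(seed = tables$truth$seed,
                            n_synapses = nrow(tables$synapses),
                            n_neurons = nrow(tables$neurons)),
                       paths[["manifest"]], auto_unbox = TRUE)
  invisible(paths)
}
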