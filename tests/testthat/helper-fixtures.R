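# Small handmade synapse/neuron tables used across the extraction tests.
# Layout: two glomeruli (DL5, DM4); DL5 has 3 OSNs, 1 uPN and 1 vPN;
# DM4 has 2 OSNs and 1 uPN; four LNs with distinct connectivity.

syn_rows <- function(pre, post, n, glom, conf = 0.95) {
  data.frame(pre_id = rep(pre, n), post_id = rep(post, n),
             pre_conf = conf, post_conf = conf, glomerulus = glom,
             stringsAsFactors = FALSE)
}

mini_neurons <- function() {
  data.frame(
    neuron_id = c("osn1", "osn2", "osn3", "osn4", "osn5",
                  "pn1", "pn2", "vpn1", "ln1", "ln2", "ln3", "ln4"),
    cell_class = c(rep("OSN", 5), "PN", "PN", "PN", rep("LN", 4)),
    receptor_type = c(rep("Or7a", 3), rep("Or59b", 2), rep("", 3),
                      rep("", 4)),
    pn_subtype = c(rep("none", 5), "uPN-adPN", "uPN-adPN", "vPN",
                   rep("none", 4)),
    glomeruli = c(rep("DL5", 3), rep("DM4", 2), "DL5", "DM4", "DL5",
                  rep("", 4)),
    stringsAsFactors = FALSE)
}

mini_tables <- function() {
  synapses <- rbind(
    # ln1: OSN-loop LN in DL5 (pattern 1100 there)
    syn_rows("ln1", "osn1", 4, "DL5"), syn_rows("ln1", "osn2", 4, "DL5"),
    syn_rows("osn1", "ln1", 7, "DL5"), syn_rows("osn2", "ln1", 3, "DL5"),
    # ln2: PN-loop LN in DL5, plus vPN contacts that must not count
    syn_rows("ln2", "pn1", 8, "DL5"), syn_rows("pn1", "ln2", 9, "DL5"),
    syn_rows("ln2", "vpn1", 6, "DL5"), syn_rows("vpn1", "ln2", 6, "DL5"),
    # ln3: mixed loop in DM4
    syn_rows("ln3", "osn4", 7, "DM4"), syn_rows("osn4", "ln3", 8, "DM4"),
    syn_rows("ln3", "pn2", 6, "DM4"), syn_rows("pn2", "ln3", 7, "DM4"),
    # ln4: too few synapses to be included (10 total, not > 10)
    syn_rows("ln4", "osn3", 5, "DL5"), syn_rows("osn3", "ln4", 5, "DL5"),
    # low-confidence rows that the filter must drop
    syn_rows("ln1", "osn3", 6, "DL5", conf = 0.60))
  rownames(synapses) <- NULL
  list(synapses = synapses, neurons = mini_neurons())
}

write_mini_tables <- function(tables = mini_tables(), dir = tempfile()) {
  dir.create(dir)
  sp <- file.path(dir, "synapses.csv")
  np <- file.path(dir, "neurons.csv")
  utils::write.csv(tables$synapses, sp, row.names = FALSE)
  utils::write.csv(tables$neurons, np, row.names = FALSE)
  list(synapses = sp, neurons = np)
}

# tiny executable circuit for engine tests: one glomerulus, 2 OSNs, 1 PN
tiny_circuit <- function(motifs = "LN1", ln2_sign = "excitatory") {
  g <- build_glomerulus("DM4", n_osn = 2, n_pn = 1,
                        ff_counts = matrix(c(15L, 12L), 2, 1),
                        receptor = "Or59b")
  cir <- al_circuit(g)
  if ("LN1" %in% motifs) {
    cir <- attach_motif(cir, feedback_motif("LN1", "DM4", id = "LN1"))
  }
  if ("LN2" %in% motifs) {
    cir <- attach_motif(cir, feedback_motif("LN2", "DM4", sign = ln2_sign,
                                            id = "LN2"))
  }
  cir
}

fast_config <- function(duration = 0.5, window = 0.25, dt = 0.01, ...) {
  simulation_config(dt = dt, duration = duration, window = window, ...)
}
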