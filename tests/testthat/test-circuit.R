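test_that("glomerulus construction validates counts and shapes", {
  dl5 <- build_glomerulus("DL5", n_osn = 3, n_pn = 1, ff_counts = 10)
  expect_s3_class(dl5, "glomerulus_model")
  expect_equal(dl5$n_pn, 1)
  expect_error(build_glomerulus("X", 0, 1, 10), "at least 1 OSN")
  expect_error(build_glomerulus("X", 2, 2, matrix(1, 3, 2)),
               "n_osn x n_pn")
  expect_error(build_glomerulus("X", 2, 1, matrix(-1, 2, 1)),
               "nonnegative")
  expect_warning(build_glomerulus("X", 2, 1, 0), "disconnected")
})

test_that("motif patterns are fixed by kind and validated for custom", {
  ln1 <- feedback_motif("LN1", c("DM4", "DL5"))
  expect_equal(unname(ln1$patterns), c("1100", "1100"))
  ln2 <- feedback_motif("LN2", "DM4")
  expect_equal(unname(ln2$patterns), "0011")
  expect_equal(ln2$sign, "excitatory")
  ln3 <- feedback_motif("LN3")
  expect_length(ln3$patterns, 0)
  expect_error(feedback_motif("custom", patterns = c(DM4 = "11x0")))
  expect_error(feedback_motif("LN1"), "glomeruli")
})

test_that("attaching motifs creates edges only at licensed ports", {
  g <- build_glomerulus("DM4", 3, 2, 10)
  cir <- attach_motif(al_circuit(g), feedback_motif("LN1", "DM4",
                                                    id = "LN1"))
  e <- cir$edges[!is.na(cir$edges$motif), ]
  expect_setequal(unique(e$port), c(1L, 2L))
  expect_true(all(e$type[e$port == 1L] == "presyn"))
  expect_true(all(e$type[e$port == 2L] == "alpha"))
  expect_equal(sum(e$port == 1L), 3)   # one terminal per OSN
  expect_true(audit_port_licensing(cir))

  # LN2 across two glomeruli touches only PN-side ports of both
  g2 <- build_glomerulus("DL5", 3, 1, 10)
  cir2 <- attach_motif(al_circuit(list(g, g2)),
                       feedback_motif("LN2", c("DM4", "DL5"), id = "LN2"))
  e2 <- cir2$edges[!is.na(cir2$edges$motif), ]
  expect_setequal(unique(e2$port), c(3L, 4L))
  expect_setequal(unique(e2$glomerulus), c("DM4", "DL5"))

  expect_warning(
    attach_motif(al_circuit(g), feedback_motif(
      "custom", patterns = c(DM4 = "0000"))), "no edges")
  expect_error(attach_motif(al_circuit(g), feedback_motif("LN3")),
               "add_ln3")
  expect_error(attach_motif(al_circuit(g),
                            feedback_motif("LN1", "DL5")), "unknown")
})

test_that("inhibitory LN2 flips the sign of its PN-facing output", {
  g <- build_glomerulus("DM4", 2, 1, 10)
  p <- al_params()
  cir <- attach_motif(al_circuit(g, p),
                      feedback_motif("LN2", "DM4", sign = "inhibitory",
                                     id = "LN2"))
  e <- cir$edges[!is.na(cir$edges$port) & cir$edges$port == 3L, ]
  expect_equal(unique(e$erev), p$syn$e_inh)
  e4 <- cir$edges[!is.na(cir$edges$port) & cir$edges$port == 4L, ]
  expect_equal(unique(e4$erev), p$syn$e_exc)  # inputs to the LN stay excitatory
})

test_that("LN3 wires bidirectionally to target motifs with default signs", {
  g <- build_glomerulus("DM4", 2, 1, 10)
  p <- al_params()
  cir <- al_circuit(g, p)
  cir <- attach_motif(cir, feedback_motif("LN1", "DM4", id = "LN1"))
  cir <- attach_motif(cir, feedback_motif("LN2", "DM4", id = "LN2"))
  cir <- add_ln3(cir)
  e <- cir$edges[!is.na(cir$edges$motif) & cir$edges$motif == "LN3", ]
  expect_equal(nrow(e), 4)   # both directions to both targets
  expect_equal(unique(e$erev[e$post == "LN3"]), p$syn$e_exc)
  expect_equal(unique(e$erev[e$pre == "LN3"]), p$syn$e_inh)

  expect_error(add_ln3(al_circuit(g)), "at least one target")
  expect_error(add_ln3(cir, targets = "LN9"), "unknown target")
  expect_error(add_ln3(add_ln3(cir, targets = "LN1", id = "LN3b"),
                       targets = "LN3b", id = "LN3c"),
               "LN1/LN2/custom")
})

test_that("pair interconnection composes the five-motif default", {
  fx <- make_pair_fixture()
  cir <- interconnect_pair(fx$glom_a, fx$glom_b, fx$motif_spec)
  expect_equal(sum(cir$neurons$class == "LN"), 5)
  expect_true(audit_port_licensing(cir))
  expect_equal(cir$motifs$LN3$targets,
               c("LN1_DM4", "LN2_DM4", "LN1_DL5", "LN2_DL5"))

  no3 <- interconnect_pair(fx$glom_a, fx$glom_b,
                           pair_motif_spec(ln3 = FALSE))
  expect_equal(sum(no3$neurons$class == "LN"), 4)
  # without LN3 there is no cross-glomerular edge
  gl <- function(id, cir) {
    i <- match(id, cir$neurons$id)
    cir$neurons$glomerulus[i]
  }
  e <- no3$edges
  expect_true(all(!is.na(e$glomerulus)))

  shared <- interconnect_pair(fx$glom_a, fx$glom_b,
                              pair_motif_spec(shared_ln2 = TRUE,
                                              ln3 = FALSE))
  ln2 <- shared$motifs$LN2_shared
  expect_setequal(names(ln2$patterns), c("DM4", "DL5"))
  e2 <- shared$edges[!is.na(shared$edges$motif) &
                       shared$edges$motif == "LN2_shared", ]
  expect_setequal(unique(e2$glomerulus), c("DM4", "DL5"))

  expect_error(interconnect_pair(fx$glom_a, fx$glom_a), "duplicate")
})

test_that("motif attachment order does not change the edge set", {
  g <- build_glomerulus("DM4", 3, 2, 10)
  m1 <- feedback_motif("LN1", "DM4", id = "A")
  m2 <- feedback_motif("LN2", "DM4", id = "B")
  c12 <- attach_motif(attach_motif(al_circuit(g), m1), m2)
  c21 <- attach_motif(attach_motif(al_circuit(g), m2), m1)
  key <- function(cir) {
    e <- cir$edges
    sort(paste(e$pre, e$post, e$type, e$gbar, e$erev, e$kappa))
  }
  expect_identical(key(c12), key(c21))
  expect_identical(sort(c12$neurons$id), sort(c21$neurons$id))
})

test_that("the crossbar realizes every 1 digit and only those", {
  gloms <- list(build_glomerulus("G1", 2, 1, 8),
                build_glomerulus("G2", 2, 1, 8))
  m <- matrix(c("1111", "1111", "1111", "1111"), 2, 2,
              dimnames = list(c("LNa", "LNb"), c("G1", "G2")))
  cir <- build_crossbar(gloms, m)
  e <- cir$edges[!is.na(cir$edges$port), ]
  # 2 LNs x 2 glomeruli x 4 ports = 16 port connections
  expect_equal(nrow(unique(e[c("motif", "glomerulus", "port")])), 16)
  expect_true(audit_port_licensing(cir))

  m2 <- matrix(c("1100", "0000", "0011", "0010"), 2, 2,
               dimnames = list(c("LNa", "LNb"), c("G1", "G2")))
  cir2 <- build_crossbar(gloms, m2)
  e2 <- cir2$edges[!is.na(cir2$edges$port), ]
  got <- unique(e2[c("motif", "glomerulus", "port")])
  expect_equal(nrow(got), 2 + 2 + 1)

  bad <- m; colnames(bad) <- c("G1", "G9")
  expect_error(build_crossbar(gloms, bad), "unknown glomerulus")
  zero <- matrix("0000", 1, 2, dimnames = list("LNz", c("G1", "G2")))
  expect_warning(build_crossbar(gloms, zero), "all-zero")
})

test_that("port-pattern extraction inverts crossbar composition", {
  gloms <- list(build_glomerulus("G1", 3, 2, 8),
                build_glomerulus("G2", 2, 2, 8))
  m <- matrix(c("1100", "1111", "0011", "1000",
                "0101", "0000", "1110", "0001"), 4, 2,
              dimnames = list(paste0("LN-", 1:4), c("G1", "G2")))
  cir <- build_crossbar(gloms, m)
  tables <- circuit_to_synapse_table(cir)
  rep <- port_pattern_report(tables)
  for (ln in rownames(m)) {
    for (g in colnames(m)) {
      row <- rep[rep$ln_id == ln & rep$glomerulus == g, ]
      got <- if (nrow(row) == 0) "0000" else row$pattern
      expect_identical(got, m[ln, g],
                       label = sprintf("pattern of %s in %s", ln, g))
    }
  }
})

test_that("ablation removes motif edges, is idempotent and invertible", {
  g <- build_glomerulus("DM4", 3, 1, 10)
  cir <- attach_motif(al_circuit(g), feedback_motif("LN1", "DM4",
                                                    id = "LN1"))
  cir <- attach_motif(cir, feedback_motif("LN2", "DM4", id = "LN2"))
  key <- function(cir) {
    e <- cir$edges
    sort(paste(e$pre, e$post, e$type, e$gbar, e$erev))
  }
  before <- key(cir)
  abl <- ablate(cir, "LN2")
  expect_false(any(!is.na(abl$edges$motif) & abl$edges$motif == "LN2"))
  expect_true("LN2" %in% abl$neurons$id)      # neuron retained
  expect_identical(key(ablate(abl, "LN2")), key(abl))   # idempotent
  expect_identical(key(restore_motif(abl, "LN2")), before)
  expect_error(ablate(cir, "nope"), "unknown motif")
})

test_that("the audit reports unlicensed edges", {
  g <- build_glomerulus("DM4", 2, 1, 10)
  cir <- attach_motif(al_circuit(g), feedback_motif("LN1", "DM4",
                                                    id = "LN1"))
  rogue <- cir$edges[nrow(cir$edges), , drop = FALSE]
  rogue$port <- 3L   # claims the LN->PN port, which 1100 does not license
  cir$edges <- rbind(cir$edges, rogue)
  bad <- audit_port_licensing(cir)
  expect_s3_class(bad, "data.frame")
  expect_equal(nrow(bad), 1)
  expect_equal(bad$port, 3L)
})

test_that("circuits round-trip through JSON serialization", {
  fx <- make_pair_fixture()
  cir <- interconnect_pair(fx$glom_a, fx$glom_b, fx$motif_spec)
  path <- tempfile(fileext = ".json")
  write_circuit(cir, path)
  back <- read_circuit(path)
  expect_equal(back$neurons$id, cir$neurons$id)
  expect_equal(back$edges$gbar, cir$edges$gbar)
  expect_equal(back$edges$pre, cir$edges$pre)
  expect_equal(names(back$motifs), names(cir$motifs))
  expect_equal(back$motifs$LN1_DM4$patterns, cir$motifs$LN1_DM4$patterns)
  expect_true(audit_port_licensing(back))
})
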