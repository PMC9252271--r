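test_that("the 15 port patterns enumerate all nonzero 4-bit codes", {
  pats <- enumerate_port_patterns()
  expect_length(pats, 15)
  expect_false(anyDuplicated(pats) > 0)
  expect_false("0000" %in% pats)
  expect_true(all(c("1111", "1100", "0011") %in% pats))
  # brute force: all 16 codes from first principles
  brute <- apply(expand.grid(0:1, 0:1, 0:1, 0:1), 1, paste, collapse = "")
  expect_setequal(pats, setdiff(brute, "0000"))
})

test_that("exactly 8 patterns close an intra-glomerular feedback loop", {
  expect_true(is_feedback_pattern("1100"))
  expect_true(is_feedback_pattern("1001"))
  expect_false(is_feedback_pattern("0110"))
  expect_error(is_feedback_pattern("11x0"), "malformed")
  expect_error(is_feedback_pattern("111"), "malformed")

  pats <- enumerate_port_patterns()
  expect_equal(sum(is_feedback_pattern(pats)), 8)

  # independent brute force: digit-wise evaluation of the three clauses
  # (out->OSN & in<-OSN) | (out->PN & in<-PN) | (out->OSN & in<-PN)
  brute <- vapply(pats, function(p) {
    d <- as.integer(strsplit(p, "")[[1]])
    (d[1] & d[2]) || (d[3] & d[4]) || (d[1] & d[4])
  }, logical(1))
  expect_equal(unname(is_feedback_pattern(pats)), unname(brute))
})

test_that("confidence filtering needs both sites strictly above 0.70", {
  s <- data.frame(pre_id = "a", post_id = "b",
                  pre_conf = c(0.71, 0.70, 0.90, 0.90),
                  post_conf = c(0.90, 0.90, 0.50, 0.71),
                  glomerulus = "DL5", stringsAsFactors = FALSE)
  kept <- filter_by_confidence(s)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$pre_conf, c(0.71, 0.90))
})

test_that("port patterns follow the total and digit threshold rules", {
  expect_equal(derive_port_pattern(c(10, 10, 10, 10)), "1111")
  expect_equal(derive_port_pattern(c(1, 1, 1, 1)), "0000")   # total 4 < 5
  expect_equal(derive_port_pattern(c(0, 8, 9, 7)), "0111")
  expect_equal(derive_port_pattern(c(2, 2, 1, 1)), "0000")   # ambiguous band
  expect_equal(derive_port_pattern(c(5, 5, 5, 5)), "0000")   # 5 is not > 5
  expect_equal(derive_port_pattern(c(6, 0, 0, 0)), "1000")
  expect_equal(derive_port_pattern(c(0, 0, 0, 6)), "0001")
  expect_error(derive_port_pattern(c(1, 2, 3)), "four nonnegative")
})

test_that("port counts are restricted to glomerulus and partner class", {
  tb <- mini_tables()
  syn <- filter_by_confidence(tb$synapses)
  counts <- count_port_synapses("ln1", "DL5", syn, tb$neurons)
  # low-confidence ln1->osn3 rows must not appear
  expect_equal(unname(counts), c(8, 10, 0, 0))
  expect_equal(names(counts), c("ln_to_osn", "osn_to_ln", "ln_to_pn",
                                "pn_to_ln"))
  # LN with synapses only in DM4, queried for DL5
  expect_equal(unname(count_port_synapses("ln3", "DL5", syn, tb$neurons)),
               c(0, 0, 0, 0))
  # vPN contacts excluded from PN counts by default, included on toggle
  c2 <- count_port_synapses("ln2", "DL5", syn, tb$neurons)
  expect_equal(unname(c2), c(0, 0, 8, 9))
  c2v <- count_port_synapses("ln2", "DL5", syn, tb$neurons,
                             extraction_config(exclude_vpn = FALSE))
  expect_equal(unname(c2v), c(0, 0, 14, 15))
  expect_error(count_port_synapses("osn1", "DL5", syn, tb$neurons),
               "not an LN")
})

test_that("feedback-loop classes follow the directed-total rules", {
  cl <- function(...) classify_loop_totals(...)
  expect_equal(cl(12, 9, 1, 2), "OSN-LN-OSN")
  expect_equal(cl(0, 0, 7, 11), "PN-LN-PN")
  expect_equal(cl(0, 0, 0, 0), "none")
  expect_equal(cl(10, 10, 10, 10), "OSN/PN-LN-OSN/PN")
  expect_equal(cl(6, 6, 4, 4), "none")   # PN total 8 not < 5, not all > 5
  expect_equal(cl(6, 6, 2, 2), "OSN-LN-OSN")  # PN total 4 < 5
  expect_equal(cl(5, 9, 1, 1), "none")   # 5 is not > 5

  # the three rules are mutually exclusive over random totals
  set.seed(42)
  for (i in 1:200) {
    x <- sample(0:12, 4, replace = TRUE)
    r1 <- x[1] > 5 && x[2] > 5 && (x[3] + x[4]) < 5
    r2 <- x[3] > 5 && x[4] > 5 && (x[1] + x[2]) < 5
    r3 <- all(x > 5)
    expect_lte(r1 + r2 + r3, 1)
    got <- cl(x[1], x[2], x[3], x[4])
    want <- if (r1) "OSN-LN-OSN" else if (r2) "PN-LN-PN" else
      if (r3) "OSN/PN-LN-OSN/PN" else "none"
    expect_identical(got, want)
  }
})

test_that("loop classification runs on tables with glomerulus scoping", {
  tb <- mini_tables()
  syn <- filter_by_confidence(tb$synapses)
  expect_equal(classify_feedback_loop("ln1", NULL, syn, tb$neurons),
               "OSN-LN-OSN")
  expect_equal(classify_feedback_loop("ln2", NULL, syn, tb$neurons),
               "PN-LN-PN")
  expect_equal(classify_feedback_loop("ln3", "DM4", syn, tb$neurons),
               "OSN/PN-LN-OSN/PN")
  expect_equal(classify_feedback_loop("ln3", "DL5", syn, tb$neurons),
               "none")
  expect_error(classify_feedback_loop("pn1", NULL, syn, tb$neurons),
               "not an LN")
})

test_that("LN inclusion requires strictly more than 10 synapses", {
  neurons <- data.frame(neuron_id = c("a", "b", "c", "o"),
                        cell_class = c("LN", "LN", "LN", "OSN"),
                        receptor_type = c("", "", "", "Or1"),
                        pn_subtype = "none", glomeruli = "",
                        stringsAsFactors = FALSE)
  syn <- rbind(syn_rows("a", "o", 11, "G"),  # 11 > 10: kept
               syn_rows("b", "o", 6, "G"), syn_rows("o", "b", 4, "G"))  # 10
  expect_identical(select_al_lns(neurons, syn), "a")
})

test_that("tables parse with validation and row-numbered errors", {
  paths <- write_mini_tables()
  tb <- read_tables(paths$synapses, paths$neurons)
  expect_equal(nrow(tb$synapses), nrow(mini_tables()$synapses))
  expect_equal(nrow(tb$neurons), 12)

  bad <- corrupt_fixture(mini_tables(), "dangling_id")
  p <- write_mini_tables(bad)
  expect_error(read_tables(p$synapses, p$neurons),
               "row 1.*no-such-neuron")

  bad <- corrupt_fixture(mini_tables(), "bad_confidence")
  p <- write_mini_tables(bad)
  expect_error(read_tables(p$synapses, p$neurons), "not in \\[0, 1\\]")

  bad <- corrupt_fixture(mini_tables(), "missing_column")
  p <- write_mini_tables(bad)
  expect_error(read_tables(p$synapses, p$neurons),
               "missing column.*glomerulus")
})

test_that("TSV tables are accepted alongside CSV", {
  tb <- mini_tables()
  dir <- tempfile(); dir.create(dir)
  sp <- file.path(dir, "synapses.tsv"); np <- file.path(dir, "neurons.tsv")
  write.table(tb$synapses, sp, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(tb$neurons, np, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_tables(sp, np)
  expect_equal(nrow(back$synapses), nrow(tb$synapses))
})

test_that("the pattern report integrates filtering, counting and classes", {
  rep <- port_pattern_report(mini_tables())
  # ln4 (10 synapses, not > 10) must be excluded
  expect_false("ln4" %in% rep$ln_id)
  r1 <- rep[rep$ln_id == "ln1" & rep$glomerulus == "DL5", ]
  expect_equal(r1$pattern, "1100")
  expect_true(r1$feedback)
  expect_equal(r1$loop_class, "OSN-LN-OSN")
  r3 <- rep[rep$ln_id == "ln3" & rep$glomerulus == "DM4", ]
  expect_equal(r3$pattern, "1111")
  expect_equal(r3$loop_class, "OSN/PN-LN-OSN/PN")
})

test_that("cell-type graphs apply the edge filter and keep self-loops", {
  neurons <- data.frame(
    neuron_id = c("a1", "a2", "b1"), cell_class = c("OSN", "OSN", "LN"),
    receptor_type = c("OrX", "OrX", ""), pn_subtype = "none",
    glomeruli = "G", stringsAsFactors = FALSE)
  syn <- rbind(syn_rows("a1", "b1", 2, "G"), syn_rows("a2", "b1", 1, "G"),
               syn_rows("a1", "a2", 2, "G"))
  g <- celltype_graph(neurons, syn, "cell_type", min_synapses = 0)
  ed <- igraph::as_data_frame(g)
  expect_equal(nrow(ed), 2)
  expect_equal(ed$weight[ed$to == "b1"], 3)       # grouped OSN:OrX -> LN
  self <- ed[ed$from == ed$to, ]
  expect_equal(self$weight, 2)                    # axo-axonal self-loop
  g5 <- celltype_graph(neurons, syn, "cell_type", min_synapses = 5)
  expect_equal(igraph::ecount(g5), 0)
})

test_that("neuron-level graph collapsed by group equals cell-type graph", {
  tb <- mini_tables()
  gn <- celltype_graph(tb$neurons, tb$synapses, "neuron")
  gt <- celltype_graph(tb$neurons, tb$synapses, "cell_type")
  lab <- antennalobe:::celltype_group_label(tb$neurons)
  names(lab) <- tb$neurons$neuron_id
  en <- igraph::as_data_frame(gn)
  en$from <- unname(lab[en$from]); en$to <- unname(lab[en$to])
  coll <- stats::aggregate(weight ~ from + to, en, sum)
  et <- igraph::as_data_frame(gt)
  key <- function(d) paste(d$from, d$to, d$weight)
  expect_setequal(key(coll), key(et))
})

test_that("graphs export to GraphML and edge-list CSV", {
  tb <- mini_tables()
  g <- celltype_graph(tb$neurons, tb$synapses, "cell_type")
  gml <- tempfile(fileext = ".graphml")
  write_graph_file(g, gml, "graphml")
  expect_true(file.exists(gml) && file.size(gml) > 0)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  csv <- tempfile(fileext = ".csv")
  write_graph_file(g, csv, "edgelist")
  ed <- read.csv(csv)
  expect_named(ed, c("from", "to", "weight"))
})
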