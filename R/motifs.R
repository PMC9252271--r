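#' Extraction thresholds for motif and feedback-loop derivation
#'
#' All thresholds are strict inequalities, read literally from the counting
#' rules the connectivity abstraction is built on: a synapse is kept only if
#' both sites are identified at confidence higher than 70%; a port digit is
#' 1 only if its count is larger than 5; a glomerular pattern is "0000" when
#' the glomerular total is less than 5; an LN participates in the analysis
#' only with more than 10 synapses in the antennal lobe. Counts equal to a
#' threshold fail it.
#'
#' @param confidence_threshold synapse site confidence bound (strict `>`).
#' @param pattern_total_threshold glomerular total below which the pattern
#'   is `"0000"` (strict `<`).
#' @param digit_threshold per-port count bound for a digit to be 1
#'   (strict `>`).
#' @param loop_high directed-total bound for feedback-loop membership
#'   (strict `>`).
#' @param loop_low opposite-class total bound (strict `<`).
#' @param ln_inclusion_min total antennal-lobe synapse bound for an LN to be
#'   analysed (strict `>`).
#' @param exclude_vpn drop vPNs from PN port counts (default `TRUE`).
#' @return A list of class `extraction_config`.
#' @export
extraction_config <- function(confidence_threshold = 0.70,
                              pattern_total_threshold = 5,
                              digit_threshold = 5,
                              loop_high = 5,
                              loop_low = 5,
                              ln_inclusion_min = 10,
                              exclude_vpn = TRUE) {
  cfg <- list(confidence_threshold = confidence_threshold,
              pattern_total_threshold = pattern_total_threshold,
              digit_threshold = digit_threshold,
              loop_high = loop_high,
              loop_low = loop_low,
              ln_inclusion_min = ln_inclusion_min,
              exclude_vpn = isTRUE(exclude_vpn))
  num <- unlist(cfg[1:6])
  if (any(num < 0)) stop("thresholds must be nonnegative", call. = FALSE)
  class(cfg) <- "extraction_config"
  cfg
}

PN_SUBTYPES <- c("uPN-adPN", "uPN-lPN", "vPN", "none")

#' Read synapse and neuron annotation tables
#'
#' The synapse table has one row per synapse with columns
#' `pre_id, post_id, pre_conf, post_conf, glomerulus`; the neuron table has
#' columns `neuron_id, cell_class, receptor_type, pn_subtype, glomeruli`
#' (the last a semicolon-joined label set). Both CSV and TSV are accepted
#' (delimiter sniffed from the header line). Every field is validated;
#' errors carry the offending row number.
#'
#' @param synapse_file,neuron_file paths to the two tables.
#' @return A list with data frames `synapses` and `neurons`.
#' @export
read_tables <- function(synapse_file, neuron_file) {
  neurons <- read_delim_sniff(neuron_file)
  need <- c("neuron_id", "cell_class", "receptor_type", "pn_subtype", "glomeruli")
  miss <- setdiff(need, names(neurons))
  if (length(miss) > 0L) {
    stop("neuron table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  neurons <- neurons[need]
  for (col in need) neurons[[col]] <- as.character(neurons[[col]])
  if (anyDuplicated(neurons$neuron_id)) {
    stop("duplicate neuron_id in neuron table: ",
         neurons$neuron_id[anyDuplicated(neurons$neuron_id)], call. = FALSE)
  }
  bad <- which(!neurons$cell_class %in% c("OSN", "PN", "LN"))
  if (length(bad) > 0L) {
    stop("neuron table row ", bad[1L], ": invalid cell_class '",
         neurons$cell_class[bad[1L]], "'", call. = FALSE)
  }
  bad <- which(neurons$cell_class == "OSN" &
                 (is.na(neurons$receptor_type) | neurons$receptor_type == ""))
  if (length(bad) > 0L) {
    stop("neuron table row ", bad[1L], ": OSN without receptor_type",
         call. = FALSE)
  }
  bad <- which(neurons$cell_class == "PN" &
                 !neurons$pn_subtype %in% PN_SUBTYPES[1:3])
  if (length(bad) > 0L) {
    stop("neuron table row ", bad[1L], ": PN without valid pn_subtype",
         call. = FALSE)
  }

  synapses <- read_delim_sniff(synapse_file)
  need <- c("pre_id", "post_id", "pre_conf", "post_conf", "glomerulus")
  miss <- setdiff(need, names(synapses))
  if (length(miss) > 0L) {
    stop("synapse table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  synapses <- synapses[need]
  synapses$pre_id <- as.character(synapses$pre_id)
  synapses$post_id <- as.character(synapses$post_id)
  synapses$glomerulus <- as.character(synapses$glomerulus)
  for (col in c("pre_conf", "post_conf")) {
    v <- suppressWarnings(as.numeric(synapses[[col]]))
    bad <- which(is.na(v) | v < 0 | v > 1)
    if (length(bad) > 0L) {
      stop("synapse table row ", bad[1L], ": ", col, " = '",
           synapses[[col]][bad[1L]], "' is not in [0, 1]", call. = FALSE)
    }
    synapses[[col]] <- v
  }
  known <- neurons$neuron_id
  bad <- which(!(synapses$pre_id %in% known & synapses$post_id %in% known))
  if (length(bad) > 0L) {
    i <- bad[1L]
    dangling <- setdiff(c(synapses$pre_id[i], synapses$post_id[i]), known)[1L]
    stop("synapse table row ", i, ": unknown neuron id '", dangling, "'",
         call. = FALSE)
  }
  list(synapses = synapses, neurons = neurons)
}

read_delim_sniff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    strip.white = TRUE)
}

#' Confidence-filter a synapse table
#'
#' Keeps a synapse only when both its presynaptic and postsynaptic site
#' confidences exceed the threshold (strict `>`, default 0.70).
#'
#' @param synapses synapse data frame from [read_tables()].
#' @param cfg an [extraction_config()].
#' @return The filtered synapse data frame.
#' @export
filter_by_confidence <- function(synapses, cfg = extraction_config()) {
  keep <- synapses$pre_conf > cfg$confidence_threshold &
    synapses$post_conf > cfg$confidence_threshold
  synapses[keep, , drop = FALSE]
}

#' Count an LN's synapses at the four ports of one glomerulus
#'
#' For one (LN, glomerulus) pair, counts synapses the LN makes with partner
#' OSNs and PNs within that glomerulus, in the four port directions
#' LN->OSN, LN<-OSN, LN->PN, LN<-PN. vPNs are excluded from the PN counts
#' unless `cfg$exclude_vpn` is `FALSE`. Synapses must already be
#' confidence-filtered.
#'
#' @param ln_id the LN's neuron id.
#' @param glomerulus glomerulus label.
#' @param synapses confidence-filtered synapse data frame.
#' @param neurons neuron annotation data frame.
#' @param cfg an [extraction_config()].
#' @return Named integer vector
#'   `c(ln_to_osn, osn_to_ln, ln_to_pn, pn_to_ln)`.
#' @export
count_port_synapses <- function(ln_id, glomerulus, synapses, neurons,
                                cfg = extraction_config()) {
  cls <- stats::setNames(neurons$cell_class, neurons$neuron_id)
  if (is.na(cls[ln_id]) || cls[ln_id] != "LN") {
    stop("'", ln_id, "' is not an LN", call. = FALSE)
  }
  sub <- stats::setNames(neurons$pn_subtype, neurons$neuron_id)
  is_pn_partner <- function(ids) {
    ok <- cls[ids] == "PN"
    if (cfg$exclude_vpn) ok <- ok & sub[ids] != "vPN"
    ok & !is.na(ok)
  }
  s <- synapses[!is.na(synapses$glomerulus) &
                  synapses$glomerulus == glomerulus, , drop = FALSE]
  out_s <- s[s$pre_id == ln_id, , drop = FALSE]
  in_s <- s[s$post_id == ln_id, , drop = FALSE]
  c(ln_to_osn = sum(cls[out_s$post_id] == "OSN", na.rm = TRUE),
    osn_to_ln = sum(cls[in_s$pre_id] == "OSN", na.rm = TRUE),
    ln_to_pn  = sum(is_pn_partner(out_s$post_id)),
    pn_to_ln  = sum(is_pn_partner(in_s$pre_id)))
}

#' Derive the 4-digit port connectivity pattern from port counts
#'
#' If the glomerular total (sum of the four counts) is below the total
#' threshold the pattern is `"0000"` (no connections). Otherwise digit i is
#' `1` exactly when the corresponding count exceeds the digit threshold, in
#' the order LN->OSN, LN<-OSN, LN->PN, LN<-PN. Totals at or above the total
#' threshold where no single count clears the digit threshold also yield
#' `"0000"`; [port_pattern_report()] flags such rows as ambiguous.
#'
#' @param counts integer vector of the four port counts (as returned by
#'   [count_port_synapses()]).
#' @param cfg an [extraction_config()].
#' @return A 4-character string over `{0,1}`.
#' @examples
#' derive_port_pattern(c(10, 10, 10, 10)) # "1111"
#' derive_port_pattern(c(1, 1, 1, 1))     # "0000" (total below threshold)
#' @export
derive_port_pattern <- function(counts, cfg = extraction_config()) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(counts < 0)) {
    stop("counts must be four nonnegative numbers", call. = FALSE)
  }
  if (sum(counts) < cfg$pattern_total_threshold) return("0000")
  paste(ifelse(counts > cfg$digit_threshold, "1", "0"), collapse = "")
}

#' All non-empty port connectivity patterns
#'
#' There are 15 patterns of port connectivity within a glomerulus: every
#' 4-digit binary code except `"0000"`, which denotes no connection.
#'
#' @return Sorted character vector of length 15.
#' @export
enumerate_port_patterns <- function() {
  codes <- vapply(0:15, function(i) {
    paste(rev(as.integer(intToBits(i))[1:4]), collapse = "")
  }, character(1))
  sort(setdiff(codes, "0000"))
}

#' Does a port pattern close a feedback loop within its glomerulus?
#'
#' An LN whose innervation follows pattern `11xx`, `xx11` or `1xx1` forms a
#' feedback loop within the glomerulus: it both writes to and reads from
#' the glomerulus through a closed port pair. Eight of the 15 patterns
#' qualify.
#'
#' @param pattern a 4-character pattern string (vectorized).
#' @return Logical vector.
#' @export
is_feedback_pattern <- function(pattern) {
  ok <- grepl("^[01]{4}$", pattern)
  if (any(!ok)) {
    stop("malformed port pattern: '", pattern[!ok][1L], "'", call. = FALSE)
  }
  grepl("^11", pattern) | grepl("11$", pattern) | grepl("^1..1$", pattern)
}

#' Classify an LN's feedback loop
#'
#' Over a glomerulus scope (one glomerulus label, several, or all when
#' `NULL`), totals the LN's directed synapse counts with OSNs and with PNs
#' and applies the loop rules: OSN-LN-OSN needs more than `loop_high`
#' synapses from the OSNs and to the OSNs and fewer than `loop_low` with
#' the PNs (both directions summed); PN-LN-PN is the mirror image;
#' OSN/PN-LN-OSN/PN needs all four directed totals above `loop_high`.
#'
#' @param ln_id the LN's neuron id.
#' @param glomerulus_scope glomerulus label(s) to restrict to, or `NULL`
#'   for the whole table.
#' @param synapses confidence-filtered synapse data frame.
#' @param neurons neuron annotation data frame.
#' @param cfg an [extraction_config()].
#' @return One of `"OSN-LN-OSN"`, `"PN-LN-PN"`, `"OSN/PN-LN-OSN/PN"`,
#'   `"none"`.
#' @export
classify_feedback_loop <- function(ln_id, glomerulus_scope = NULL,
                                   synapses, neurons,
                                   cfg = extraction_config()) {
  cls <- stats::setNames(neurons$cell_class, neurons$neuron_id)
  if (is.na(cls[ln_id]) || cls[ln_id] != "LN") {
    stop("'", ln_id, "' is not an LN", call. = FALSE)
  }
  s <- synapses
  if (!is.null(glomerulus_scope)) {
    s <- s[!is.na(s$glomerulus) & s$glomerulus %in% glomerulus_scope, ,
           drop = FALSE]
  }
  sub <- stats::setNames(neurons$pn_subtype, neurons$neuron_id)
  partner_is <- function(ids, what) {
    ok <- cls[ids] == what
    if (what == "PN" && cfg$exclude_vpn) ok <- ok & sub[ids] != "vPN"
    sum(ok, na.rm = TRUE)
  }
  out_s <- s[s$pre_id == ln_id, , drop = FALSE]
  in_s <- s[s$post_id == ln_id, , drop = FALSE]
  to_osn <- partner_is(out_s$post_id, "OSN")
  from_osn <- partner_is(in_s$pre_id, "OSN")
  to_pn <- partner_is(out_s$post_id, "PN")
  from_pn <- partner_is(in_s$pre_id, "PN")
  classify_loop_totals(from_osn, to_osn, from_pn, to_pn, cfg)
}

# loop rules on the four directed totals; exposed for direct testing
classify_loop_totals <- function(from_osn, to_osn, from_pn, to_pn,
                                 cfg = extraction_config()) {
  hi <- cfg$loop_high; lo <- cfg$loop_low
  if (from_osn > hi && to_osn > hi && (from_pn + to_pn) < lo) {
    "OSN-LN-OSN"
  } else if (from_pn > hi && to_pn > hi && (from_osn + to_osn) < lo) {
    "PN-LN-PN"
  } else if (from_osn > hi && to_osn > hi && from_pn > hi && to_pn > hi) {
    "OSN/PN-LN-OSN/PN"
  } else {
    "none"
  }
}

#' Select the LNs participating in antennal-lobe analysis
#'
#' Keeps LNs whose total synapse count in the table (presynaptic plus
#' postsynaptic, after confidence filtering) exceeds the inclusion
#' threshold (strict `>`, default 10).
#'
#' @param neurons neuron annotation data frame.
#' @param synapses confidence-filtered synapse data frame.
#' @param cfg an [extraction_config()].
#' @return Character vector of LN ids.
#' @export
select_al_lns <- function(neurons, synapses, cfg = extraction_config()) {
  lns <- neurons$neuron_id[neurons$cell_class == "LN"]
  tot <- table(factor(c(synapses$pre_id, synapses$post_id), levels = lns))
  names(tot)[tot > cfg$ln_inclusion_min]
}

#' Port pattern report for every (LN, glomerulus) pair
#'
#' Runs the whole extraction pipeline: confidence filtering, LN inclusion,
#' per-(LN, glomerulus) port counts, pattern derivation, the feedback-
#' pattern flag, and the feedback-loop class restricted to the glomerulus.
#' Rows whose glomerular total reaches the total threshold without any
#' single count clearing the digit threshold are flagged `ambiguous`.
#'
#' @param tables list with `synapses` and `neurons` (see [read_tables()]).
#' @param cfg an [extraction_config()].
#' @return Data frame with one row per (LN, glomerulus) pair carrying
#'   nonzero counts: ids, the four counts, `pattern`, `feedback`,
#'   `loop_class`, `ambiguous`.
#' @export
port_pattern_report <- function(tables, cfg = extraction_config()) {
  syn <- filter_by_confidence(tables$synapses, cfg)
  neurons <- tables$neurons
  lns <- select_al_lns(neurons, syn, cfg)
  gloms <- sort(unique(syn$glomerulus[!is.na(syn$glomerulus) &
                                        syn$glomerulus != ""]))
  rows <- list()
  for (ln in lns) {
    for (g in gloms) {
      counts <- count_port_synapses(ln, g, syn, neurons, cfg)
      if (sum(counts) == 0L) next
      pattern <- derive_port_pattern(counts, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        ln_id = ln, glomerulus = g,
        ln_to_osn = counts[[1L]], osn_to_ln = counts[[2L]],
        ln_to_pn = counts[[3L]], pn_to_ln = counts[[4L]],
        pattern = pattern,
        feedback = is_feedback_pattern(pattern),
        loop_class = classify_feedback_loop(ln, g, syn, neurons, cfg),
        ambiguous = sum(counts) >= cfg$pattern_total_threshold &&
          all(counts <= cfg$digit_threshold),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(ln_id = character(), glomerulus = character(),
                      ln_to_osn = integer(), osn_to_ln = integer(),
                      ln_to_pn = integer(), pn_to_ln = integer(),
                      pattern = character(), feedback = logical(),
                      loop_class = character(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type connectivity graph
#'
#' Builds the directed connectivity graph of a synapse table at neuron or
#' cell-type granularity. At cell-type level, OSNs collapse to one node per
#' receptor type, PNs to one node per (glomerulus, subtype) group, and LNs
#' stay individual. A directed edge exists when the summed synapse count
#' from source group to target group is at least `max(1, min_synapses)`;
#' the edge weight is that count. Self-loops are kept (they carry e.g.
#' axo-axonal OSN-OSN blocks).
#'
#' @param neurons neuron annotation data frame.
#' @param synapses synapse data frame (filter first if desired).
#' @param group_by `"neuron"` or `"cell_type"`.
#' @param min_synapses minimum synapse count `N >= 0` for an edge.
#' @return An [igraph::igraph] directed graph with edge attribute `weight`.
#' @export
celltype_graph <- function(neurons, synapses,
                           group_by = c("cell_type", "neuron"),
                           min_synapses = 0) {
  group_by <- match.arg(group_by)
  if (min_synapses < 0) stop("min_synapses must be >= 0", call. = FALSE)
  grp <- if (group_by == "neuron") {
    stats::setNames(neurons$neuron_id, neurons$neuron_id)
  } else {
    stats::setNames(celltype_group_label(neurons), neurons$neuron_id)
  }
  ec <- stats::aggregate(
    list(weight = rep(1L, nrow(synapses))),
    by = list(from = unname(grp[synapses$pre_id]),
              to = unname(grp[synapses$post_id])),
    FUN = sum
  )
  ec <- ec[ec$weight >= max(1, min_synapses), , drop = FALSE]
  igraph::graph_from_data_frame(
    ec, directed = TRUE,
    vertices = data.frame(name = unique(unname(grp)),
                          stringsAsFactors = FALSE)
  )
}

celltype_group_label <- function(neurons) {
  ifelse(neurons$cell_class == "OSN",
         paste0("OSN:", neurons$receptor_type),
         ifelse(neurons$cell_class == "PN",
                paste0("PN:", neurons$glomeruli, ":", neurons$pn_subtype),
                neurons$neuron_id))
}

#' Export a connectivity graph
#'
#' Writes a graph from [celltype_graph()] as GraphML or as an edge-list CSV
#' (`from,to,weight`).
#'
#' @param graph an igraph object.
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(graph, what = "edges")
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
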