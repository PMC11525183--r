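# Independent oracles used across tests.

# Connected same-label components via igraph (independent of the union-find
# scan in find_patches).
oracle_patches <- function(grid, connectivity = 4) {
  nr <- nrow(grid); nc <- ncol(grid)
  cells <- which(grid != "none")
  if (length(cells) == 0) {
    return(list(patches = data.frame(label = character(0), size = integer(0)),
                membership = integer(0)))
  }
  coord <- arrayInd(cells, dim(grid))
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(-1, 1)))
  edges <- NULL
  for (o in offs) {
    r2 <- coord[, 1] + o[1]; c2 <- coord[, 2] + o[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    j <- (c2 - 1) * nr + r2
    ok[ok] <- grid[j[ok]] == grid[cells[ok]]
    if (any(ok)) {
      edges <- rbind(edges, cbind(match(cells[ok], cells),
                                  match(j[ok], cells)))
    }
  }
  g <- igraph::make_empty_graph(length(cells), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  sizes <- tabulate(memb)
  labels <- grid[cells][match(seq_along(sizes), memb)]
  list(patches = data.frame(label = labels, size = sizes,
                            stringsAsFactors = FALSE),
       membership = as.integer(memb), cells = cells)
}

# Canonical renumbering of a partition by first appearance, for comparing
# partitions irrespective of component ids.
canonical_partition <- function(memb) {
  as.integer(factor(memb, levels = unique(memb)))
}

# Minimal hand-built ground-truth object for gen_variant_table tests.
make_truth <- function(tumour_id, purity, fractions, codons,
                       labels = NULL) {
  stopifnot(length(fractions) == length(codons))
  founders <- data.frame(
    tumour_id = tumour_id,
    founder = seq_along(fractions),
    label = labels %||% rep("none", length(fractions)),
    fraction = fractions,
    codon = as.integer(codons),
    growth_rate = 0.05,
    stringsAsFactors = FALSE)
  tumours <- data.frame(
    tumour_id = tumour_id,
    class = if (length(fractions) > 1) "polyclonal" else "monoclonal",
    purity = purity,
    day = 100L,
    stringsAsFactors = FALSE)
  structure(list(tumours = tumours, founders = founders,
                 apc_bin_probs = default_bin_probs()$monoclonal),
            class = "cohort_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Worked amplicon-filter examples: one passing call, one failing the mutant-
# read rule, one indel, one single-amplicon-window call.
worked_examples <- function() {
  data.frame(
    sample_id = "S1",
    gene = "Apc",
    codon = c(1300L, 1300L, 700L, 80L),
    aa_change = NA_character_,
    consequence = c("stop_gained", "stop_gained", "indel", "stop_gained"),
    vaf = c(0.20, 0.20, 0.30, 0.05),
    depth = 500L,
    alt_reads = c(50L, 4L, 150L, 6L),
    n_amplicons = c(2L, 2L, 2L, 1L),
    stringsAsFactors = FALSE)
}

apc_call <- function(vaf, codon, consequence = "stop_gained",
                     sample_id = "T1") {
  data.frame(sample_id = sample_id, gene = "Apc", codon = codon,
             aa_change = NA_character_, consequence = consequence,
             vaf = vaf, depth = 500L, alt_reads = as.integer(round(vaf * 500)),
             n_amplicons = 2L, stringsAsFactors = FALSE)
}

random_variant_table <- function(n, seed) {
  set.seed(seed)
  depth <- sample(100:1000, n, replace = TRUE)
  alt <- pmin(depth, stats::rpois(n, 20))
  data.frame(
    sample_id = sample(sprintf("S%02d", 1:8), n, replace = TRUE),
    gene = sample(c("Apc", "Kras", "Trp53"), n, replace = TRUE),
    codon = sample(1:2000, n, replace = TRUE),
    aa_change = NA_character_,
    consequence = sample(c("stop_gained", "missense", "indel", "synonymous"),
                         n, replace = TRUE),
    vaf = alt / depth,
    depth = depth,
    alt_reads = alt,
    n_amplicons = sample(1:3, n, replace = TRUE),
    stringsAsFactors = FALSE)
}
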