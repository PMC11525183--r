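#' Confetti fluorophore labelling frequencies
#'
#' Per-crypt probabilities that a crypt expresses a given Confetti colour.
#' Defaults are the observed recombination frequencies in the mouse intestine
#' (CFP 2.7%, YFP 4.1%, RFP 3.8%); GFP is retained in the alphabet with a
#' default frequency of zero because nuclear GFP is rarely scored in
#' wholemounts. The remainder (1 - sum) is the unlabelled fraction.
#'
#' @param CFP,YFP,RFP,GFP per-crypt labelling probabilities.
#' @return A named numeric vector of per-colour probabilities.
#' @examples
#' confetti_freqs()
#' sum(confetti_freqs())  # ~0.106 labelled overall
#' @export
confetti_freqs <- function(CFP = 0.027, YFP = 0.041, RFP = 0.038, GFP = 0) {
  freqs <- c(CFP = CFP, YFP = YFP, RFP = RFP, GFP = GFP)
  validate_label_freqs(freqs)
  freqs
}

#' Validate a label-frequency vector
#'
#' @param freqs named numeric vector of per-colour probabilities.
#' @return `freqs`, invisibly, if valid; otherwise an error.
#' @export
validate_label_freqs <- function(freqs) {
  abort_if(!is.numeric(freqs) || is.null(names(freqs)) ||
             any(!nzchar(names(freqs))) || anyDuplicated(names(freqs)) > 0,
           "label frequencies must be a uniquely named numeric vector")
  abort_if("none" %in% names(freqs),
           "'none' is reserved for the unlabelled state")
  abort_if(!is_prob(freqs), "label frequencies must lie in [0, 1]")
  abort_if(sum(freqs) > 1 + 1e-12,
           "label frequencies sum to more than 1 (no unlabelled remainder)")
  invisible(freqs)
}

#' Simulate Confetti labelling of a crypt field
#'
#' Assigns each crypt of a `rows x cols` field an independent label draw:
#' colour `c` with probability `freqs[c]`, otherwise `"none"`. This is the
#' null model for patch statistics in unperturbed epithelium.
#'
#' @param rows,cols field dimensions in crypts (the reference field is
#'   10 x 100).
#' @param freqs label frequencies, see [confetti_freqs()].
#' @param seed optional integer seed; the draw is deterministic given it.
#' @return A character matrix of dimension `rows x cols` over the label
#'   alphabet plus `"none"`.
#' @examples
#' g <- simulate_labelling(10, 100, seed = 1)
#' mean(g != "none")
#' @export
simulate_labelling <- function(rows, cols, freqs = confetti_freqs(),
                               seed = NULL) {
  abort_if(!is_count(rows) || !is_count(cols) || rows < 1 || cols < 1,
           "grid dimensions must be positive integers")
  validate_label_freqs(freqs)
  alphabet <- c(names(freqs), "none")
  p <- c(freqs, none = 1 - sum(freqs))
  with_seed(seed, {
    matrix(sample(alphabet, rows * cols, replace = TRUE, prob = p),
           nrow = rows, ncol = cols)
  })
}

#' Fraction of labelled crypts in a grid
#'
#' @param grid character matrix from [simulate_labelling()].
#' @return Proportion of cells that carry any colour.
#' @export
labelled_fraction <- function(grid) {
  abort_if(!is.matrix(grid), "grid must be a matrix")
  mean(grid != "none")
}

#' Find contiguous same-colour patches
#'
#' Partitions the labelled cells of a crypt grid into maximal connected
#' components of identical colour ("patches"). Unlabelled (`"none"`) cells
#' never belong to a patch. Connectivity 4 (von Neumann, the default and the
#' conservative reading of "contiguous") or 8 (adds diagonals). The field has
#' hard edges (no wrap-around).
#'
#' @param grid character matrix of labels.
#' @param connectivity 4 or 8.
#' @return A data.frame with columns `patch_id`, `label`, `size`, one row per
#'   patch. The integer matrix of per-cell patch membership (0 for unlabelled
#'   cells) is attached as attribute `"membership"`.
#' @examples
#' g <- matrix(c("RFP", "RFP", "none", "YFP"), 2, 2)
#' find_patches(g)
#' @export
find_patches <- function(grid, connectivity = 4) {
  abort_if(!is.matrix(grid), "grid must be a matrix")
  abort_if(!connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- as.vector(grid)
  n <- nr * nc
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  link <- function(a, b) {
    ra <- find_root(a); rb <- find_root(b)
    if (ra != rb) parent[rb] <<- ra
  }
  # union each labelled cell with its right/down (and diagonal) same-label
  # neighbours; scanning half the neighbourhood covers every edge once
  for (cc in seq_len(nc)) {
    base <- (cc - 1L) * nr
    for (rr in seq_len(nr)) {
      i <- base + rr
      if (lab[i] == "none") next
      if (rr < nr && lab[i + 1L] == lab[i]) link(i, i + 1L)
      if (cc < nc) {
        j <- i + nr
        if (lab[j] == lab[i]) link(i, j)
        if (connectivity == 8) {
          if (rr < nr && lab[j + 1L] == lab[i]) link(i, j + 1L)
          if (rr > 1L && lab[j - 1L] == lab[i]) link(i, j - 1L)
        }
      }
    }
  }
  labelled <- which(lab != "none")
  membership <- matrix(0L, nr, nc)
  if (length(labelled) > 0) {
    roots <- vapply(labelled, find_root, integer(1))
    ids <- match(roots, unique(roots))
    membership[labelled] <- ids
    sizes <- tabulate(ids)
    patch_label <- lab[labelled][match(seq_along(sizes), ids)]
    out <- data.frame(patch_id = seq_along(sizes),
                      label = patch_label,
                      size = sizes,
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(patch_id = integer(0), label = character(0),
                      size = integer(0), stringsAsFactors = FALSE)
  }
  attr(out, "membership") <- membership
  out
}

#' Summarise patch sizes across replicate simulations
#'
#' Tabulates, per fluorophore, how many patches of each size were seen and
#' which fraction of that colour's crypts sit in patches of that size (the
#' patch-size distribution of coloured crypts). Fractions sum to 1 within a
#' fluorophore whenever it has any coloured crypt.
#'
#' @param patches a patch table from [find_patches()], or a list of such
#'   tables (one per replicate grid).
#' @return data.frame with columns `label`, `size`, `n_patches`,
#'   `crypt_fraction`.
#' @export
patch_size_summary <- function(patches) {
  if (is.data.frame(patches)) patches <- list(patches)
  abort_if(!is.list(patches), "patches must be a data.frame or list of them")
  all <- do.call(rbind, lapply(patches, function(p) p[c("label", "size")]))
  if (is.null(all) || nrow(all) == 0) {
    return(data.frame(label = character(0), size = integer(0),
                      n_patches = integer(0), crypt_fraction = numeric(0),
                      stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_patches = all$size),
                          by = list(label = all$label, size = all$size),
                          FUN = length)
  agg$crypts <- agg$size * agg$n_patches
  total <- stats::ave(agg$crypts, agg$label, FUN = sum)
  agg$crypt_fraction <- agg$crypts / total
  agg <- agg[order(agg$label, agg$size), ]
  rownames(agg) <- NULL
  agg[c("label", "size", "n_patches", "crypt_fraction")]
}

#' Gland composition of a tumour
#'
#' Observed gland counts of a tumour by Confetti colour, with optional flags
#' for colours represented by a single intermixed gland (most probably an
#' entrapped normal crypt, and therefore disregarded when scoring).
#'
#' @param counts named non-negative numeric vector of gland counts; use the
#'   name `"none"` for unlabelled glands.
#' @param intermixed character vector of colour names whose single gland was
#'   scored as intermixed.
#' @return An object of class `gland_composition`.
#' @examples
#' gland_composition(c(RFP = 9, YFP = 1), intermixed = "YFP")
#' @export
gland_composition <- function(counts, intermixed = character()) {
  abort_if(!is.numeric(counts) || is.null(names(counts)) ||
             any(!nzchar(names(counts))),
           "counts must be a named numeric vector")
  abort_if(any(!is.finite(counts)) || any(counts < 0) ||
             any(counts != floor(counts)),
           "gland counts must be non-negative integers")
  abort_if(sum(counts) < 1, "a composition needs at least one gland")
  abort_if(!is.character(intermixed), "intermixed must be a character vector")
  structure(list(counts = counts, intermixed = intermixed),
            class = "gland_composition")
}

#' Score the Confetti status of a tumour
#'
#' Applies the microscopy rule: a tumour is heterotypic if it shows glands of
#' at least two Confetti colours, or one Confetti colour in the presence of
#' unlabelled glands; homotypic if all scored glands are one colour; and
#' uncoloured if no coloured glands remain. Colours flagged as single
#' intermixed glands are disregarded before scoring.
#'
#' @param comp a [gland_composition()].
#' @return list with elements `status` (one of `"homotypic"`, `"heterotypic"`,
#'   `"uncoloured"`) and `label` (the colour for homotypic tumours, otherwise
#'   `NA`).
#' @examples
#' score_confetti_status(gland_composition(c(RFP = 6, YFP = 4)))
#' score_confetti_status(gland_composition(c(RFP = 6, none = 4)))
#' @export
score_confetti_status <- function(comp) {
  abort_if(!inherits(comp, "gland_composition"),
           "comp must be a gland_composition")
  counts <- comp$counts
  for (l in intersect(comp$intermixed, names(counts))) {
    if (counts[[l]] == 1) counts[[l]] <- 0
  }
  counts <- counts[counts > 0]
  abort_if(length(counts) == 0,
           "no glands remain after discarding intermixed singletons")
  status_from_labels(rep(names(counts), counts))
}

# Core scoring rule on a vector of per-gland (or per-founder) labels.
status_from_labels <- function(labels) {
  coloured <- unique(labels[labels != "none"])
  has_none <- any(labels == "none")
  if (length(coloured) >= 2 || (length(coloured) >= 1 && has_none)) {
    list(status = "heterotypic", label = NA_character_)
  } else if (length(coloured) == 1) {
    list(status = "homotypic", label = coloured)
  } else {
    list(status = "uncoloured", label = NA_character_)
  }
}

#' Heterotypic fraction among coloured tumours
#'
#' The fraction of heterotypic tumours among tumours expressing any Confetti
#' colour; uncoloured tumours are excluded from the denominator, matching how
#' the 60/40 homotypic/heterotypic split is quantified.
#'
#' @param statuses character vector of statuses (`"homotypic"`,
#'   `"heterotypic"`, `"uncoloured"`), or a list of results from
#'   [score_confetti_status()].
#' @return Numeric fraction in \[0, 1\]; `NA` (with a warning) when there are
#'   no coloured tumours.
#' @examples
#' heterotypic_fraction(c(rep("homotypic", 6), rep("heterotypic", 4)))
#' @export
heterotypic_fraction <- function(statuses) {
  if (is.list(statuses)) {
    statuses <- vapply(statuses, function(s) s$status, character(1))
  }
  bad <- setdiff(unique(statuses),
                 c("homotypic", "heterotypic", "uncoloured"))
  abort_if(length(bad) > 0,
           "unknown status value(s): ", paste(bad, collapse = ", "))
  het <- sum(statuses == "heterotypic")
  hom <- sum(statuses == "homotypic")
  if (het + hom == 0) {
    warning("no coloured tumours: heterotypic fraction is undefined",
            call. = FALSE)
    return(NA_real_)
  }
  het / (het + hom)
}
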