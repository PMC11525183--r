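#' Apc protein-domain bins
#'
#' Default codon bins over the mouse Apc protein (2,842 aa), half-open
#' `[start, end)` on 1-based codons: Pre-Armadillo, Armadillo repeats, the
#' inter-domain region, the 15-aa repeats, the 20-aa repeats containing the
#' mutation cluster region (MCR), and the C-terminus including the EB1-binding
#' region. Boundaries follow the standard APC domain literature and are
#' overridable via [domain_bins()].
#'
#' @return data.frame of class `domain_bins` with columns `name`, `start`,
#'   `end` and attribute `protein_length`.
#' @examples
#' apc_domain_bins()
#' @export
apc_domain_bins <- function() {
  domain_bins(data.frame(
    name = c("Pre-Armadillo", "Armadillo", "Inter-domain", "15aa-repeats",
             "MCR", "C-terminal"),
    start = c(1L, 453L, 767L, 1020L, 1170L, 1530L),
    end = c(453L, 767L, 1020L, 1170L, 1530L, 2843L),
    stringsAsFactors = FALSE), protein_length = 2842L)
}

#' Construct and validate a domain bin set
#'
#' @param bins data.frame with columns `name`, `start`, `end`; intervals are
#'   1-based, half-open `[start, end)`, must be sorted and non-overlapping and
#'   lie within the protein.
#' @param protein_length protein length in amino acids.
#' @return Validated data.frame of class `domain_bins`.
#' @export
domain_bins <- function(bins, protein_length) {
  need_cols(bins, c("name", "start", "end"), "bin table")
  abort_if(nrow(bins) == 0, "at least one bin is required")
  abort_if(anyDuplicated(bins$name) > 0, "bin names must be unique")
  abort_if(any(bins$start >= bins$end), "bins must satisfy start < end")
  abort_if(is.unsorted(bins$start, strictly = TRUE),
           "bins must be sorted by start")
  abort_if(any(bins$end[-nrow(bins)] > bins$start[-1]),
           "bins must not overlap")
  abort_if(bins$start[1] < 1 || bins$end[nrow(bins)] > protein_length + 1,
           "bins must lie within [1, protein_length]")
  structure(bins, protein_length = as.integer(protein_length),
            class = c("domain_bins", "data.frame"))
}

#' Assign codons to domain bins
#'
#' @param codon integer vector of 1-based protein codons.
#' @param bins a [domain_bins()] set.
#' @return character vector of bin names; `"unbinned"` for codons covered by
#'   no bin. Codons outside `[1, protein_length]` are an error.
#' @examples
#' assign_domain_bin(c(452, 453, 1300))
#' @export
assign_domain_bin <- function(codon, bins = apc_domain_bins()) {
  abort_if(!inherits(bins, "domain_bins"), "bins must come from domain_bins()")
  len <- attr(bins, "protein_length")
  abort_if(any(!is.finite(codon)) || any(codon < 1) || any(codon > len) ||
             any(codon != floor(codon)),
           "codons must be integers in [1, ", len, "]")
  idx <- findInterval(codon, bins$start)
  out <- rep("unbinned", length(codon))
  hit <- idx >= 1
  hit[hit] <- codon[hit] < bins$end[idx[hit]]
  out[hit] <- bins$name[idx[hit]]
  out
}

bin_columns <- function(samples) {
  setdiff(names(samples), c("sample_id", "group", "pair_id"))
}

#' Per-bin mutation probability by group
#'
#' The probability of mutation in each bin is the mean of the per-sample
#' binary indicator (at least one inactivating mutation in the bin) within
#' each group.
#'
#' @param samples data.frame with a `group` column and one 0/1 indicator
#'   column per bin (as produced by [gen_domain_mutation_cohort()] or
#'   [group_samples()]).
#' @return data.frame with columns `group`, `bin`, `probability`, `n`.
#' @export
bin_probabilities <- function(samples) {
  need_cols(samples, "group", "sample table")
  abort_if(nrow(samples) == 0, "no samples: probabilities are undefined")
  bins <- bin_columns(samples)
  abort_if(length(bins) == 0, "no bin indicator columns found")
  out <- do.call(rbind, lapply(split(samples, samples$group), function(g) {
    data.frame(group = g$group[1], bin = bins,
               probability = colMeans(as.matrix(g[bins])),
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Stratified bootstrap CIs for per-bin probability differences
#'
#' Percentile confidence intervals for the difference in per-bin mutation
#' probabilities between two tumour groups, via a stratified non-parametric
#' bootstrap: in independent mode each group is resampled with replacement
#' within its own stratum; in paired mode (major versus minor clones of the
#' same tumours) whole tumour pairs are resampled, preserving the dependence.
#'
#' @param group_a,group_b data.frames of per-sample 0/1 bin indicators
#'   (columns other than `sample_id`, `group`, `pair_id` are taken as bins);
#'   the difference reported is `P(A) - P(B)`.
#' @param paired resample tumour pairs matched on `pair_id`.
#' @param B number of bootstrap resamples (>= 100).
#' @param level confidence level in (0, 1).
#' @param seed optional integer seed; the resampling is deterministic given
#'   it.
#' @return data.frame with one row per bin: `bin`, `point` (observed
#'   difference), `lower`, `upper`, `level`, `B`, `significant` (interval
#'   excludes 0).
#' @examples
#' cohort <- gen_domain_mutation_cohort(n_per_group = 40, seed = 1)
#' a <- cohort[cohort$group == "monoclonal", ]
#' b <- cohort[cohort$group == "minor", ]
#' bootstrap_diff_ci(a, b, B = 200, seed = 2)
#' @export
bootstrap_diff_ci <- function(group_a, group_b, paired = FALSE, B = 10000,
                              level = 0.95, seed = NULL) {
  abort_if(!is_count(B) || B < 100, "B must be a count >= 100")
  abort_if(!is.numeric(level) || level <= 0 || level >= 1,
           "level must be in (0, 1)")
  bins <- intersect(bin_columns(group_a), bin_columns(group_b))
  abort_if(length(bins) == 0, "no shared bin columns")
  abort_if(nrow(group_a) == 0 || nrow(group_b) == 0,
           "both groups must be non-empty")
  A <- as.matrix(group_a[bins])
  Bm <- as.matrix(group_b[bins])
  if (paired) {
    abort_if(!"pair_id" %in% names(group_a) || !"pair_id" %in% names(group_b),
             "paired mode requires pair_id columns")
    abort_if(anyNA(group_a$pair_id) || anyNA(group_b$pair_id),
             "paired mode requires complete pair_id values")
    m <- match(group_a$pair_id, group_b$pair_id)
    abort_if(anyNA(m) || nrow(group_a) != nrow(group_b),
             "pair_ids of the two groups do not match one-to-one")
    Bm <- Bm[m, , drop = FALSE]
  }
  point <- colMeans(A) - colMeans(Bm)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  boot <- with_seed(seed, {
    if (paired) {
      n <- nrow(A)
      idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
      D <- A - Bm
      vapply(bins, function(k) {
        rowMeans(matrix(D[, k][idx], nrow = B))
      }, numeric(B))
    } else {
      na <- nrow(A); nb <- nrow(Bm)
      idx_a <- matrix(sample.int(na, na * B, replace = TRUE), nrow = B)
      idx_b <- matrix(sample.int(nb, nb * B, replace = TRUE), nrow = B)
      vapply(bins, function(k) {
        rowMeans(matrix(A[, k][idx_a], nrow = B)) -
          rowMeans(matrix(Bm[, k][idx_b], nrow = B))
      }, numeric(B))
    }
  })
  ci <- apply(boot, 2, stats::quantile, probs = probs, names = FALSE)
  out <- data.frame(bin = bins, point = unname(point),
                    lower = ci[1, ], upper = ci[2, ],
                    level = level, B = B,
                    significant = ci[1, ] > 0 | ci[2, ] < 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build domain-bin group samples from clonality calls
#'
#' Converts a cohort clonality result into the per-sample bin indicators used
#' by [bin_probabilities()] and [bootstrap_diff_ci()]: monoclonal tumours form
#' the `monoclonal` group; each polyclonal tumour contributes its
#' highest-VAF clone to the `major` group and its second-ranked clone to the
#' `minor` group, linked by a shared `pair_id`.
#'
#' @param cohort result of [classify_cohort()].
#' @param bins a [domain_bins()] set.
#' @return data.frame with `sample_id`, `group`, `pair_id` and one indicator
#'   column per bin.
#' @export
group_samples <- function(cohort, bins = apc_domain_bins()) {
  abort_if(!is.list(cohort) || is.null(cohort$samples) ||
             is.null(cohort$clones), "cohort must come from classify_cohort()")
  bin_names <- bins$name
  indicator <- function(codons) {
    hit <- assign_domain_bin(codons, bins)
    as.integer(bin_names %in% hit)
  }
  rows <- list()
  for (i in seq_len(nrow(cohort$samples))) {
    s <- cohort$samples[i, ]
    cl <- cohort$clones[cohort$clones$sample_id == s$sample_id, , drop = FALSE]
    if (s$class == "monoclonal") {
      rows[[length(rows) + 1L]] <- c(
        list(sample_id = s$sample_id, group = "monoclonal",
             pair_id = NA_character_),
        stats::setNames(as.list(indicator(cl$codon)), bin_names))
    } else if (s$class == "polyclonal") {
      cl <- cl[order(-cl$vaf, cl$codon), , drop = FALSE]
      pid <- s$sample_id
      rows[[length(rows) + 1L]] <- c(
        list(sample_id = paste0(s$sample_id, "_major"), group = "major",
             pair_id = pid),
        stats::setNames(as.list(indicator(cl$codon[1])), bin_names))
      rows[[length(rows) + 1L]] <- c(
        list(sample_id = paste0(s$sample_id, "_minor"), group = "minor",
             pair_id = pid),
        stats::setNames(as.list(indicator(cl$codon[2])), bin_names))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), group = character(0),
                      pair_id = character(0), stringsAsFactors = FALSE)
    for (b in bin_names) out[[b]] <- integer(0)
  }
  rownames(out) <- NULL
  out
}
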