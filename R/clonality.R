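#' Amplicon variant filter parameters
#'
#' The filtering rules applied to amplicon variant calls before clonality
#' assessment: a minimum allele fraction of 0.01, support by at least five
#' mutant reads, calls in at least two amplicons per sample, and removal of
#' indels (ENU overwhelmingly induces single-nucleotide variants). Apc codons
#' 73-84 and 122-139 are covered by a single amplicon; calls there cannot meet
#' the two-amplicon rule and are routed to a review list instead of being
#' discarded, provided they have at least `min_alt_reads` mutant reads and a
#' VAF strictly above `min_vaf`.
#'
#' @param min_vaf minimum variant allele fraction.
#' @param min_alt_reads minimum supporting mutant reads.
#' @param min_amplicons minimum number of amplicons in which the variant is
#'   called.
#' @param drop_indels remove indels entirely.
#' @param single_amplicon_windows list of inclusive codon intervals of Apc
#'   covered by only one amplicon.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_vaf = 0.01, min_alt_reads = 5,
                          min_amplicons = 2, drop_indels = TRUE,
                          single_amplicon_windows = list(c(73L, 84L),
                                                         c(122L, 139L))) {
  abort_if(min_vaf < 0 || min_alt_reads < 0 || min_amplicons < 0,
           "thresholds must be >= 0")
  structure(list(min_vaf = min_vaf,
                 min_alt_reads = min_alt_reads,
                 min_amplicons = min_amplicons,
                 drop_indels = isTRUE(drop_indels),
                 single_amplicon_windows = single_amplicon_windows),
            class = "filter_params")
}

validate_variant_calls <- function(calls) {
  need_cols(calls, c("sample_id", "gene", "codon", "consequence", "vaf",
                     "depth", "alt_reads", "n_amplicons"), "variant table")
  abort_if(any(calls$vaf < 0 | calls$vaf > 1, na.rm = TRUE),
           "vaf must lie in [0, 1]")
  abort_if(any(calls$alt_reads > calls$depth, na.rm = TRUE),
           "alt_reads cannot exceed depth")
  abort_if(any(calls$n_amplicons < 1, na.rm = TRUE),
           "n_amplicons must be >= 1")
  invisible(calls)
}

#' Filter amplicon variant calls
#'
#' Applies the thresholds of [filter_params()]. Calls inside the
#' single-amplicon Apc windows that fail only the amplicon-count rule, but
#' have at least `min_alt_reads` mutant reads and VAF strictly above
#' `min_vaf`, are returned as `review_flagged` (the manual-inspection route)
#' rather than discarded; `accept_flagged = TRUE` additionally retains them.
#'
#' @param calls variant table (see [read_variant_table()] for the dialect).
#' @param params a [filter_params()].
#' @param accept_flagged also place review-flagged calls in the retained set.
#' @return list with data.frames `retained` and `review_flagged`.
#' @examples
#' calls <- data.frame(sample_id = "T1", gene = "Apc", codon = 1300,
#'                     consequence = "stop_gained", vaf = 0.2, depth = 500,
#'                     alt_reads = 100, n_amplicons = 2)
#' filter_amplicon_variants(calls)
#' @export
filter_amplicon_variants <- function(calls, params = filter_params(),
                                     accept_flagged = FALSE) {
  abort_if(!inherits(params, "filter_params"),
           "params must come from filter_params()")
  if (nrow(calls) == 0) {
    return(list(retained = calls, review_flagged = calls))
  }
  validate_variant_calls(calls)
  keep <- rep(TRUE, nrow(calls))
  if (params$drop_indels) keep <- keep & calls$consequence != "indel"
  pass_basic <- keep &
    calls$vaf >= params$min_vaf &
    calls$alt_reads >= params$min_alt_reads
  pass_amp <- calls$n_amplicons >= params$min_amplicons
  in_window <- in_single_amplicon_window(calls$gene, calls$codon,
                                         params$single_amplicon_windows)
  retained <- pass_basic & pass_amp
  flagged <- pass_basic & !pass_amp & in_window &
    calls$alt_reads >= params$min_alt_reads & calls$vaf > params$min_vaf
  out_ret <- calls[retained, , drop = FALSE]
  out_flag <- calls[flagged, , drop = FALSE]
  if (accept_flagged) out_ret <- rbind(out_ret, out_flag)
  rownames(out_ret) <- rownames(out_flag) <- NULL
  list(retained = out_ret, review_flagged = out_flag)
}

#' Filter long-read (haplotype-phasing) variant calls
#'
#' Retains nonsense (stop-gained) calls with VAF at least 0.02 and read depth
#' at least 100 -- the thresholds at which technical duplicates reproduce
#' mutation calls in long-read transcript phasing.
#'
#' @param calls variant table with `consequence`, `vaf`, `depth`.
#' @param min_vaf minimum VAF.
#' @param min_depth minimum read depth.
#' @return The retained subset of `calls`.
#' @export
filter_longread_variants <- function(calls, min_vaf = 0.02, min_depth = 100) {
  need_cols(calls, c("consequence", "vaf", "depth"), "variant table")
  out <- calls[calls$consequence == "stop_gained" &
                 calls$vaf >= min_vaf &
                 calls$depth >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify one tumour as monoclonal or polyclonal
#'
#' Counts inactivating (nonsense-only) Apc mutations among the sample's
#' filtered calls: one such mutation means monoclonal, two or more mean
#' polyclonal, none means no driver detected. Clones are ranked by descending
#' VAF (ties broken by codon); every clone whose VAF is within `tie_delta` of
#' the maximum is a (co-)major clone and `tie_flag` is set when there is more
#' than one. The purity estimate is `min(1, 2 * summed VAF)`: clone fractions
#' sum to one, so under the heterozygous-mutation convention the summed VAF
#' equals half the tumour-cell fraction.
#'
#' @param calls filtered variant calls for a single sample.
#' @param gene driver gene symbol.
#' @param inactivating consequences counted as inactivating.
#' @param tie_delta VAF difference below which clones are co-major.
#' @return list of class `clonality_call`: `sample_id`, `class`
#'   (`"monoclonal"`, `"polyclonal"` or `"no_driver"`),
#'   `n_inactivating_apc`, `summed_vaf`, `purity_estimate`, `clones`
#'   (data.frame `rank`, `gene`, `codon`, `aa_change`, `vaf`), `tie_flag`.
#' @examples
#' calls <- data.frame(sample_id = "T1", gene = "Apc", codon = c(700, 1450),
#'                     aa_change = NA, consequence = "stop_gained",
#'                     vaf = c(0.30, 0.12), depth = 500,
#'                     alt_reads = c(150, 60), n_amplicons = 2)
#' classify_clonality(calls)
#' @export
classify_clonality <- function(calls, gene = "Apc",
                               inactivating = "stop_gained",
                               tie_delta = 0.02) {
  sample_id <- unique(calls$sample_id)
  abort_if(length(sample_id) > 1,
           "classify_clonality expects calls from a single sample")
  if (length(sample_id) == 0) sample_id <- NA_character_
  drv <- calls[calls$gene == gene & calls$consequence %in% inactivating, ,
               drop = FALSE]
  n <- nrow(drv)
  cls <- if (n == 0) "no_driver" else if (n == 1) "monoclonal" else
    "polyclonal"
  if (n > 0) {
    ord <- order(-drv$vaf, drv$codon)
    drv <- drv[ord, , drop = FALSE]
    rank <- ifelse(max(drv$vaf) - drv$vaf < tie_delta, "major", "minor")
    if (!"aa_change" %in% names(drv)) drv$aa_change <- NA_character_
    clones <- data.frame(rank = rank, gene = drv$gene, codon = drv$codon,
                         aa_change = drv$aa_change, vaf = drv$vaf,
                         stringsAsFactors = FALSE)
    tie_flag <- sum(rank == "major") > 1
    summed <- sum(drv$vaf)
    purity <- min(1, 2 * summed)
  } else {
    clones <- data.frame(rank = character(0), gene = character(0),
                         codon = integer(0), aa_change = character(0),
                         vaf = numeric(0), stringsAsFactors = FALSE)
    tie_flag <- FALSE
    summed <- 0
    purity <- NA_real_
  }
  structure(list(sample_id = sample_id, class = cls,
                 n_inactivating_apc = n, summed_vaf = summed,
                 purity_estimate = purity, clones = clones,
                 tie_flag = tie_flag),
            class = "clonality_call")
}

#' @export
print.clonality_call <- function(x, ...) {
  cat(sprintf("Sample %s: %s (%d inactivating mutation(s), summed VAF %.3f)\n",
              x$sample_id, x$class, x$n_inactivating_apc, x$summed_vaf))
  if (nrow(x$clones) > 0) print(x$clones, row.names = FALSE)
  invisible(x)
}

#' Classify every sample of a cohort
#'
#' Applies [classify_clonality()] per sample and collects the results.
#'
#' @param calls filtered variant table for many samples.
#' @param ... passed to [classify_clonality()].
#' @return list with `samples` (one row per sample: `sample_id`, `class`,
#'   `n_inactivating_apc`, `summed_vaf`, `purity_estimate`, `tie_flag`) and
#'   `clones` (ranked clone table across samples).
#' @export
classify_cohort <- function(calls, ...) {
  validate_variant_calls(calls)
  by_sample <- split(calls, calls$sample_id)
  res <- lapply(by_sample, classify_clonality, ...)
  samples <- do.call(rbind, lapply(res, function(r) {
    data.frame(sample_id = r$sample_id, class = r$class,
               n_inactivating_apc = r$n_inactivating_apc,
               summed_vaf = r$summed_vaf,
               purity_estimate = r$purity_estimate,
               tie_flag = r$tie_flag, stringsAsFactors = FALSE)
  }))
  clones <- do.call(rbind, lapply(res, function(r) {
    if (nrow(r$clones) == 0) return(NULL)
    cbind(data.frame(sample_id = r$sample_id, stringsAsFactors = FALSE),
          r$clones)
  }))
  if (is.null(clones)) {
    clones <- data.frame(sample_id = character(0), rank = character(0),
                         gene = character(0), codon = integer(0),
                         aa_change = character(0), vaf = numeric(0),
                         stringsAsFactors = FALSE)
  }
  rownames(samples) <- rownames(clones) <- NULL
  list(samples = samples, clones = clones)
}

#' Tumour purity from variant allele fractions
#'
#' Two conventions for heterozygous clonal driver mutations: `"sum"` returns
#' the summed VAF (the quantity whose distribution is compared across
#' Confetti categories), and `"two_times_mean"` returns twice the mean VAF
#' clamped to \[0, 1\] (the whole-genome cellularity convention).
#'
#' @param vafs numeric VAFs of the driver mutations in one sample.
#' @param mode `"two_times_mean"` or `"sum"`.
#' @return A purity/tumour-fraction estimate.
#' @examples
#' purity_from_vafs(0.5)                     # 1.0
#' purity_from_vafs(c(0.3, 0.1), mode = "sum")  # 0.4
#' @export
purity_from_vafs <- function(vafs, mode = c("two_times_mean", "sum")) {
  mode <- match.arg(mode)
  vafs <- vafs[!is.na(vafs)]
  abort_if(length(vafs) == 0, "purity is undefined without any VAF")
  abort_if(!is_prob(vafs), "VAFs must lie in [0, 1]")
  switch(mode,
         two_times_mean = min(1, 2 * mean(vafs)),
         sum = sum(vafs))
}
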