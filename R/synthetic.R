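#' Configuration for a synthetic tumour cohort
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults emulate
#' the Apc-het + ENU study conditions: Confetti labelling at the observed
#' per-colour frequencies, a high sporadic tumour burden along multiple
#' intestinal segments per mouse, a substantial polyclonal fraction with 2-9
#' founders per polyclonal tumour, amplicon sequencing at depth ~500x with a
#' small per-base error rate, and tumour purities well below 1 (bulk-dissected
#' material carries stroma).
#'
#' @param n_mice number of mice.
#' @param segments_per_mouse imaged bowel segments per mouse.
#' @param segment_length_mm,segment_width_mm segment dimensions (mm).
#' @param tumour_intensity expected tumours per mm^2 (homogeneous spatial
#'   Poisson process per segment).
#' @param label_freqs per-colour crypt labelling probabilities,
#'   see [confetti_freqs()].
#' @param polyclonal_fraction probability that a tumour has >= 2 founders.
#' @param founder_geom_p success parameter of the truncated geometric
#'   distribution of founder counts among polyclonal tumours
#'   (support `2..max_founders`).
#' @param max_founders upper bound on founders per tumour (observed range of
#'   Apc mutation multiplicity is 2-9).
#' @param clone_conc symmetric Dirichlet concentration for founder clone
#'   fractions; values > 1 favour clones of comparable size.
#' @param growth_rate_law distribution of per-day exponential growth rates:
#'   either `list(type = "lognormal", meanlog =, sdlog =)` or
#'   `list(type = "empirical", rates = <vector>)`.
#' @param r0_mm initial tumour radius (mm) at initiation.
#' @param collection_day inclusive day range from which each mouse's
#'   collection day is drawn.
#' @param seq_depth amplicon sequencing depth (reads).
#' @param seq_error per-base sequencing/calling error probability.
#' @param purity_range interval of tumour purities, uniform draw per tumour.
#' @param panel_genes genes on the targeted amplicon panel.
#' @param panel_codons effective number of panel codons at which background
#'   error calls can arise.
#' @param apc_bins domain bins used to place founder Apc codons,
#'   see [apc_domain_bins()].
#' @param apc_bin_probs per-bin probabilities for founder Apc codon placement.
#' @param rng_seed integer seed; all generator stages derive deterministic
#'   substreams from it.
#' @return A validated list of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_mice = 2, rng_seed = 1)
#' @export
cohort_config <- function(n_mice = 5,
                          segments_per_mouse = 7,
                          segment_length_mm = 60,
                          segment_width_mm = 10,
                          tumour_intensity = 0.03,
                          label_freqs = confetti_freqs(),
                          polyclonal_fraction = 0.4,
                          founder_geom_p = 0.5,
                          max_founders = 9,
                          clone_conc = 5,
                          growth_rate_law = list(type = "lognormal",
                                                 meanlog = log(0.04),
                                                 sdlog = 0.4),
                          r0_mm = 0.05,
                          collection_day = c(80, 120),
                          seq_depth = 500,
                          seq_error = 1e-3,
                          purity_range = c(0.4, 0.9),
                          panel_genes = c("Apc", "Ctnnb1", "Kras", "Nras",
                                          "Hras", "Braf", "Pten", "Fbxw7",
                                          "Smad4", "Trp53"),
                          panel_codons = 3000,
                          apc_bins = apc_domain_bins(),
                          apc_bin_probs = NULL,
                          rng_seed = 1L) {
  abort_if(!is_count(n_mice) || n_mice < 1, "n_mice must be a positive count")
  abort_if(!is_count(segments_per_mouse) || segments_per_mouse < 1,
           "segments_per_mouse must be a positive count")
  abort_if(!is.numeric(segment_length_mm) || !is.numeric(segment_width_mm),
           "segment dimensions must be numeric")
  abort_if(!is.numeric(tumour_intensity) || tumour_intensity < 0,
           "tumour_intensity must be >= 0")
  validate_label_freqs(label_freqs)
  abort_if(!is_prob(polyclonal_fraction),
           "polyclonal_fraction must be a probability")
  abort_if(!is_prob(founder_geom_p) || founder_geom_p <= 0,
           "founder_geom_p must be in (0, 1]")
  abort_if(!is_count(max_founders) || max_founders < 2,
           "max_founders must be >= 2")
  abort_if(!is.numeric(clone_conc) || clone_conc <= 0,
           "clone_conc must be positive")
  abort_if(!is.list(growth_rate_law) || is.null(growth_rate_law$type),
           "growth_rate_law must be a list with a 'type' field")
  abort_if(!growth_rate_law$type %in% c("lognormal", "empirical"),
           "growth_rate_law$type must be 'lognormal' or 'empirical'")
  if (growth_rate_law$type == "empirical") {
    abort_if(length(growth_rate_law$rates) == 0 ||
               !all(is.finite(growth_rate_law$rates)),
             "empirical growth_rate_law needs a finite, non-empty rates vector")
  }
  abort_if(!is.numeric(r0_mm) || r0_mm <= 0, "r0_mm must be positive")
  abort_if(length(collection_day) != 2 || any(collection_day < 0) ||
             collection_day[1] > collection_day[2],
           "collection_day must be an increasing day interval")
  abort_if(!is_count(seq_depth) || seq_depth < 1, "seq_depth must be >= 1")
  abort_if(!is_prob(seq_error), "seq_error must be a probability")
  abort_if(length(purity_range) != 2 || !is_prob(purity_range) ||
             purity_range[1] > purity_range[2],
           "purity_range must be an increasing interval in [0, 1]")
  if (is.null(apc_bin_probs)) {
    apc_bin_probs <- default_bin_probs()[["monoclonal"]]
  }
  abort_if(is.null(names(apc_bin_probs)) ||
             !setequal(names(apc_bin_probs), apc_bins$name),
           "apc_bin_probs must be named by the bins in apc_bins")
  abort_if(abs(sum(apc_bin_probs) - 1) > 1e-8,
           "apc_bin_probs must sum to 1")
  abort_if(!is.numeric(rng_seed) || length(rng_seed) != 1,
           "rng_seed must be a single integer")
  structure(list(n_mice = as.integer(n_mice),
                 segments_per_mouse = as.integer(segments_per_mouse),
                 segment_length_mm = segment_length_mm,
                 segment_width_mm = segment_width_mm,
                 tumour_intensity = tumour_intensity,
                 label_freqs = label_freqs,
                 polyclonal_fraction = polyclonal_fraction,
                 founder_geom_p = founder_geom_p,
                 max_founders = as.integer(max_founders),
                 clone_conc = clone_conc,
                 growth_rate_law = growth_rate_law,
                 r0_mm = r0_mm,
                 collection_day = collection_day,
                 seq_depth = as.integer(seq_depth),
                 seq_error = seq_error,
                 purity_range = purity_range,
                 panel_genes = panel_genes,
                 panel_codons = as.integer(panel_codons),
                 apc_bins = apc_bins,
                 apc_bin_probs = apc_bin_probs[apc_bins$name],
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_config")
}

draw_growth_rates <- function(law, n) {
  switch(law$type,
         lognormal = stats::rlnorm(n, law$meanlog, law$sdlog),
         empirical = sample(law$rates, n, replace = TRUE))
}

# Truncated geometric founder counts on 2..max_founders.
draw_founder_counts <- function(n, p, max_founders) {
  k <- 0:(max_founders - 2L)
  w <- stats::dgeom(k, p)
  2L + sample(k, n, replace = TRUE, prob = w / sum(w))
}

#' Generate a synthetic tumour field with ground truth
#'
#' Places tumours by a homogeneous spatial Poisson process in each bowel
#' segment, assigns each tumour one founder (monoclonal) or several
#' (polyclonal, truncated-geometric count on 2..`max_founders`), gives every
#' founder an independent Confetti label draw, a clone fraction (symmetric
#' Dirichlet) and an Apc nonsense codon, and scores each tumour's Confetti
#' status by the microscopy rule on its founder labels.
#'
#' @param config a [cohort_config()].
#' @return list with elements
#'   \describe{
#'     \item{tumours}{data.frame: `tumour_id`, `mouse_id`, `segment_id`,
#'       `x_mm`, `y_mm`, `diameter_mm`, `confetti_status`, `day`.}
#'     \item{truth}{immutable ground truth: `tumours` (true clonality class,
#'       purity, day), `founders` (per-founder label, clone fraction, Apc
#'       codon, growth rate), and the generating `apc_bin_probs`.}
#'   }
#' @examples
#' field <- gen_tumour_field(cohort_config(n_mice = 1, rng_seed = 7))
#' head(field$tumours)
#' @export
gen_tumour_field <- function(config) {
  abort_if(!inherits(config, "cohort_config"),
           "config must come from cohort_config()")
  area <- config$segment_length_mm * config$segment_width_mm
  abort_if(!is.finite(area) || area <= 0, "segments must have positive area")
  alphabet <- c(names(config$label_freqs), "none")
  p_label <- c(config$label_freqs, none = 1 - sum(config$label_freqs))
  bins <- config$apc_bins
  with_seed(stage_seed(config$rng_seed, "field"), {
    days <- sample(seq(config$collection_day[1], config$collection_day[2]),
                   config$n_mice, replace = TRUE)
    tum_rows <- list(); founder_rows <- list(); tid <- 0L
    for (m in seq_len(config$n_mice)) {
      for (s in seq_len(config$segments_per_mouse)) {
        n_t <- stats::rpois(1, config$tumour_intensity * area)
        if (n_t == 0) next
        xs <- stats::runif(n_t, 0, config$segment_length_mm)
        ys <- stats::runif(n_t, 0, config$segment_width_mm)
        poly <- stats::runif(n_t) < config$polyclonal_fraction
        k <- ifelse(poly,
                    draw_founder_counts(n_t, config$founder_geom_p,
                                        config$max_founders),
                    1L)
        rates <- draw_growth_rates(config$growth_rate_law, n_t)
        purity <- stats::runif(n_t, config$purity_range[1],
                               config$purity_range[2])
        for (i in seq_len(n_t)) {
          tid <- tid + 1L
          id <- sprintf("T%04d", tid)
          labels <- sample(alphabet, k[i], replace = TRUE, prob = p_label)
          fracs <- as.vector(rdirichlet(1, rep(config$clone_conc, k[i])))
          bin_idx <- sample(seq_len(nrow(bins)), k[i], replace = TRUE,
                            prob = config$apc_bin_probs)
          codons <- bins$start[bin_idx] +
            floor(stats::runif(k[i]) * (bins$end[bin_idx] - bins$start[bin_idx]))
          status <- status_from_labels(labels)$status
          day <- days[m]
          tum_rows[[tid]] <- data.frame(
            tumour_id = id,
            mouse_id = sprintf("M%02d", m),
            segment_id = sprintf("M%02d_S%d", m, s),
            x_mm = xs[i], y_mm = ys[i],
            diameter_mm = 2 * config$r0_mm * exp(rates[i] * day),
            confetti_status = status,
            day = day,
            class = if (k[i] > 1) "polyclonal" else "monoclonal",
            purity = purity[i],
            stringsAsFactors = FALSE)
          founder_rows[[tid]] <- data.frame(
            tumour_id = id,
            founder = seq_len(k[i]),
            label = labels,
            fraction = fracs,
            codon = as.integer(codons),
            growth_rate = rates[i],
            stringsAsFactors = FALSE)
        }
      }
    }
    if (tid == 0) {
      tumours <- data.frame(tumour_id = character(0), mouse_id = character(0),
                            segment_id = character(0), x_mm = numeric(0),
                            y_mm = numeric(0), diameter_mm = numeric(0),
                            confetti_status = character(0), day = integer(0),
                            stringsAsFactors = FALSE)
      founders <- data.frame(tumour_id = character(0), founder = integer(0),
                             label = character(0), fraction = numeric(0),
                             codon = integer(0), growth_rate = numeric(0),
                             stringsAsFactors = FALSE)
      truth_tum <- data.frame(tumour_id = character(0), class = character(0),
                              purity = numeric(0), day = integer(0),
                              stringsAsFactors = FALSE)
    } else {
      all_rows <- do.call(rbind, tum_rows)
      tumours <- all_rows[c("tumour_id", "mouse_id", "segment_id", "x_mm",
                            "y_mm", "diameter_mm", "confetti_status", "day")]
      truth_tum <- all_rows[c("tumour_id", "class", "purity", "day")]
      founders <- do.call(rbind, founder_rows)
      rownames(tumours) <- rownames(truth_tum) <- rownames(founders) <- NULL
    }
    truth <- list(tumours = truth_tum, founders = founders,
                  apc_bin_probs = config$apc_bin_probs)
    class(truth) <- "cohort_truth"
    list(tumours = tumours, truth = truth)
  })
}

# Single-amplicon codon windows of the Apc panel (1-based, inclusive).
.single_amplicon_windows <- list(c(73L, 84L), c(122L, 139L))

in_single_amplicon_window <- function(gene, codon,
                                      windows = .single_amplicon_windows) {
  hit <- rep(FALSE, length(codon))
  for (w in windows) hit <- hit | (codon >= w[1] & codon <= w[2])
  hit & gene == "Apc"
}

#' Generate an amplicon variant table from cohort ground truth
#'
#' For each founder clone with clone fraction `f` in a tumour of purity `rho`,
#' the true variant allele fraction of its heterozygous Apc nonsense mutation
#' is `f * rho / 2`; observed alt reads are Binomial(depth, true VAF). Driver
#' variants falling in the single-amplicon codon windows (73-84, 122-139) are
#' annotated with `n_amplicons = 1`, all others with 2. Background error calls
#' are added at rate `seq_error` per panel codon, with few supporting reads.
#' Variants with zero observed alt reads are not emitted (a caller would not
#' report them).
#'
#' @param truth ground truth from [gen_tumour_field()].
#' @param config the matching [cohort_config()].
#' @return data.frame of variant calls with columns `sample_id`, `gene`,
#'   `codon`, `aa_change`, `consequence`, `vaf`, `depth`, `alt_reads`,
#'   `n_amplicons`.
#' @export
gen_variant_table <- function(truth, config) {
  abort_if(!inherits(truth, "cohort_truth"),
           "truth must come from gen_tumour_field()")
  abort_if(!inherits(config, "cohort_config"),
           "config must come from cohort_config()")
  abort_if(any(truth$tumours$purity < 0 | truth$tumours$purity > 1),
           "purity outside [0, 1]")
  depth <- config$seq_depth
  with_seed(stage_seed(config$rng_seed, "variants"), {
    f <- truth$founders
    out <- list()
    if (nrow(f) > 0) {
      purity <- truth$tumours$purity[match(f$tumour_id,
                                           truth$tumours$tumour_id)]
      true_vaf <- f$fraction * purity / 2
      alt <- stats::rbinom(nrow(f), depth, true_vaf)
      keep <- alt > 0
      if (any(keep)) {
        out$drivers <- data.frame(
          sample_id = f$tumour_id[keep],
          gene = "Apc",
          codon = f$codon[keep],
          aa_change = sprintf("p.Q%d*", f$codon[keep]),
          consequence = "stop_gained",
          vaf = alt[keep] / depth,
          depth = depth,
          alt_reads = alt[keep],
          n_amplicons = ifelse(
            in_single_amplicon_window("Apc", f$codon[keep]), 1L, 2L),
          stringsAsFactors = FALSE)
      }
    }
    samples <- truth$tumours$tumour_id
    if (config$seq_error > 0 && length(samples) > 0) {
      n_err <- stats::rpois(length(samples),
                            config$seq_error * config$panel_codons)
      tot <- sum(n_err)
      if (tot > 0) {
        sid <- rep(samples, n_err)
        gene <- sample(config$panel_genes, tot, replace = TRUE)
        codon <- ifelse(gene == "Apc",
                        sample.int(2842L, tot, replace = TRUE),
                        sample.int(500L, tot, replace = TRUE))
        csq <- sample(c("missense", "synonymous", "stop_gained"), tot,
                      replace = TRUE, prob = c(0.6, 0.3, 0.1))
        alt <- pmax(1L, stats::rbinom(tot, depth, 3 * config$seq_error))
        out$errors <- data.frame(
          sample_id = sid, gene = gene, codon = as.integer(codon),
          aa_change = NA_character_, consequence = csq,
          vaf = alt / depth, depth = depth, alt_reads = alt,
          n_amplicons = sample(1:2, tot, replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, out)
    if (is.null(calls)) {
      calls <- data.frame(sample_id = character(0), gene = character(0),
                          codon = integer(0), aa_change = character(0),
                          consequence = character(0), vaf = numeric(0),
                          depth = integer(0), alt_reads = integer(0),
                          n_amplicons = integer(0), stringsAsFactors = FALSE)
    }
    calls <- calls[order(calls$sample_id, calls$gene, calls$codon), ]
    rownames(calls) <- NULL
    calls
  })
}

#' Generate longitudinal tumour growth series
#'
#' Log tumour size follows `intercept + rate_g * day + mouse effect + noise`,
#' with per-group exponential rates differing by `rate_ratio`, a Normal(0,
#' `mouse_sd`) random intercept per mouse, and Normal(0, `noise_sd`)
#' measurement noise. Intercepts are set so both groups share the same
#' expected size on the first measured day (the onset of the exponential
#' phase).
#'
#' @param n_per_group tumours per group.
#' @param rate_ratio heterotypic/homotypic growth-rate ratio.
#' @param base_rate homotypic per-day exponential rate.
#' @param mouse_sd SD of the per-mouse random intercept (log scale).
#' @param noise_sd SD of the residual noise (log scale).
#' @param days measurement days post-ENU.
#' @param n_mice number of mice over which tumours are spread.
#' @param size_at_start expected size of both groups at `days[1]`.
#' @param seed optional integer seed.
#' @return data.frame with columns `tumour_id`, `group`, `mouse_id`, `day`,
#'   `size`.
#' @examples
#' g <- gen_growth_series(n_per_group = 5, seed = 1)
#' @export
gen_growth_series <- function(n_per_group = 30, rate_ratio = 4,
                              base_rate = 0.05, mouse_sd = 0.1,
                              noise_sd = 0.2, days = c(40, 47, 55, 63),
                              n_mice = 6, size_at_start = 0.1, seed = NULL) {
  abort_if(!is_count(n_per_group) || n_per_group < 1,
           "n_per_group must be a positive count")
  abort_if(rate_ratio <= 0, "rate_ratio must be positive")
  abort_if(length(days) < 2, "need at least two measurement days")
  with_seed(seed, {
    groups <- c(homotypic = base_rate, heterotypic = base_rate * rate_ratio)
    mouse_eff <- stats::rnorm(n_mice, 0, mouse_sd)
    rows <- list()
    idx <- 0L
    for (g in names(groups)) {
      rate <- groups[[g]]
      intercept <- log(size_at_start) - rate * days[1]
      mouse <- sample.int(n_mice, n_per_group, replace = TRUE)
      for (i in seq_len(n_per_group)) {
        idx <- idx + 1L
        log_size <- intercept + rate * days + mouse_eff[mouse[i]] +
          stats::rnorm(length(days), 0, noise_sd)
        rows[[idx]] <- data.frame(
          tumour_id = sprintf("G%03d", idx),
          group = g,
          mouse_id = sprintf("M%02d", mouse[i]),
          day = days,
          size = exp(log_size),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "true_rates") <- groups
    out
  })
}

#' Default per-bin Apc mutation probabilities by tumour group
#'
#' Generating probabilities for the synthetic domain-mutation cohort: the bulk
#' of truncating mutations falls in the mutation cluster region for all
#' groups, while minor clones carry a clear excess of Pre-Armadillo (N-terminal)
#' truncations relative to monoclonal tumours. These are implementer defaults
#' on the default [apc_domain_bins()].
#'
#' @return named list (`monoclonal`, `major`, `minor`) of probability vectors
#'   over the default bins, each summing to 1.
#' @export
default_bin_probs <- function() {
  bins <- c("Pre-Armadillo", "Armadillo", "Inter-domain", "15aa-repeats",
            "MCR", "C-terminal")
  out <- list(
    monoclonal = c(0.08, 0.12, 0.10, 0.15, 0.45, 0.10),
    major      = c(0.10, 0.12, 0.10, 0.15, 0.43, 0.10),
    minor      = c(0.22, 0.13, 0.10, 0.14, 0.31, 0.10))
  lapply(out, function(p) stats::setNames(p, bins))
}

#' Generate a synthetic domain-mutation cohort
#'
#' Draws, for each sample in each group, the domain bin carrying its
#' inactivating Apc mutation from the group's multinomial distribution, and
#' returns one-hot bin indicators. When both a `major` and a `minor` group of
#' equal size are present, samples are linked by `pair_id` (major and minor
#' clone of the same tumour).
#'
#' @param bin_probs named list of per-group probability vectors over bins
#'   (each summing to 1); see [default_bin_probs()].
#' @param n_per_group samples per group: a single count or a named vector.
#' @param seed optional integer seed.
#' @return data.frame with columns `sample_id`, `group`, `pair_id` and one 0/1
#'   indicator column per bin.
#' @examples
#' cohort <- gen_domain_mutation_cohort(n_per_group = 10, seed = 1)
#' @export
gen_domain_mutation_cohort <- function(bin_probs = default_bin_probs(),
                                       n_per_group = 94, seed = NULL) {
  abort_if(!is.list(bin_probs) || is.null(names(bin_probs)),
           "bin_probs must be a named list of probability vectors")
  bins <- names(bin_probs[[1]])
  for (g in names(bin_probs)) {
    abort_if(!setequal(names(bin_probs[[g]]), bins),
             "all groups must share one bin set")
    abort_if(abs(sum(bin_probs[[g]]) - 1) > 1e-8,
             "bin probabilities must sum to 1 (group ", g, ")")
  }
  if (length(n_per_group) == 1 && is.null(names(n_per_group))) {
    n_per_group <- stats::setNames(rep(n_per_group, length(bin_probs)),
                                   names(bin_probs))
  }
  abort_if(!all(names(bin_probs) %in% names(n_per_group)),
           "n_per_group must cover every group in bin_probs")
  with_seed(seed, {
    rows <- list()
    for (g in names(bin_probs)) {
      n <- n_per_group[[g]]
      if (n == 0) next
      draw <- sample(bins, n, replace = TRUE,
                     prob = bin_probs[[g]][bins])
      ind <- matrix(0L, n, length(bins), dimnames = list(NULL, bins))
      ind[cbind(seq_len(n), match(draw, bins))] <- 1L
      rows[[g]] <- data.frame(
        sample_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g,
        pair_id = NA_character_,
        ind,
        check.names = FALSE,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(sample_id = character(0), group = character(0),
                        pair_id = character(0), stringsAsFactors = FALSE)
      for (b in bins) out[[b]] <- integer(0)
    }
    if (all(c("major", "minor") %in% out$group)) {
      n_major <- sum(out$group == "major")
      n_minor <- sum(out$group == "minor")
      if (n_major == n_minor) {
        out$pair_id[out$group == "major"] <- sprintf("P%03d",
                                                     seq_len(n_major))
        out$pair_id[out$group == "minor"] <- sprintf("P%03d",
                                                     seq_len(n_minor))
      }
    }
    rownames(out) <- NULL
    out
  })
}

#' Generate a synthetic gene-by-sample count matrix
#'
#' Each sample's gene proportions are drawn from a symmetric Dirichlet and its
#' counts from a multinomial at the given depth, so column sums equal `depth`
#' exactly. A fixture generator for pseudo-bulk mixing.
#'
#' @param n_genes number of genes.
#' @param n_samples number of samples (columns).
#' @param depth total counts per sample.
#' @param dirichlet_conc symmetric Dirichlet concentration of the per-sample
#'   gene proportions.
#' @param seed optional integer seed.
#' @return integer matrix `n_genes x n_samples` with dimnames.
#' @examples
#' m <- gen_count_matrix(50, 2, 1e4, seed = 1)
#' colSums(m)
#' @export
gen_count_matrix <- function(n_genes, n_samples = 2, depth = 1e5,
                             dirichlet_conc = 1, seed = NULL) {
  abort_if(!is_count(n_genes) || n_genes < 1, "n_genes must be >= 1")
  abort_if(!is_count(n_samples) || n_samples < 1, "n_samples must be >= 1")
  abort_if(!is_count(depth) || depth < 1, "depth must be >= 1")
  with_seed(seed, {
    m <- vapply(seq_len(n_samples), function(j) {
      p <- as.vector(rdirichlet(1, rep(dirichlet_conc, n_genes)))
      stats::rmultinom(1, depth, p)[, 1]
    }, integer(n_genes))
    m <- matrix(m, nrow = n_genes, ncol = n_samples)
    dimnames(m) <- list(sprintf("gene_%04d", seq_len(n_genes)),
                        sprintf("sample_%02d", seq_len(n_samples)))
    m
  })
}
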