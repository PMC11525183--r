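#' Per-adenoma collision probability (Poisson approximation)
#'
#' For `n` adenomas of width `x` crypts in a one-dimensional arrangement of
#' `y` crypts, the number of inter-adenoma spacings smaller than `x` (i.e.
#' collisions) is approximately binomial with per-spacing probability
#' `P = 1 - exp(-n * x / y)`. The approximation treats spacings as
#' exponential, which holds for large adenoma counts in the sparse regime.
#'
#' @param n adenoma count.
#' @param x adenoma width (crypts).
#' @param y total crypts in the arrangement.
#' @return Collision probability per adenoma.
#' @examples
#' collision_probability(10, 2, 1000)
#' @export
collision_probability <- function(n, x, y) {
  check_geometry(n, x, y)
  1 - exp(-n * x / y)
}

check_geometry <- function(n, x, y) {
  abort_if(!is.numeric(n) || !is.numeric(x) || !is.numeric(y),
           "geometry must be numeric")
  abort_if(n < 0 || n != floor(n), "n must be a non-negative integer")
  abort_if(x < 0, "x must be >= 0")
  abort_if(y <= 0, "y must be positive")
  if (n * x > y) {
    warning("adenomas cannot physically pack: n * x > y", call. = FALSE)
  }
  invisible(NULL)
}

#' Expected collisions and their variance
#'
#' Binomial moments under the Poisson approximation: expected collisions
#' `n * P` and variance `n * P * (1 - P)` with `P` from
#' [collision_probability()].
#'
#' @inheritParams collision_probability
#' @return list with elements `P`, `expected`, `variance`.
#' @examples
#' expected_collisions(10, 2, 1000)
#' @export
expected_collisions <- function(n, x, y) {
  P <- collision_probability(n, x, y)
  list(P = P, expected = n * P, variance = n * P * (1 - P))
}

#' Exact per-spacing collision probability for finite adenoma counts
#'
#' For `n` positions placed uniformly on a circle of `y` crypts, a given
#' spacing is below `x` with probability `1 - (1 - x/y)^(n-1)` exactly. The
#' Poisson approximation [collision_probability()] is its large-`n` limit;
#' this closed form is the oracle against which the placement simulator is
#' validated.
#'
#' @inheritParams collision_probability
#' @return Exact probability that one inter-adenoma spacing is below `x`.
#' @export
exact_spacing_probability <- function(n, x, y) {
  check_geometry(n, x, y)
  if (n < 2) return(0)
  1 - (1 - min(x, y) / y)^(n - 1)
}

#' Brute-force collision simulation on a circle
#'
#' Places `n` adenoma start positions uniformly on a circle of `y` crypts and
#' counts inter-adenoma spacings smaller than `x`, averaged over `reps`
#' replicates. Two equivalent samplers are available: direct placement with
#' sorting (`"placement"`) and the exact Dirichlet-spacing representation via
#' normalised exponentials (`"gaps"`, the default, O(n) per replicate and so
#' usable at the large adenoma counts where the analytic approximation
#' applies). Both sample the identical distribution.
#'
#' @inheritParams collision_probability
#' @param reps number of placement replicates.
#' @param seed optional integer seed.
#' @param method `"gaps"` or `"placement"`.
#' @return list with `mean`, `se` (Monte-Carlo standard error of the mean),
#'   `ci` (95% normal interval), `reps`, and the per-replicate counts in
#'   `counts`.
#' @examples
#' brute_force_collisions(10, 2, 1000, reps = 1000, seed = 1)
#' @export
brute_force_collisions <- function(n, x, y, reps = 1e5, seed = NULL,
                                   method = c("gaps", "placement")) {
  check_geometry(n, x, y)
  method <- match.arg(method)
  abort_if(!is_count(reps) || reps < 1, "reps must be a positive count")
  counts <- with_seed(seed, {
    cpp_spacing_collisions(as.integer(n), x, y, as.integer(reps),
                           if (method == "placement") 0L else 1L)
  })
  m <- mean(counts)
  se <- stats::sd(counts) / sqrt(reps)
  list(mean = m, se = se, ci = m + c(-1.96, 1.96) * se, reps = reps,
       counts = counts)
}

#' Configuration for the growth-based collision simulation
#'
#' @param segment_length_mm,segment_width_mm segment rectangle (mm).
#' @param n_founders fixed founder count per seed, or `NULL` to draw
#'   Poisson(`founder_intensity * area`) per seed.
#' @param founder_intensity founders per mm^2 (used when `n_founders` is
#'   `NULL`).
#' @param label_freqs Confetti label frequencies, see [confetti_freqs()].
#' @param growth_rates vector of per-day exponential growth rates sampled
#'   with replacement (the observed growth-rate distribution).
#' @param r0_mm initial tumour radius (mm).
#' @param endpoint_day simulation horizon (humane endpoint, days).
#' @param n_seeds number of simulation seeds (replicates); 10,000 in the
#'   reference analysis.
#' @param seed optional integer RNG seed.
#' @return Validated list of class `growth_sim_config`.
#' @export
growth_sim_config <- function(segment_length_mm = 60, segment_width_mm = 10,
                              n_founders = NULL, founder_intensity = NULL,
                              label_freqs = confetti_freqs(),
                              growth_rates, r0_mm = 0.05, endpoint_day,
                              n_seeds = 10000, seed = NULL) {
  abort_if(segment_length_mm <= 0 || segment_width_mm <= 0,
           "segment dimensions must be positive")
  abort_if(is.null(n_founders) && is.null(founder_intensity),
           "give n_founders or founder_intensity")
  if (!is.null(n_founders)) {
    abort_if(!is_count(n_founders), "n_founders must be a count")
  }
  validate_label_freqs(label_freqs)
  abort_if(missing(growth_rates) || length(growth_rates) == 0,
           "growth_rates must be a non-empty vector")
  abort_if(!all(is.finite(growth_rates)), "growth rates must be finite")
  abort_if(r0_mm <= 0, "r0_mm must be positive")
  abort_if(missing(endpoint_day) || endpoint_day < 0,
           "endpoint_day must be >= 0")
  abort_if(!is_count(n_seeds) || n_seeds < 1, "n_seeds must be >= 1")
  structure(list(segment_length_mm = segment_length_mm,
                 segment_width_mm = segment_width_mm,
                 n_founders = n_founders,
                 founder_intensity = founder_intensity,
                 label_freqs = label_freqs,
                 growth_rates = growth_rates,
                 r0_mm = r0_mm,
                 endpoint_day = endpoint_day,
                 n_seeds = as.integer(n_seeds),
                 seed = seed),
            class = "growth_sim_config")
}

#' Growth-based Monte-Carlo collision simulation
#'
#' Per seed: founder points are placed uniformly in the segment rectangle,
#' each carrying a Confetti label (or none) and a growth rate sampled with
#' replacement from the observed rates; each grows as a disc of radius
#' `r0 * exp(rate * t)` until the endpoint day; overlapping discs are merged
#' transitively into clusters; each cluster is scored by the microscopy rule
#' applied to its founder labels. Clusters of two or more founders are
#' collisions; those scoring heterotypic are the collisions a microscopist
#' would actually see (uncoloured-uncoloured collisions are invisible).
#'
#' @param config a [growth_sim_config()].
#' @return list with `per_seed` (data.frame: `seed`, `n_founders`,
#'   `n_clusters`, `n_collisions`, `n_heterotypic`) and `summary` (means and
#'   quantiles of the heterotypic collision count).
#' @export
simulate_growth_collisions <- function(config) {
  abort_if(!inherits(config, "growth_sim_config"),
           "config must come from growth_sim_config()")
  L <- config$segment_length_mm; W <- config$segment_width_mm
  alphabet <- c(names(config$label_freqs), "none")
  p_label <- c(config$label_freqs, none = 1 - sum(config$label_freqs))
  area <- L * W
  with_seed(config$seed, {
    res <- matrix(0L, config$n_seeds, 4,
                  dimnames = list(NULL, c("n_founders", "n_clusters",
                                          "n_collisions", "n_heterotypic")))
    for (s in seq_len(config$n_seeds)) {
      k <- if (!is.null(config$n_founders)) config$n_founders
           else stats::rpois(1, config$founder_intensity * area)
      if (k == 0) next
      xs <- stats::runif(k, 0, L); ys <- stats::runif(k, 0, W)
      labels <- sample(alphabet, k, replace = TRUE, prob = p_label)
      rates <- sample(config$growth_rates, k, replace = TRUE)
      radius <- config$r0_mm * exp(rates * config$endpoint_day)
      membership <- disc_clusters(xs, ys, radius)
      sizes <- tabulate(membership)
      het <- vapply(seq_along(sizes), function(cl) {
        status_from_labels(labels[membership == cl])$status == "heterotypic"
      }, logical(1))
      res[s, ] <- c(k, length(sizes), sum(sizes >= 2), sum(het))
    }
    per_seed <- data.frame(seed = seq_len(config$n_seeds), res)
    list(per_seed = per_seed,
         summary = list(
           mean_heterotypic = mean(per_seed$n_heterotypic),
           mean_collisions = mean(per_seed$n_collisions),
           mean_clusters = mean(per_seed$n_clusters),
           q_heterotypic = stats::quantile(per_seed$n_heterotypic,
                                           c(0.025, 0.5, 0.975))))
  })
}

# Transitive merging of overlapping discs into clusters; order-independent by
# construction (connected components of the overlap graph).
disc_clusters <- function(xs, ys, radius) {
  k <- length(xs)
  if (k == 1) return(1L)
  d <- as.matrix(stats::dist(cbind(xs, ys)))
  touch <- d < outer(radius, radius, "+")
  diag(touch) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(touch, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Paired comparison of observed and expected collision counts
#'
#' Paired two-tailed t-test of per-segment observed heterotypic counts against
#' the per-segment expectations from a null model (analytic or simulated).
#' Degenerate inputs with zero variance of the differences return `t = 0,
#' p = 1` when the means agree exactly.
#'
#' @param observed numeric vector of observed counts per segment.
#' @param expected numeric vector of expected counts per segment (same
#'   order/length).
#' @return list with `statistic`, `p_value`, `df`, `mean_difference`.
#' @export
compare_observed_expected <- function(observed, expected) {
  abort_if(length(observed) != length(expected),
           "observed and expected must have equal length")
  abort_if(length(observed) < 2,
           "need at least two segments for a paired t-test")
  d <- observed - expected
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    t_stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
  } else {
    t_stat <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  list(statistic = t_stat, p_value = p, df = n - 1, mean_difference = md)
}

#' Local spatial tumour density at tumour locations
#'
#' Gaussian kernel density of the tumour point pattern, evaluated at each
#' tumour's own location (leave-self-in). Bandwidth defaults to the mean of
#' the per-axis Silverman rule-of-thumb bandwidths.
#'
#' @param x,y tumour coordinates within one segment.
#' @param bandwidth kernel bandwidth; required when fewer than two points.
#' @return numeric vector of densities, one per tumour.
#' @export
local_density_field <- function(x, y, bandwidth = NULL) {
  abort_if(length(x) != length(y), "x and y must have equal length")
  abort_if(length(x) < 1, "need at least one tumour")
  if (is.null(bandwidth)) {
    abort_if(length(x) < 2,
             "bandwidth must be supplied for a single point")
    bandwidth <- mean(c(stats::bw.nrd0(x), stats::bw.nrd0(y)))
    abort_if(!is.finite(bandwidth) || bandwidth <= 0,
             "degenerate coordinates: supply a bandwidth")
  }
  d2 <- as.matrix(stats::dist(cbind(x, y)))^2
  unname(rowMeans(exp(-d2 / (2 * bandwidth^2)))) / (2 * pi * bandwidth^2)
}

#' Do heterotypic tumours sit in denser regions?
#'
#' Two-sample Kolmogorov-Smirnov comparison of local density values at
#' heterotypic versus non-heterotypic tumour locations, with paired Q-Q
#' quantiles for plotting. Under the clustering hypothesis, densities at
#' heterotypic tumours would be stochastically larger.
#'
#' @param densities densities from [local_density_field()].
#' @param statuses Confetti status per tumour (same length).
#' @return list with `statistic` (KS D), `p_value`, `qq` (data.frame of
#'   matched quantiles `q_heterotypic`, `q_other`, `prob`), and group sizes.
#' @export
heterotypia_density_test <- function(densities, statuses) {
  abort_if(length(densities) != length(statuses),
           "densities and statuses must have equal length")
  het <- densities[statuses == "heterotypic"]
  other <- densities[statuses != "heterotypic"]
  abort_if(length(het) == 0 || length(other) == 0,
           "both heterotypic and non-heterotypic tumours are required")
  ks <- suppressWarnings(stats::ks.test(het, other))
  p <- stats::ppoints(min(length(het), length(other)))
  qq <- data.frame(prob = p,
                   q_heterotypic = stats::quantile(het, p, names = FALSE),
                   q_other = stats::quantile(other, p, names = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value, qq = qq,
       n_heterotypic = length(het), n_other = length(other))
}

#' Regression of heterotypic fraction on mean tumour density
#'
#' Ordinary least-squares regression of per-segment heterotypic fraction on
#' per-segment mean tumour density, reporting the slope and the adjusted
#' R-squared `1 - (1 - R^2)(n - 1)/(n - 2)`. A value near (or below) zero
#' indicates no relationship between overall density and heterotypia.
#'
#' @param mean_density per-segment mean local density.
#' @param het_fraction per-segment heterotypic fraction.
#' @return list with `slope`, `intercept`, `adj_r_squared`, `n`.
#' @export
density_fraction_regression <- function(mean_density, het_fraction) {
  abort_if(length(mean_density) != length(het_fraction),
           "inputs must have equal length")
  abort_if(length(mean_density) < 3,
           "adjusted R-squared needs at least three segments")
  fit <- stats::lm(het_fraction ~ mean_density)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r_squared = s$adj.r.squared,
       n = length(mean_density))
}
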