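#' Fit exponential growth rates with per-mouse random effects
#'
#' Models log tumour size during the exponential growth phase (observations
#' inside `window`, default days 40-63 post-ENU) as
#' `log(size) = alpha + beta_group * day + u_mouse + eps` with a group main
#' effect, separate per-group slopes, and a zero-mean random intercept per
#' mouse. Fitted by restricted maximum likelihood (`nlme::lme`); if that
#' fails (e.g. degenerate noise-free input), a fixed-effects fallback with
#' mouse indicator terms is used -- slopes are estimated consistently either
#' way. Size units cancel on the log scale, so area or diameter both work.
#'
#' @param series data.frame with columns `tumour_id`, `group`, `mouse_id`,
#'   `day`, `size` (see [gen_growth_series()]).
#' @param window inclusive day window of the exponential phase.
#' @return list of class `growth_fit`: `rates` (per-group per-day slope),
#'   `rate_se`, `ratio` (heterotypic/homotypic where those groups are
#'   present, otherwise second/first group level), `window`,
#'   `mouse_variance`, `sigma`, `method`, `n_obs`.
#' @examples
#' fit_exponential_growth(gen_growth_series(n_per_group = 10, seed = 1))
#' @export
fit_exponential_growth <- function(series, window = c(40, 63)) {
  need_cols(series, c("tumour_id", "group", "mouse_id", "day", "size"),
            "growth series")
  abort_if(length(window) != 2 || window[1] >= window[2],
           "window must be an increasing day interval")
  abort_if(any(series$size <= 0), "sizes must be positive")
  dat <- series[series$day >= window[1] & series$day <= window[2], ,
                drop = FALSE]
  abort_if(nrow(dat) == 0, "no observations inside the fitting window")
  groups <- sort(unique(dat$group))
  abort_if(length(groups) < 2,
           "both tumour groups are needed to contrast growth rates")
  abort_if(length(groups) > 2, "exactly two groups are supported")
  abort_if(length(unique(dat$day)) < 2,
           "need at least two timepoints inside the window")
  abort_if(length(unique(dat$mouse_id)) < 2, "need at least two mice")
  dat$log_size <- log(dat$size)
  dat$group <- factor(dat$group, levels = groups)
  dat$mouse_id <- factor(dat$mouse_id)
  fit <- tryCatch(
    nlme::lme(log_size ~ group * day, random = ~ 1 | mouse_id, data = dat,
              method = "REML"),
    error = function(e) NULL)
  if (!is.null(fit)) {
    fe <- nlme::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    mouse_var <- as.numeric(nlme::VarCorr(fit)["(Intercept)", "Variance"])
    sigma <- fit$sigma
    method <- "lme"
  } else {
    lmfit <- stats::lm(log_size ~ mouse_id + group * day, data = dat)
    fe <- stats::coef(lmfit)
    V <- stats::vcov(lmfit)
    V[is.na(V)] <- 0
    mouse_var <- NA_real_
    sigma <- summary(lmfit)$sigma
    method <- "lm"
  }
  slope_ref <- fe[["day"]]
  int_name <- paste0("group", groups[2], ":day")
  slope_alt <- slope_ref + fe[[int_name]]
  se_ref <- sqrt(V["day", "day"])
  se_alt <- sqrt(V["day", "day"] + V[int_name, int_name] +
                   2 * V["day", int_name])
  rates <- stats::setNames(c(slope_ref, slope_alt), groups)
  rate_se <- stats::setNames(c(se_ref, se_alt), groups)
  if (all(c("heterotypic", "homotypic") %in% groups)) {
    ratio <- rates[["heterotypic"]] / rates[["homotypic"]]
  } else {
    ratio <- rates[[2]] / rates[[1]]
  }
  structure(list(rates = rates, rate_se = rate_se, ratio = unname(ratio),
                 window = window, mouse_variance = mouse_var, sigma = sigma,
                 method = method, n_obs = nrow(dat)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit (%s), days %g-%g, %d observations\n",
              x$method, x$window[1], x$window[2], x$n_obs))
  for (g in names(x$rates)) {
    cat(sprintf("  %-12s rate %.4f /day (se %.4f)\n", g, x$rates[[g]],
                x$rate_se[[g]]))
  }
  cat(sprintf("  rate ratio: %.3f\n", x$ratio))
  invisible(x)
}

#' Mix major and minor clone counts into a pseudo-bulk sample
#'
#' Reconstructs the expression profile of an intact polyclonal tumour by
#' sampling reads from its constituent clones at a fixed ratio (default 2:1
#' major:minor): `ceiling(2/3 * target_depth)` reads are drawn multinomially
#' from the major clone's gene proportions and the remaining
#' `floor(1/3 * target_depth)` from the minor clone's, then summed per gene.
#' Operating on gene-count columns is distributionally equivalent to sampling
#' raw reads.
#'
#' @param major,minor named non-negative count vectors over a shared gene
#'   universe (aligned by name when named, by position otherwise).
#' @param ratio length-2 mixing ratio (major:minor).
#' @param target_depth total reads of the pseudo-sample.
#' @param seed optional integer seed.
#' @return named integer vector of pseudo-bulk counts summing to
#'   `target_depth`.
#' @examples
#' m <- gen_count_matrix(20, 2, 1e4, seed = 1)
#' pb <- mix_pseudobulk(m[, 1], m[, 2], target_depth = 1e4, seed = 2)
#' sum(pb)
#' @export
mix_pseudobulk <- function(major, minor, ratio = c(2, 1), target_depth,
                           seed = NULL) {
  abort_if(length(ratio) != 2 || any(ratio < 0) || sum(ratio) == 0,
           "ratio must be two non-negative numbers")
  abort_if(!is_count(target_depth) || target_depth < 1,
           "target_depth must be >= 1")
  if (!is.null(names(major)) && !is.null(names(minor))) {
    genes <- union(names(major), names(minor))
    a <- stats::setNames(numeric(length(genes)), genes)
    b <- a
    a[names(major)] <- major
    b[names(minor)] <- minor
    major <- a; minor <- b
  } else {
    abort_if(length(major) != length(minor),
             "unnamed count vectors must have equal length")
    genes <- names(major) %||% sprintf("gene_%04d", seq_along(major))
  }
  abort_if(any(major < 0) || any(minor < 0), "counts must be non-negative")
  abort_if(sum(major) == 0 || sum(minor) == 0,
           "all-zero count column: proportions are undefined")
  n_major <- ceiling(ratio[1] * target_depth / sum(ratio))
  n_minor <- target_depth - n_major
  with_seed(seed, {
    draw <- stats::rmultinom(1, n_major, major / sum(major))[, 1]
    if (n_minor > 0) {
      draw <- draw + stats::rmultinom(1, n_minor, minor / sum(minor))[, 1]
    }
    stats::setNames(as.integer(draw), genes)
  })
}
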