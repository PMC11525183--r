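.pipeline_stages <- c("synthesize", "patches", "collide", "clonality",
                      "domains", "growth")

# Stages whose inputs come from an earlier stage.
.stage_deps <- list(synthesize = character(0),
                    patches = character(0),
                    collide = "synthesize",
                    clonality = "synthesize",
                    domains = c("synthesize", "clonality"),
                    growth = character(0))

#' Run the analysis pipeline on a synthetic cohort
#'
#' Executes the requested stages in dependency order
#' (synthesize -> patches/collide -> clonality -> domains -> growth), writing
#' each stage's outputs under `out_dir` and a `manifest.json` recording the
#' seed, package version, stage parameters and MD5 hashes of every written
#' file. Dependencies of a requested stage are run automatically.
#'
#' `config` is a list (or path to a YAML file) with top-level keys `seed`,
#' optional `out_dir`, and `stages`: a named list whose names select stages
#' and whose values hold per-stage parameter overrides:
#' \describe{
#'   \item{synthesize}{arguments of [cohort_config()].}
#'   \item{patches}{`rows`, `cols`, `reps`, `connectivity`.}
#'   \item{collide}{`bandwidth` for the density diagnostics (optional).}
#'   \item{clonality}{arguments of [filter_params()] plus `accept_flagged`.}
#'   \item{domains}{`B`, `level`.}
#'   \item{growth}{arguments of [gen_growth_series()] plus `window`.}
#' }
#' Unknown top-level keys or stage names are rejected before any work is
#' done.
#'
#' @param config configuration list or YAML path.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(!is.list(config), "config must be a list or a YAML path")
  unknown <- setdiff(names(config), c("seed", "out_dir", "stages"))
  abort_if(length(unknown) > 0,
           "unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stages <- config$stages %||% stats::setNames(list(), character(0))
  bad <- setdiff(names(stages), .pipeline_stages)
  abort_if(length(bad) > 0,
           "unknown stage name(s): ", paste(bad, collapse = ", "))
  abort_if(length(stages) == 0, "no stages requested")
  out_dir <- out_dir %||% config$out_dir %||% stop("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  requested <- names(stages)
  run <- unique(unlist(lapply(requested, function(s) c(.stage_deps[[s]], s))))
  run <- .pipeline_stages[.pipeline_stages %in% run]
  pars <- function(stage) stages[[stage]] %||% list()

  files <- character(0)
  state <- new.env(parent = emptyenv())

  for (stage in run) {
    p <- pars(stage)
    if (stage == "synthesize") {
      cfg <- do.call(cohort_config, c(p, list(rng_seed = seed)))
      field <- gen_tumour_field(cfg)
      calls <- gen_variant_table(field$truth, cfg)
      state$cfg <- cfg; state$field <- field; state$calls <- calls
      f1 <- file.path(out_dir, "tumours.tsv")
      f2 <- file.path(out_dir, "variants.tsv")
      f3 <- file.path(out_dir, "variants.vcf")
      f4 <- file.path(out_dir, "ground_truth.json")
      write_tumour_table(field$tumours, f1)
      write_variant_table(calls, f2)
      write_variant_vcf(calls, f3)
      write_ground_truth(field$truth, f4)
      files <- c(files, f1, f2, f3, f4)
    } else if (stage == "patches") {
      rows <- p$rows %||% 10L; cols <- p$cols %||% 100L
      reps <- p$reps %||% 1000L; conn <- p$connectivity %||% 4L
      grids <- lapply(seq_len(reps), function(i) {
        simulate_labelling(rows, cols, seed = seed + i)
      })
      summary <- patch_size_summary(lapply(grids, find_patches,
                                           connectivity = conn))
      frac <- mean(vapply(grids, labelled_fraction, numeric(1)))
      f1 <- file.path(out_dir, "patch_sizes.tsv")
      tsv_write(summary, f1)
      f2 <- file.path(out_dir, "patch_summary.json")
      jsonlite::write_json(list(rows = rows, cols = cols, reps = reps,
                                connectivity = conn,
                                mean_labelled_fraction = frac),
                           f2, auto_unbox = TRUE, digits = NA)
      files <- c(files, f1, f2)
    } else if (stage == "collide") {
      tum <- state$field$tumours
      segs <- split(tum, tum$segment_id)
      seg_stats <- do.call(rbind, lapply(segs, function(s) {
        dens <- if (nrow(s) >= 2) {
          local_density_field(s$x_mm, s$y_mm, bandwidth = p$bandwidth)
        } else NA_real_
        data.frame(segment_id = s$segment_id[1], n_tumours = nrow(s),
                   mean_density = mean(dens),
                   het_fraction = suppressWarnings(
                     heterotypic_fraction(s$confetti_status)),
                   stringsAsFactors = FALSE)
      }))
      rownames(seg_stats) <- NULL
      f1 <- file.path(out_dir, "segment_density.tsv")
      tsv_write(seg_stats, f1)
      ok <- stats::complete.cases(seg_stats[c("mean_density",
                                              "het_fraction")])
      reg <- if (sum(ok) >= 3) {
        density_fraction_regression(seg_stats$mean_density[ok],
                                    seg_stats$het_fraction[ok])
      } else NULL
      f2 <- file.path(out_dir, "density_regression.json")
      jsonlite::write_json(reg %||% list(), f2, auto_unbox = TRUE,
                           digits = NA)
      files <- c(files, f1, f2)
    } else if (stage == "clonality") {
      fp_args <- p[intersect(names(p), names(formals(filter_params)))]
      filt <- filter_amplicon_variants(
        state$calls, do.call(filter_params, fp_args),
        accept_flagged = isTRUE(p$accept_flagged))
      cohort <- classify_cohort(filt$retained)
      state$cohort <- cohort
      f1 <- file.path(out_dir, "clonality.tsv")
      f2 <- file.path(out_dir, "clones.tsv")
      f3 <- file.path(out_dir, "review_flagged.tsv")
      tsv_write(cohort$samples, f1)
      tsv_write(cohort$clones, f2)
      tsv_write(filt$review_flagged, f3)
      files <- c(files, f1, f2, f3)
    } else if (stage == "domains") {
      samples <- group_samples(state$cohort)
      f1 <- file.path(out_dir, "domain_samples.tsv")
      tsv_write(samples, f1)
      files <- c(files, f1)
      B <- p$B %||% 2000L; level <- p$level %||% 0.95
      groups <- split(samples, samples$group)
      cis <- list()
      if (!is.null(groups$monoclonal) && !is.null(groups$major)) {
        cis$monoclonal_vs_major <- bootstrap_diff_ci(
          groups$monoclonal, groups$major, B = B, level = level,
          seed = seed + 1L)
      }
      if (!is.null(groups$monoclonal) && !is.null(groups$minor)) {
        cis$monoclonal_vs_minor <- bootstrap_diff_ci(
          groups$monoclonal, groups$minor, B = B, level = level,
          seed = seed + 2L)
      }
      if (!is.null(groups$major) && !is.null(groups$minor)) {
        cis$major_vs_minor <- bootstrap_diff_ci(
          groups$major, groups$minor, paired = TRUE, B = B, level = level,
          seed = seed + 3L)
      }
      for (nm in names(cis)) {
        f <- file.path(out_dir, paste0("bootstrap_", nm, ".tsv"))
        tsv_write(cis[[nm]], f)
        files <- c(files, f)
      }
    } else if (stage == "growth") {
      window <- p$window %||% c(40, 63)
      gp <- p[intersect(names(p), names(formals(gen_growth_series)))]
      series <- do.call(gen_growth_series,
                        c(gp, list(seed = stage_seed(seed, "growth"))))
      fit <- fit_exponential_growth(series, window = window)
      f1 <- file.path(out_dir, "growth_series.tsv")
      f2 <- file.path(out_dir, "growth_fit.json")
      write_growth_series(series, f1)
      jsonlite::write_json(list(rates = as.list(fit$rates),
                                ratio = fit$ratio, method = fit$method,
                                window = fit$window, n_obs = fit$n_obs),
                           f2, auto_unbox = TRUE, digits = NA)
      files <- c(files, f1, f2)
    }
  }

  manifest <- list(
    package = "polyclone",
    version = as.character(utils::packageVersion("polyclone")),
    seed = seed,
    stages = run,
    parameters = stages,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))),
    generated_at = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
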