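test_that("zero tumour intensity yields an empty field", {
  cfg <- cohort_config(n_mice = 2, tumour_intensity = 0, rng_seed = 1)
  field <- gen_tumour_field(cfg)
  expect_equal(nrow(field$tumours), 0)
  expect_equal(nrow(field$truth$founders), 0)
})

test_that("zero polyclonal fraction forces single founders", {
  cfg <- cohort_config(n_mice = 2, polyclonal_fraction = 0, rng_seed = 2)
  field <- gen_tumour_field(cfg)
  k <- table(field$truth$founders$tumour_id)
  expect_true(all(k == 1))
  expect_true(all(field$truth$tumours$class == "monoclonal"))
})

test_that("tumour counts follow the spatial Poisson mean", {
  # oracle: closed form lambda * A per segment
  cfg_base <- cohort_config(n_mice = 1, segments_per_mouse = 1,
                            segment_length_mm = 20, segment_width_mm = 10,
                            tumour_intensity = 0.03, rng_seed = 1)
  lambdaA <- 0.03 * 200
  counts <- vapply(1:400, function(s) {
    cfg <- cohort_config(n_mice = 1, segments_per_mouse = 1,
                         segment_length_mm = 20, segment_width_mm = 10,
                         tumour_intensity = 0.03, rng_seed = s)
    nrow(gen_tumour_field(cfg)$tumours)
  }, numeric(1))
  se <- sqrt(lambdaA / 400)
  expect_lt(abs(mean(counts) - lambdaA), 3 * se)
  # variance of a Poisson count equals its mean, within Monte-Carlo error
  expect_lt(abs(var(counts) - lambdaA), 5 * lambdaA / sqrt(400))
  expect_true(all(counts >= 0))
  expect_error(gen_tumour_field(
    cohort_config(segment_length_mm = 0, rng_seed = 1)), "positive area")
  invisible(cfg_base)
})

test_that("the field generator is deterministic and truth is coherent", {
  cfg <- cohort_config(n_mice = 2, rng_seed = 7)
  f1 <- gen_tumour_field(cfg)
  f2 <- gen_tumour_field(cfg)
  expect_identical(f1, f2)
  # clone fractions sum to 1 per tumour
  sums <- tapply(f1$truth$founders$fraction, f1$truth$founders$tumour_id, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # founder counts stay in 2..9 for polyclonal tumours
  k <- table(f1$truth$founders$tumour_id)
  poly <- f1$truth$tumours$tumour_id[f1$truth$tumours$class == "polyclonal"]
  expect_true(all(k[poly] >= 2 & k[poly] <= 9))
  # confetti status matches the scoring rule applied to founder labels
  for (id in sample(f1$tumours$tumour_id, 20)) {
    labs <- f1$truth$founders$label[f1$truth$founders$tumour_id == id]
    expect_equal(f1$tumours$confetti_status[f1$tumours$tumour_id == id],
                 polyclone:::status_from_labels(labs)$status)
  }
})

test_that("true VAF follows f * purity / 2", {
  cfg <- cohort_config(seq_depth = 200000, seq_error = 0, rng_seed = 3)
  # single clone, purity 1 -> VAF 0.5
  t1 <- make_truth("T1", purity = 1, fractions = 1, codons = 1300)
  v1 <- gen_variant_table(t1, cfg)
  expect_equal(v1$vaf, 0.5, tolerance = 0.01)
  # two clones at f = 0.7/0.3, purity 0.8 -> VAFs 0.28 and 0.12
  t2 <- make_truth("T2", purity = 0.8, fractions = c(0.7, 0.3),
                   codons = c(900, 1500))
  v2 <- gen_variant_table(t2, cfg)
  expect_equal(sort(v2$vaf, decreasing = TRUE), c(0.28, 0.12),
               tolerance = 0.02)
  # no background errors when seq_error = 0
  expect_true(all(v2$consequence == "stop_gained"))
  expect_true(all(v2$gene == "Apc"))
  expect_error(gen_variant_table(
    make_truth("T3", purity = 1.4, fractions = 1, codons = 100), cfg),
    "purity")
})

test_that("single-amplicon windows and VAF bounds are respected", {
  cfg <- cohort_config(seq_depth = 500, seq_error = 0, rng_seed = 4)
  tr <- make_truth("T1", purity = 0.9, fractions = c(0.5, 0.5),
                   codons = c(80, 130))
  v <- gen_variant_table(tr, cfg)
  expect_true(all(v$n_amplicons == 1))
  tr2 <- make_truth("T2", purity = 0.9, fractions = 1, codons = 1300)
  expect_equal(gen_variant_table(tr2, cfg)$n_amplicons, 2L)
  # VAFs never exceed 0.5 * purity + 6 binomial SDs
  cfg2 <- cohort_config(n_mice = 3, rng_seed = 5)
  field <- gen_tumour_field(cfg2)
  calls <- gen_variant_table(field$truth, cfg2)
  drivers <- calls[!is.na(calls$aa_change), ]
  purity <- field$truth$tumours$purity[match(drivers$sample_id,
                                             field$truth$tumours$tumour_id)]
  cap <- 0.5 * purity +
    6 * sqrt(0.5 * purity * (1 - 0.5 * purity) / cfg2$seq_depth)
  expect_true(all(drivers$vaf <= cap))
})

test_that("growth series are exactly linear without noise", {
  g <- gen_growth_series(n_per_group = 4, rate_ratio = 4, base_rate = 0.05,
                         mouse_sd = 0, noise_sd = 0, seed = 1)
  for (id in unique(g$tumour_id)) {
    sub <- g[g$tumour_id == id, ]
    slopes <- diff(log(sub$size)) / diff(sub$day)
    expected <- if (sub$group[1] == "heterotypic") 0.2 else 0.05
    expect_equal(slopes, rep(expected, length(slopes)), tolerance = 1e-10)
  }
  expect_identical(gen_growth_series(n_per_group = 3, seed = 9),
                   gen_growth_series(n_per_group = 3, seed = 9))
})

test_that("domain mutation cohorts are one-hot multinomial draws", {
  probs <- default_bin_probs()
  degenerate <- lapply(probs, function(p) {
    p[] <- 0; p["MCR"] <- 1; p
  })
  cohort <- gen_domain_mutation_cohort(degenerate, n_per_group = 15, seed = 1)
  expect_true(all(cohort$MCR == 1))
  bins <- setdiff(names(cohort), c("sample_id", "group", "pair_id"))
  expect_true(all(rowSums(cohort[bins]) == 1))
  # major/minor samples are paired one-to-one
  expect_true(all(!is.na(cohort$pair_id[cohort$group %in% c("major",
                                                            "minor")])))
  expect_equal(sort(cohort$pair_id[cohort$group == "major"]),
               sort(cohort$pair_id[cohort$group == "minor"]))
  # n = 0 produces an empty group and bin_probabilities then errors
  cohort0 <- gen_domain_mutation_cohort(probs["monoclonal"],
                                        n_per_group = 0, seed = 1)
  expect_equal(nrow(cohort0), 0)
  expect_error(bin_probabilities(cohort0), "no samples")
  # frequencies track the generating multinomial within 3 binomial SEs
  big <- gen_domain_mutation_cohort(probs, n_per_group = 400, seed = 2)
  bp <- bin_probabilities(big)
  for (g in names(probs)) {
    for (b in bins) {
      p <- probs[[g]][[b]]
      obs <- bp$probability[bp$group == g & bp$bin == b]
      expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / 400) + 1e-9)
    }
  }
})

test_that("count matrices meet the multinomial constraint", {
  m <- gen_count_matrix(50, 3, depth = 1e4, seed = 1)
  expect_true(all(colSums(m) == 1e4))
  expect_identical(m, gen_count_matrix(50, 3, depth = 1e4, seed = 1))
  m1 <- gen_count_matrix(1, 2, depth = 500, seed = 2)
  expect_true(all(m1 == 500))
})
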