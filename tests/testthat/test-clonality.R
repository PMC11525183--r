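test_that("the four worked filter examples behave exactly", {
  calls <- worked_examples()
  res <- filter_amplicon_variants(calls)
  # passing stop_gained at codon 1300 retained
  expect_equal(nrow(res$retained), 1)
  expect_equal(res$retained$alt_reads, 50L)
  # alt_reads = 4 removed; indel removed regardless of VAF
  expect_false(any(res$retained$alt_reads == 4))
  expect_false(any(res$retained$consequence == "indel"))
  expect_false(any(res$review_flagged$consequence == "indel"))
  # single-amplicon window call routed to review, not discarded
  expect_equal(nrow(res$review_flagged), 1)
  expect_equal(res$review_flagged$codon, 80L)
  # accept_flagged moves it into the retained set
  res2 <- filter_amplicon_variants(calls, accept_flagged = TRUE)
  expect_equal(nrow(res2$retained), 2)
  expect_true(80L %in% res2$retained$codon)
})

test_that("single-amplicon review requires the window, reads and VAF", {
  base <- worked_examples()[4, ]
  # outside the windows a single-amplicon call is discarded
  out <- base; out$codon <- 200L
  res <- filter_amplicon_variants(out)
  expect_equal(nrow(res$review_flagged), 0)
  expect_equal(nrow(res$retained), 0)
  # VAF exactly at the threshold is not "more than 0.01"
  at <- base; at$vaf <- 0.01; at$alt_reads <- 5L
  expect_equal(nrow(filter_amplicon_variants(at)$review_flagged), 0)
  # second window
  w2 <- base; w2$codon <- 130L
  expect_equal(nrow(filter_amplicon_variants(w2)$review_flagged), 1)
  # empty input passes through
  empty <- worked_examples()[0, ]
  res0 <- filter_amplicon_variants(empty)
  expect_equal(nrow(res0$retained), 0)
  expect_equal(nrow(res0$review_flagged), 0)
})

test_that("raising any threshold never enlarges the retained set", {
  base_params <- filter_params()
  for (seed in 1:6) {
    calls <- random_variant_table(120, seed)
    base <- filter_amplicon_variants(calls, base_params)$retained
    variants <- list(
      filter_params(min_vaf = 0.05),
      filter_params(min_alt_reads = 10),
      filter_params(min_amplicons = 3),
      filter_params(min_vaf = 0.03, min_alt_reads = 8, min_amplicons = 3))
    key <- function(df) paste(df$sample_id, df$gene, df$codon, df$vaf)
    for (p in variants) {
      tightened <- filter_amplicon_variants(calls, p)$retained
      expect_true(all(key(tightened) %in% key(base)))
    }
    # relaxing the indel rule can only add calls
    relaxed <- filter_amplicon_variants(
      calls, filter_params(drop_indels = FALSE))$retained
    expect_true(all(key(base) %in% key(relaxed)))
  }
})

test_that("long-read filtering keeps deep nonsense calls only", {
  calls <- data.frame(
    consequence = c("stop_gained", "stop_gained", "missense", "stop_gained"),
    vaf = c(0.019, 0.30, 0.50, 0.25),
    depth = c(500L, 99L, 1000L, 400L))
  kept <- filter_longread_variants(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$vaf, 0.25)
  # boundary values are inclusive
  edge <- data.frame(consequence = "stop_gained", vaf = 0.02, depth = 100L)
  expect_equal(nrow(filter_longread_variants(edge)), 1)
})

test_that("clonality classes follow the nonsense-mutation count", {
  mono <- classify_clonality(apc_call(0.41, 1300))
  expect_equal(mono$class, "monoclonal")
  expect_equal(mono$summed_vaf, 0.41)
  expect_equal(mono$purity_estimate, 0.82)
  expect_false(mono$tie_flag)

  poly <- classify_clonality(rbind(apc_call(0.12, 700), apc_call(0.30, 1450)))
  expect_equal(poly$class, "polyclonal")
  expect_equal(poly$clones$rank, c("major", "minor"))
  expect_equal(poly$clones$vaf, c(0.30, 0.12))
  expect_equal(poly$summed_vaf, 0.42)

  nodrv <- classify_clonality(apc_call(0.5, 1000, consequence = "missense"))
  expect_equal(nodrv$class, "no_driver")
  expect_equal(nrow(nodrv$clones), 0)
  expect_true(is.na(nodrv$purity_estimate))
})

test_that("near-equal VAFs produce a deterministic co-major tie", {
  tie <- classify_clonality(rbind(apc_call(0.2, 1450), apc_call(0.2, 700)))
  expect_true(tie$tie_flag)
  expect_equal(tie$clones$rank, c("major", "major"))
  # deterministic order by codon within the tie
  expect_equal(tie$clones$codon, c(700, 1450))
  # just outside the tie window: a clear major emerges
  clear <- classify_clonality(rbind(apc_call(0.22, 1450), apc_call(0.19, 700)))
  expect_false(clear$tie_flag)
  expect_equal(clear$clones$rank, c("major", "minor"))
})

test_that("classification is invariant to call order", {
  calls <- rbind(apc_call(0.30, 1450), apc_call(0.12, 700),
                 apc_call(0.05, 200))
  ref <- classify_clonality(calls)
  for (seed in 1:5) {
    set.seed(seed)
    perm <- classify_clonality(calls[sample(nrow(calls)), ])
    expect_identical(ref, perm)
  }
})

test_that("cohort classification splits by sample", {
  calls <- rbind(apc_call(0.41, 1300, sample_id = "A"),
                 apc_call(0.30, 700, sample_id = "B"),
                 apc_call(0.11, 1450, sample_id = "B"))
  res <- classify_cohort(calls)
  expect_equal(sort(res$samples$class), c("monoclonal", "polyclonal"))
  expect_equal(res$clones$sample_id, c("A", "B", "B"))
  expect_error(classify_clonality(calls), "single sample")
})

test_that("purity conventions match their definitions", {
  expect_equal(purity_from_vafs(0.5), 1.0)
  expect_equal(purity_from_vafs(c(0.3, 0.1), mode = "sum"), 0.4)
  expect_equal(purity_from_vafs(c(0.3, 0.1)), 0.4)  # 2 * mean
  expect_equal(purity_from_vafs(c(0.6, 0.6)), 1.0)  # clamped
  expect_error(purity_from_vafs(numeric(0)), "undefined")
})
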