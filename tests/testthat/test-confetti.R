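test_that("labelling respects degenerate and invalid frequencies", {
  g0 <- simulate_labelling(5, 8, confetti_freqs(CFP = 0, YFP = 0, RFP = 0),
                           seed = 1)
  expect_true(all(g0 == "none"))
  g1 <- simulate_labelling(5, 8, c(RFP = 1), seed = 1)
  expect_true(all(g1 == "RFP"))
  expect_error(simulate_labelling(5, 8, c(CFP = 0.6, YFP = 0.6)),
               "sum to more")
  expect_error(validate_label_freqs(c(0.1, 0.2)), "named")
  expect_error(validate_label_freqs(c(none = 0.1)), "reserved")
})

test_that("labelled fraction is unbiased for the sum of frequencies", {
  # closed-form Bernoulli mean: 0.027 + 0.041 + 0.038 = 0.106
  reps <- 300
  fr <- vapply(seq_len(reps), function(i) {
    labelled_fraction(simulate_labelling(10, 100, seed = 1000 + i))
  }, numeric(1))
  se <- sqrt(0.106 * 0.894 / 1000) / sqrt(reps)
  expect_lt(abs(mean(fr) - 0.106), 3 * se)
})

test_that("labelling is deterministic given a seed", {
  expect_identical(simulate_labelling(10, 20, seed = 42),
                   simulate_labelling(10, 20, seed = 42))
})

test_that("find_patches handles degenerate grids", {
  empty <- matrix("none", 4, 6)
  expect_equal(nrow(find_patches(empty)), 0)
  full <- matrix("YFP", 4, 6)
  p <- find_patches(full)
  expect_equal(nrow(p), 1)
  expect_equal(p$size, 24)
  expect_equal(p$label, "YFP")
})

test_that("a 4-connectivity checkerboard splits into singleton patches", {
  n <- 6
  grid <- matrix("none", n, n)
  grid[(row(grid) + col(grid)) %% 2 == 0] <- "RFP"
  p4 <- find_patches(grid, connectivity = 4)
  expect_equal(nrow(p4), sum(grid == "RFP"))
  expect_true(all(p4$size == 1))
  # with diagonals the same grid is one connected patch
  p8 <- find_patches(grid, connectivity = 8)
  expect_equal(nrow(p8), 1)
})

test_that("patches partition the labelled cells exactly", {
  for (seed in 1:8) {
    g <- simulate_labelling(12, 15, confetti_freqs(CFP = 0.1, YFP = 0.15,
                                                   RFP = 0.1),
                            seed = seed)
    p <- find_patches(g)
    memb <- attr(p, "membership")
    expect_identical(memb > 0, g != "none")
    expect_equal(sum(p$size), sum(g != "none"))
    expect_equal(as.vector(table(memb[memb > 0])),
                 p$size[order(p$patch_id)])
    # patch cells all share the patch label
    for (id in p$patch_id) {
      expect_true(all(g[memb == id] == p$label[p$patch_id == id]))
    }
  }
})

test_that("find_patches agrees with the igraph components oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    nr <- sample(2:20, 1); nc <- sample(2:20, 1)
    g <- simulate_labelling(nr, nc,
                            confetti_freqs(CFP = 0.2, YFP = 0.2, RFP = 0.1),
                            seed = seed)
    for (conn in c(4, 8)) {
      p <- find_patches(g, connectivity = conn)
      o <- oracle_patches(g, connectivity = conn)
      expect_equal(
        p[order(p$label, p$size), c("label", "size")],
        o$patches[order(o$patches$label, o$patches$size), ],
        ignore_attr = TRUE)
      memb <- attr(p, "membership")[o$cells]
      expect_identical(canonical_partition(memb),
                       canonical_partition(o$membership))
    }
  }
})

test_that("patch_size_summary tabulates crypt fractions per colour", {
  g <- matrix("none", 1, 5)
  g[1, 1:3] <- "CFP"
  s <- patch_size_summary(find_patches(g))
  expect_equal(s$size, 3)
  expect_equal(s$crypt_fraction, 1)
  expect_equal(nrow(patch_size_summary(find_patches(matrix("none", 3, 3)))), 0)
})

test_that("1xN run counts match the Bernoulli closed form", {
  # E[#runs] = N*p - (N-1)*p^2 for a Bernoulli(p) sequence of length N
  N <- 50; p <- 0.3; reps <- 2000
  counts <- vapply(seq_len(reps), function(i) {
    g <- simulate_labelling(1, N, c(RFP = p), seed = 5000 + i)
    nrow(find_patches(g))
  }, numeric(1))
  expected <- N * p - (N - 1) * p^2
  se <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("confetti status scoring follows the microscopy rule", {
  expect_equal(score_confetti_status(gland_composition(c(RFP = 10))),
               list(status = "homotypic", label = "RFP"))
  expect_equal(score_confetti_status(gland_composition(c(RFP = 6, YFP = 4)))$status,
               "heterotypic")
  expect_equal(score_confetti_status(gland_composition(c(RFP = 6, none = 4)))$status,
               "heterotypic")
  # a single intermixed gland is disregarded
  expect_equal(score_confetti_status(
    gland_composition(c(RFP = 9, YFP = 1), intermixed = "YFP")),
    list(status = "homotypic", label = "RFP"))
  # but two intermixed-flagged glands of one colour are kept
  expect_equal(score_confetti_status(
    gland_composition(c(RFP = 9, YFP = 2), intermixed = "YFP"))$status,
    "heterotypic")
  expect_equal(score_confetti_status(gland_composition(c(none = 5)))$status,
               "uncoloured")
  expect_error(score_confetti_status(
    gland_composition(c(YFP = 1), intermixed = "YFP")), "no glands")
})

test_that("heterotypic fraction excludes uncoloured tumours", {
  expect_equal(heterotypic_fraction(rep("homotypic", 5)), 0)
  expect_equal(heterotypic_fraction(c(rep("homotypic", 6),
                                      rep("heterotypic", 4),
                                      rep("uncoloured", 7))), 0.4)
  expect_warning(out <- heterotypic_fraction(rep("uncoloured", 3)),
                 "undefined")
  expect_true(is.na(out))
  expect_error(heterotypic_fraction("weird"), "unknown status")
})
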