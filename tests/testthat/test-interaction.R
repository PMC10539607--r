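test_that("signature overlap handles identical and disjoint pairs", {
  U <- paste0("g", 1:20)
  sa <- setNames(rnorm(10), U[1:10])
  ov <- signature_overlap(sa, sa, U)
  expect_length(ov$genes, 10L)
  expect_identical(ov$enrichment$odds_ratio, Inf)
  expect_true(ov$enrichment$significant)

  sb <- setNames(rnorm(10), U[11:20])
  dis <- signature_overlap(sa, sb, U)
  expect_length(dis$genes, 0L)
  expect_equal(dis$enrichment$p_value, 1)
  expect_error(signature_overlap(sa, sb, character(0)), "empty universe")
})

test_that("discordance fractions count sign quadrants correctly", {
  genes <- paste0("g", 1:6)
  sa <- setNames(c(1, 2, -3, -1, 2, -2), genes)
  opp <- directional_discordance(sa, -sa, genes)
  expect_equal(opp$overall_discordance, 1)
  same <- directional_discordance(sa, sa, genes)
  expect_equal(same$overall_discordance, 0)

  # B-up genes g1..g4 with A-signs (-, -, +, +)
  sb <- setNames(c(1, 1, 1, 1, -1, -1), genes)
  sa2 <- setNames(c(-1, -2, 3, 1, 1, -1), genes)
  d <- directional_discordance(sa2, sb, genes)
  expect_equal(d$frac_b_up_a_down, 0.5)
  expect_equal(d$frac_b_up_a_up, 0.5)
  expect_equal(d$frac_b_up_a_down + d$frac_b_up_a_up, 1)
  expect_equal(d$frac_b_down_a_up + d$frac_b_down_a_down, 1)

  # negating both signatures leaves fractions for the flipped quadrants:
  # overall discordance is unchanged, concordance maps to discordance
  dn <- directional_discordance(-sa2, -sb, genes)
  expect_equal(dn$overall_discordance, d$overall_discordance)
  d1 <- directional_discordance(-sa2, sb, genes)
  expect_equal(d1$overall_discordance, 1 - d$overall_discordance)

  # zero scores are counted but excluded from fractions
  sz <- setNames(c(0, 1, -1, 1, 1, -1), genes)
  dz <- directional_discordance(sz, sb, genes)
  expect_identical(dz$n_zero, 1L)

  expect_error(directional_discordance(sa[1:3], sb, genes), "missing")
})

test_that("KS statistic matches the grid oracle exactly", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(3, 2, 1))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(3, 2, 1))$p_value, 1)
  expect_equal(ks_two_sample(c(1, 2), c(3, 4))$D, 1)

  set.seed(8)
  for (i in 1:25) {
    n <- sample(2:100, 1)
    m <- sample(2:100, 1)
    x <- round(rnorm(n), sample(0:2, 1))   # force ties sometimes
    y <- round(rnorm(m, mean = runif(1, -1, 1)), sample(0:2, 1))
    ks <- ks_two_sample(x, y)
    expect_equal(ks$D, ks_grid_oracle(x, y), tolerance = 1e-12)
    # invariance under a common strictly increasing transform
    expect_equal(ks_two_sample(exp(x), exp(y))$D, ks$D, tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, c(1, 2)), "at least 2")
  expect_error(ks_two_sample(c(1, NA), c(1, 2)), "finite")
})

test_that("the asymptotic KS p-value reproduces series values", {
  # lambda = 1: p = 2 (e^-2 - e^-8 + e^-18 - ...)
  by_hand <- 2 * sum((-1)^(0:9) * exp(-2 * (1:10)^2))
  expect_equal(ks_asymptotic_pvalue(0.5, 8, 8), by_hand, tolerance = 1e-12)
  expect_equal(round(ks_asymptotic_pvalue(0.5, 8, 8), 4), 0.27)
  expect_equal(ks_asymptotic_pvalue(0, 10, 10), 1)

  # strictly decreasing in D
  ds <- seq(0.05, 0.95, by = 0.05)
  ps <- vapply(ds, ks_asymptotic_pvalue, numeric(1), n = 30, m = 40)
  expect_true(all(diff(ps) < 0))

  # agrees with the classic asymptotic implementation
  x <- rnorm(60); y <- rnorm(60, 0.5)
  ks <- ks_two_sample(x, y)
  ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  expect_equal(ks$D, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ks$p_value, ref$p.value, tolerance = 1e-6)

  expect_error(ks_asymptotic_pvalue(1.2, 10, 10), "0, 1")
  expect_error(ks_asymptotic_pvalue(NA, 10, 10), "finite")
})

test_that("interaction reports compose the analyses and round-trip JSON", {
  U <- paste0("g", 1:50)
  sa <- setNames(c(rnorm(10, 3), rnorm(5)), U[1:15])
  sb <- setNames(c(-sa[1:10], rnorm(5)), c(U[1:10], U[21:25]))
  rep <- build_interaction_report(sa, sb, U)
  expect_identical(rep$n_overlap, 10L)
  expect_equal(rep$discordance$overall_discordance, 1)
  expect_identical(rep$ks$n, 10L)
  expect_identical(nrow(rep$effects), 10L)

  f <- withr::local_tempfile(fileext = ".json")
  write_interaction_report(rep, f)
  back <- read_interaction_report(f)
  expect_equal(back$enrichment$p_value, rep$enrichment$p_value,
               tolerance = 1e-12)
  expect_equal(back$ks$D, rep$ks$D, tolerance = 1e-12)
  expect_identical(back$overlap_genes, rep$overlap_genes)
  expect_equal(as.data.frame(back$effects), rep$effects)

  # tiny overlap: overlap stats only, directional components NULL
  tiny <- build_interaction_report(sa[1:2], setNames(1, names(sa)[1]), U,
                                   min_overlap = 2)
  expect_identical(tiny$n_overlap, 1L)
  expect_null(tiny$ks)
  expect_null(tiny$discordance)
})
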