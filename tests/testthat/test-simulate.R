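test_that("cohort simulation is deterministic and respects the factor model", {
  a <- small_cohort(seed = 5)
  b <- small_cohort(seed = 5)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth$module, b$truth$module)
  expect_false(identical(a$expr, small_cohort(seed = 6)$expr))

  # near-noiseless limit: hub-pair correlations approach the loading product
  low <- simulate_cohort(n_genes = 60, n_samples = 150, n_modules = 2,
                         module_size = 25, noise_sd = 1e-4, seed = 2)
  hubs <- names(low$truth$module)[low$truth$module == "M1"][1:3]
  C <- abs(cor(t(low$expr[hubs, ])))
  expect_true(all(C[upper.tri(C)] >= 0.99))

  # closed form: cor = l_i l_j / sqrt((l_i^2 + s^2)(l_j^2 + s^2))
  big <- simulate_cohort(n_genes = 30, n_samples = 4000, n_modules = 1,
                         module_size = 20, noise_sd = 1, seed = 3)
  l <- big$truth$loading
  g1 <- names(l)[1]; g2 <- names(l)[10]
  expected <- l[g1] * l[g2] / sqrt((l[g1]^2 + 1) * (l[g2]^2 + 1))
  observed <- cor(big$expr[g1, ], big$expr[g2, ])
  expect_lt(abs(unname(observed) - unname(expected)), 0.05)

  expect_error(simulate_cohort(n_genes = 10, n_modules = 3, module_size = 5),
               "infeasible")
})

test_that("within-module correlation exceeds between-module correlation", {
  ok <- vapply(1:20, function(s) {
    sim <- simulate_cohort(n_genes = 120, n_samples = 200, n_modules = 2,
                           module_size = 50, noise_sd = 1, seed = s)
    C <- abs(cor(t(sim$expr)))
    m1 <- sim$truth$module == "M1"
    m2 <- sim$truth$module == "M2"
    within <- c(C[m1, m1][upper.tri(C[m1, m1])],
                C[m2, m2][upper.tri(C[m2, m2])])
    mean(within) > mean(C[m1, m2])
  }, logical(1L))
  expect_true(all(ok))
})

test_that("external cohorts preserve or destroy modules as requested", {
  sim <- small_cohort(seed = 9)
  dens <- function(expr, genes) {
    C <- abs(cor(t(expr[genes, ])))
    mean(C[upper.tri(C)])
  }
  m1 <- names(sim$truth$module)[sim$truth$module == "M1"]

  keep <- vapply(1:10, function(s) {
    ext <- simulate_external_cohort(sim$truth, c("M1", "M2"), 80, seed = s)
    dens(ext, m1)
  }, numeric(1L))
  ref_dens <- dens(sim$expr, m1)
  expect_lt(abs(mean(keep) - ref_dens), 0.05)

  drop <- vapply(1:10, function(s) {
    ext <- simulate_external_cohort(sim$truth, character(0), 80, seed = s)
    dens(ext, m1)
  }, numeric(1L))
  expect_lt(mean(drop), 0.12)

  expect_error(simulate_external_cohort(sim$truth, "M9", 80), "unknown")
  expect_error(simulate_external_cohort(sim$truth, "M1", 0), "n_samples")
})

test_that("drug panels plant directional effects reproducibly", {
  sim <- small_cohort(seed = 4)
  drugs <- data.frame(name = c("up", "down", "null"),
                      module = c("M1", "M1", "M2"),
                      direction = c(1, -1, 1),
                      effect_size = c(2, 2, 0),
                      frac_affected = 0.8)
  panel <- simulate_drug_panel(sim$truth, drugs, seed = 11)
  aff <- attr(panel, "affected")
  expect_gt(mean(panel$up[aff$up]), 0)
  expect_lt(mean(panel$down[aff$down]), 0)
  # zero effect size behaves as pure background
  expect_lt(abs(mean(panel$null)), 0.2)
  expect_lt(abs(sd(panel$null) - 0.5), 0.1)

  again <- simulate_drug_panel(sim$truth, drugs, seed = 11)
  expect_identical(attr(again, "affected"), aff)
  expect_identical(again$up, panel$up)

  drugs$module <- "M7"
  expect_error(simulate_drug_panel(sim$truth, drugs), "unknown")
})

test_that("mixtures live on the simplex and recover the noiseless case", {
  S <- make_signature_matrix(list(A = c("g1", "g2"), B = c("g3", "g4")),
                             seed = 1)
  mix <- simulate_mixtures(S, n_samples = 50, noise_sd = 0, seed = 2)
  expect_equal(unname(rowSums(mix$proportions)), rep(1, 50),
               tolerance = 1e-9)
  expect_equal(mix$expr, S %*% t(mix$proportions), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(simulate_mixtures(S, 50, noise_sd = 0, seed = 2)$expr,
                   mix$expr)

  bad <- cbind(S, S[, 1])
  expect_error(simulate_mixtures(bad, 10), "rank deficient")
})

test_that("phenotypes are bounded fractions tracking their driver modules", {
  sim <- small_cohort(seed = 8)
  ph <- simulate_phenotype(sim$truth, "M1", beta = 1, noise_sd = 0.5,
                           seed = 1)
  expect_true(all(ph >= 0 & ph <= 1))

  quiet <- simulate_phenotype(sim$truth, "M1", beta = 1, noise_sd = 1e-8,
                              seed = 1)
  rho <- cor(quiet, sim$truth$factors["M1", ], method = "spearman")
  expect_gt(abs(rho), 0.99)

  nulls <- vapply(1:20, function(s) {
    sim200 <- simulate_cohort(n_genes = 40, n_samples = 200, n_modules = 2,
                              module_size = 15, noise_sd = 1, seed = s)
    ph0 <- simulate_phenotype(sim200$truth, character(0), beta = 0,
                              noise_sd = 0.5, seed = s + 100)
    max(abs(cor(ph0, t(sim200$truth$factors), method = "spearman")))
  }, numeric(1L))
  expect_true(all(nulls < 0.2))

  expect_error(simulate_phenotype(sim$truth, "M3"), "unknown")
})
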