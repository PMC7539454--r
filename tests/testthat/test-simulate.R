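test_that("founder sampling reproduces the requested distribution", {
  expect_equal(sample_founder(50, c(1, 0, 0), seed = 1), rep(0, 50))
  expect_equal(length(sample_founder(0, c(0.5, 0.25, 0.25))), 0)
  st <- sample_founder(100000, c(0.5, 0.25, 0.25), seed = 2)
  freq <- c(mean(st == 0), mean(st == 0.5), mean(st == 1))
  se <- sqrt(c(0.5, 0.25, 0.25) * c(0.5, 0.75, 0.75) / 100000)
  expect_true(all(abs(freq - c(0.5, 0.25, 0.25)) < 4 * se))
})

test_that("identity kernel propagates the founder unchanged", {
  ped <- two_lineage_pedigree(8)
  out <- evolve_pedigree(ped, "clonal", alpha = 0, beta = 0,
                         n_loci = 2000, founder_pi = c(0.3, 0.3, 0.4),
                         seed = 5)
  expect_equal(unname(out$S_L1_G8$states), unname(out$S_F$states))
  expect_equal(unname(out$S_L2_G8$states), unname(out$S_F$states))
})

test_that("selfing heterozygotes decay as 2^-g without epimutation", {
  n <- 100000
  g <- 4
  ped <- ma_pedigree(1, g, founder_sampled = FALSE)
  out <- evolve_pedigree(ped, "selfing", alpha = 0, beta = 0,
                         n_loci = n, founder_pi = c(0, 1, 0), seed = 31)
  het <- mean(out[[1]]$states == 0.5)
  p <- 2^-g
  expect_lt(abs(het - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("one-step transition frequencies match the kernel rows", {
  n <- 100000
  ped <- ma_pedigree(1, 1, founder_sampled = FALSE)
  G <- epi_kernel("selfing", "ABuu", 0.05, 0.1, w = 0.6)
  for (s0 in 1:3) {
    pi0 <- replace(rep(0, 3), s0, 1)
    out <- evolve_pedigree(ped, "selfing", form = "ABuu", alpha = 0.05,
                           beta = 0.1, w = 0.6, n_loci = n,
                           founder_pi = pi0, seed = 40 + s0)
    freq <- c(mean(out[[1]]$states == 0), mean(out[[1]]$states == 0.5),
              mean(out[[1]]$states == 1))
    se <- sqrt(pmax(G[s0, ] * (1 - G[s0, ]), 1e-12) / n)
    expect_true(all(abs(freq - G[s0, ]) < 4 * se + 1e-9))
  }
})

test_that("simulation is reproducible and misclassification is bounded", {
  ped <- two_lineage_pedigree(5)
  a1 <- evolve_pedigree(ped, "clonal", alpha = 1e-3, beta = 4e-3,
                        n_loci = 5000, founder_pi = c(0.6, 0.1, 0.3),
                        misclass_rate = 0.01, seed = 77)
  a2 <- evolve_pedigree(ped, "clonal", alpha = 1e-3, beta = 4e-3,
                        n_loci = 5000, founder_pi = c(0.6, 0.1, 0.3),
                        misclass_rate = 0.01, seed = 77)
  expect_identical(lapply(a1, `[[`, "states"), lapply(a2, `[[`, "states"))
})

test_that("observation noise on identical truths matches its expectation", {
  # alpha = beta = 0 clonal: both observations are independent e-flips of
  # the same truth; E[D] enumerates over the flip pattern per true state
  e <- 0.05
  n <- 120000
  pi0 <- c(0.5, 0.2, 0.3)
  ped <- two_lineage_pedigree(3)
  out <- evolve_pedigree(ped, "clonal", alpha = 0, beta = 0, n_loci = n,
                         founder_pi = pi0, misclass_rate = e, seed = 12)
  D <- pair_divergence(out$S_L1_G3, out$S_L2_G3)$D
  states <- c(0, 0.5, 1)
  exp_d <- 0
  for (s in 1:3) for (o1 in 1:3) for (o2 in 1:3) {
    p1 <- if (o1 == s) 1 - e else e / 2
    p2 <- if (o2 == s) 1 - e else e / 2
    exp_d <- exp_d + pi0[s] * p1 * p2 * abs(states[o1] - states[o2])
  }
  expect_lt(abs(D - exp_d), 4 * sqrt(exp_d * (1 - exp_d) / n))
})

test_that("the Monte-Carlo oracle reproduces the enumerated 0.375 case", {
  mc <- mc_divergence("selfing", "ABneutral", 0, 0, 1,
                      t_i = 2, t_j = 2, t_ij = 1, pi = c(0, 1, 0),
                      reps = 200000, seed = 8)
  expect_lt(abs(mc$estimate - 0.375), 3 * mc$se)
  mc0 <- mc_divergence("clonal", "ABneutral", 0, 0, 1,
                       t_i = 5, t_j = 7, t_ij = 2, pi = c(0.2, 0.5, 0.3),
                       reps = 1000, seed = 9)
  expect_equal(mc0$estimate, 0)
  expect_equal(mc0$se, 0)
})

test_that("fractional edge durations require explicit opt-in", {
  ped <- tree_pedigree(10.5, list(c(5.25), c(3)))
  expect_error(evolve_pedigree(ped, "clonal", alpha = 1e-3, beta = 1e-3,
                               n_loci = 10, founder_pi = c(1, 0, 0)),
               "fractional")
  out <- evolve_pedigree(ped, "clonal", alpha = 1e-3, beta = 1e-3,
                         n_loci = 10, founder_pi = c(1, 0, 0),
                         seed = 2, fractional = TRUE)
  expect_length(out, 2)
})

test_that("selfing divergence shows the founder-heterozygote transient", {
  # with pi2 > 0 and no epimutation, D rises with time and plateaus at the
  # analytic expectation rather than growing without bound
  pi0 <- c(0.25, 0.5, 0.25)
  d_short <- expected_divergence("selfing", "ABneutral", 0, 0, 1,
                                 t_i = 3, t_j = 3, t_ij = 1, pi = pi0)
  d_long <- expected_divergence("selfing", "ABneutral", 0, 0, 1,
                                t_i = 60, t_j = 60, t_ij = 1, pi = pi0)
  d_longer <- expected_divergence("selfing", "ABneutral", 0, 0, 1,
                                  t_i = 120, t_j = 120, t_ij = 1, pi = pi0)
  expect_gt(d_long, d_short)
  expect_equal(d_long, d_longer, tolerance = 1e-9)
  ped <- ma_pedigree(2, c(2, 40))
  out <- evolve_pedigree(ped, "selfing", alpha = 0, beta = 0,
                         n_loci = 60000, founder_pi = pi0, seed = 3)
  D40 <- pair_divergence(out$S_L1_G40, out$S_L2_G40)$D
  expect_lt(abs(D40 - expected_divergence(
    "selfing", "ABneutral", 0, 0, 1, 41, 41, 1, pi0)),
    4 * sqrt(0.25 / 60000) * 2)
})
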