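test_that("raw transition matrices match their printed entries", {
  expect_equal(unname(transition_matrix("selfing", 0, 0)),
               rbind(c(1, 0, 0), c(0.25, 0.5, 0.25), c(0, 0, 1)))
  expect_equal(unname(transition_matrix("clonal", 0, 0)), diag(3))
  expect_equal(unname(transition_matrix("selfing", 0.1, 0.2)[1, ]),
               c(0.81, 0.18, 0.01))
  expect_equal(unname(transition_matrix("clonal", 0.1, 0.2)[2, ]),
               c(0.2 * 0.9, 0.9 * 0.8 + 0.1 * 0.2, 0.1 * 0.8))
  expect_error(transition_matrix("selfing", 1.2, 0))
})

test_that("selection weight matrices take the documented forms", {
  expect_equal(unname(selection_weights("ABneutral", 1)),
               matrix(1, 3, 3))
  expect_equal(unname(selection_weights("ABnull", 0.3)), matrix(1, 3, 3))
  expect_equal(unname(selection_weights("ABmm", 0.5)[2, ]),
               c(0.5, 0.75, 1))
  expect_equal(unname(selection_weights("ABuu", 0)[1, ]), c(1, 0.5, 0))
})

test_that("kernel normalization restores row-stochasticity", {
  # neutral: normalization is a no-op
  G <- epi_kernel("clonal", "ABneutral", 0.3, 0.4)
  expect_equal(unname(G), unname(transition_matrix("clonal", 0.3, 0.4)))
  # hand-normalized heterozygote row under lethal selection against m:
  # raw (1/4, 1/2, 1/4) o (1, 1/2, 0) = (1/4, 1/4, 0) -> (1/2, 1/2, 0)
  raw <- transition_matrix("selfing", 0, 0) * selection_weights("ABuu", 0)
  expect_equal(unname(raw[2, ] / sum(raw[2, ])), c(0.5, 0.5, 0))
  # but the full kernel is degenerate there: the m/m row is annihilated
  expect_error(epi_kernel("selfing", "ABuu", 0, 0, w = 0), "annihilate")
  set.seed(7)
  for (r in 1:50) {
    cfg <- random_kernel_config()
    G3 <- epi_kernel(cfg$system, cfg$form, cfg$alpha, cfg$beta, cfg$w)
    expect_equal(unname(rowSums(G3)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(G3 >= 0))
  }
})

test_that("eigendecomposition powers agree with repeated multiplication", {
  set.seed(11)
  for (r in 1:25) {
    cfg <- random_kernel_config()
    G <- epi_kernel(cfg$system, cfg$form, cfg$alpha, cfg$beta, cfg$w)
    P5 <- kernel_power(G, 5)
    expect_equal(P5, G %*% G %*% G %*% G %*% G, tolerance = 1e-10)
    expect_equal(unname(kernel_power(G, 0)), diag(3))
    # semigroup property with fractional exponents
    H <- kernel_power(G, 0.5)
    expect_equal(H %*% H, kernel_power(G, 1), tolerance = 1e-8)
  }
  expect_error(kernel_power(diag(3), -1))
})

test_that("nearly defective kernels fall back to exact multiplication", {
  Gdef <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5), c(0, 0, 1))  # defective
  expect_equal(kernel_power(Gdef, 3), Gdef %*% Gdef %*% Gdef,
               tolerance = 1e-10)
})

test_that("founder distribution splits observed-methylated mass by gamma", {
  expect_equal(unname(founder_distribution(0.6, 0.4, 0.25)),
               c(0.6, 0.1, 0.3))
  expect_equal(unname(founder_distribution(0.6, 0.4, 0)), c(0.6, 0, 0.4))
  expect_equal(unname(founder_distribution(0.6, 0.4, 1)), c(0.6, 0.4, 0))
  # residual (observed-intermediate) mass goes to the heterozygote class
  expect_equal(unname(founder_distribution(0.5, 0.3, 0.5)),
               c(0.5, 0.2 + 0.15, 0.15))
  expect_error(founder_distribution(0.8, 0.4, 0.5), "exceeds 1")
})

test_that("expected divergence reproduces enumerable limits", {
  # identity kernel: descendants identical, divergence zero
  expect_equal(expected_divergence("clonal", "ABneutral", 0, 0, 1,
                                   t_i = 9, t_j = 5, t_ij = 2,
                                   pi = c(0.2, 0.3, 0.5)), 0)
  # founder heterozygote segregating once down each branch:
  # offspring law (1/4, 1/2, 1/4) for both, E[I] enumerates to 0.375
  expect_equal(expected_divergence("selfing", "ABneutral", 0, 0, 1,
                                   t_i = 2, t_j = 2, t_ij = 1,
                                   pi = c(0, 1, 0)), 0.375)
  # long-time selfing limit: independent absorption into u/u or m/m
  expect_equal(expected_divergence("selfing", "ABneutral", 0, 0, 1,
                                   t_i = 200, t_j = 200, t_ij = 1,
                                   pi = c(0, 1, 0)), 0.5, tolerance = 1e-9)
  expect_error(expected_divergence("clonal", "ABneutral", 1e-3, 1e-3, 1,
                                   t_i = 3, t_j = 3, t_ij = 0.5,
                                   pi = c(1, 0, 0)))
})

test_that("equilibrium closed forms match the stationary eigenvector", {
  expect_equal(equilibrium_uu("clonal", "ABneutral", 0.2, 0.6), 0.5625)
  expect_equal(equilibrium_uu("clonal", "ABneutral", 0.1, 0.1), 0.25)
  set.seed(13)
  for (r in 1:20) {
    a <- runif(1, 1e-4, 0.9); b <- runif(1, 1e-4, 0.9)
    for (sys in c("selfing", "clonal")) {
      closed <- equilibrium_uu(sys, "ABneutral", a, b)
      expect_equal(closed, unname(stationary_distribution(
        sys, "ABneutral", a, b)[1]), tolerance = 1e-8)
    }
  }
  expect_error(equilibrium_uu("clonal", "ABneutral", 0, 0), "undefined")
})

test_that("compiled backend agrees with the pure-R model functions", {
  set.seed(17)
  sys_code <- c(selfing = 1, clonal = 2)
  frm_code <- c(ABneutral = 1, ABmm = 2, ABuu = 3, ABnull = 4)
  for (r in 1:20) {
    cfg <- random_kernel_config()
    a <- runif(1, 1e-5, 0.05); b <- runif(1, 1e-5, 0.05)
    g <- runif(1)
    G_r <- epi_kernel(cfg$system, cfg$form, a, b, cfg$w)
    G_c <- epiclock:::cpp_kernel(sys_code[[cfg$system]],
                                 frm_code[[cfg$form]], a, b, cfg$w)
    expect_equal(unname(G_r), G_c, tolerance = 1e-12)

    p1 <- runif(1, 0.2, 0.7); p3 <- runif(1, 0, 1 - p1)
    pi <- founder_distribution(p1, p3, g)
    tij <- sample(1:5, 1); ti <- tij + sample(0:20, 1)
    tj <- tij + sample(0:20, 1)
    d_r <- expected_divergence(cfg$system, cfg$form, a, b, cfg$w,
                               ti, tj, tij, pi)
    d_c <- epiclock:::cpp_pred_d(sys_code[[cfg$system]],
                                 frm_code[[cfg$form]], a, b, cfg$w, g,
                                 p1, p3, matrix(c(tij, ti, tj), 1))
    expect_equal(d_r, as.numeric(d_c), tolerance = 1e-10)

    eq_r <- equilibrium_uu(cfg$system, cfg$form, a, b, cfg$w)
    eq_c <- epiclock:::cpp_equilibrium_uu(sys_code[[cfg$system]],
                                          frm_code[[cfg$form]], a, b,
                                          cfg$w)
    expect_equal(eq_r, eq_c, tolerance = 1e-8)
  }
})
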