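# shared fixtures: all synthetic, built in code at test time

# methylome with loci chr1:1..n from a plain state vector
mk_methylome <- function(id, states) {
  n <- length(states)
  methylome(id, data.frame(seqname = rep("chr1", n),
                           position = seq_len(n),
                           strand = rep("+", n),
                           context = rep("CG", n)), states)
}

# single founder -> two lineages, both sampled at generation g
two_lineage_pedigree <- function(g = 10, founder_sampled = TRUE) {
  ma_pedigree(2, g, founder_sampled = founder_sampled)
}

# noise-free divergence dataset generated from the analytic model
analytic_dataset <- function(system, alpha, beta, w = 1, gamma = 0,
                             c = 0.01, t_j = seq(4, 31, 3),
                             p1 = 0.7, p3 = 0.3,
                             form = "ABneutral") {
  tm <- data.frame(sample_i = "a", sample_j = sprintf("b%02d",
                                                      seq_along(t_j)),
                   t_i = 1, t_j = t_j, t_ij = 1)
  tm$delta_t <- (tm$t_i - tm$t_ij) + (tm$t_j - tm$t_ij)
  pi <- founder_distribution(p1, p3, gamma)
  tm$D <- c + vapply(seq_len(nrow(tm)), function(q)
    expected_divergence(system, form, alpha, beta, w,
                        tm$t_i[q], tm$t_j[q], tm$t_ij[q], pi), numeric(1))
  divergence_data(tm, p1, p3,
                  p_bar_1 = equilibrium_uu(system, form, alpha, beta, w))
}

# random valid kernel configurations for property-style loops; rates are
# kept below 0.45 each so the kernel spectrum stays positive (fractional
# matrix powers are real only on that regime, which is also the
# biologically relevant one)
random_kernel_config <- function() {
  sys <- sample(c("selfing", "clonal"), 1)
  frm <- sample(c("ABneutral", "ABmm", "ABuu"), 1)
  w <- if (frm == "ABneutral") 1 else runif(1, 0.2, 1)
  list(system = sys, form = frm,
       alpha = runif(1, 0, 0.45), beta = runif(1, 0, 0.45), w = w)
}
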