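#' Raw epigenotype transition matrix
#'
#' One-time-unit transition probabilities between the diploid epigenotypes
#' (u/u, m/u, m/m), before any selection weighting.  `alpha` is the
#' per-allele probability of a stochastic methylation gain (u to m) within
#' one time unit, `beta` the per-allele loss probability (m to u).  For a
#' selfing system the epiheterozygote row combines the allele-switch
#' probabilities with Mendelian segregation (at `alpha = beta = 0` it is
#' exactly (1/4, 1/2, 1/4)); for a clonal/somatic system the two alleles
#' switch independently and the matrix reduces to the identity at
#' `alpha = beta = 0`.
#'
#' @param system `"selfing"` or `"clonal"`.
#' @param alpha,beta gain and loss probabilities in `[0, 1]`.
#' @return A row-stochastic 3x3 matrix with rows/columns in state order
#'   (u/u, m/u, m/m).
#' @export
transition_matrix <- function(system = c("selfing", "clonal"), alpha, beta) {
  system <- match.arg(system)
  stopifnot(alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  a <- alpha; b <- beta
  mid <- if (system == "selfing") {
    c(0.25 * (b + 1 - a)^2,
      0.50 * (b + 1 - a) * (a + 1 - b),
      0.25 * (a + 1 - b)^2)
  } else {
    c(b * (1 - a), (1 - a) * (1 - b) + a * b, a * (1 - b))
  }
  G <- rbind(c((1 - a)^2, 2 * (1 - a) * a, a^2),
             mid,
             c(b^2, 2 * (1 - b) * b, (1 - b)^2))
  dimnames(G) <- list(c("u/u", "m/u", "m/m"), c("u/u", "m/u", "m/m"))
  G
}

#' Selection weight matrix
#'
#' Fitness weights applied (Hadamard product) to the raw transition matrix.
#' Under `ABmm` selection acts against the u epiallele: transitions into
#' u/u are weighted by `w` and into m/u by `(w+1)/2`.  Under `ABuu`
#' selection acts against m, mirroring the columns.  The neutral forms
#' (`ABneutral`, `ABnull`) give an all-ones matrix.
#'
#' @param form one of `"ABneutral"`, `"ABmm"`, `"ABuu"`, `"ABnull"`.
#' @param w selection coefficient in `[0, 1]` (`w = 1` is neutral).
#' @return A 3x3 matrix of weights.
#' @export
selection_weights <- function(form = c("ABneutral", "ABmm", "ABuu", "ABnull"),
                              w = 1) {
  form <- match.arg(form)
  stopifnot(w >= 0, w <= 1)
  cols <- switch(form,
                 ABmm = c(w, (w + 1) / 2, 1),
                 ABuu = c(1, (w + 1) / 2, w),
                 c(1, 1, 1))
  W <- matrix(cols, nrow = 3, ncol = 3, byrow = TRUE)
  dimnames(W) <- list(c("u/u", "m/u", "m/m"), c("u/u", "m/u", "m/m"))
  W
}

#' Normalized (selection-weighted) transition kernel
#'
#' The selection-weighted kernel `G' = diag(rowSums(G o W))^-1 (G o W)`,
#' renormalized so each row is again a probability distribution.  With
#' `w = 1` this equals the raw matrix.
#'
#' @inheritParams transition_matrix
#' @inheritParams selection_weights
#' @return A row-stochastic 3x3 matrix.
#' @export
epi_kernel <- function(system = c("selfing", "clonal"),
                       form = c("ABneutral", "ABmm", "ABuu", "ABnull"),
                       alpha, beta, w = 1) {
  G <- transition_matrix(system, alpha, beta) * selection_weights(form, w)
  rs <- rowSums(G)
  if (any(rs <= 0))
    stop("selection weights annihilate a whole kernel row")
  G / rs
}

#' Matrix power of a transition kernel for (possibly fractional) time
#'
#' Computes `G^tau` by eigendecomposition (`G = P V P^-1`, so
#' `G^tau = P V^tau P^-1`), which extends the repeated-multiplication
#' semantics to non-integer exponents (tree ages in years, profiled founder
#' ages).  Tiny imaginary parts arising from numerically complex eigenpairs
#' are clamped to real.  If the eigenvector matrix is ill-conditioned
#' (nearly defective kernel), integer exponents fall back to exact repeated
#' multiplication and fractional exponents to the matrix exponential of
#' `tau * logm(G)`.
#'
#' @param G a square (row-stochastic) matrix.
#' @param tau non-negative exponent.
#' @return The matrix power `G^tau`.
#' @export
kernel_power <- function(G, tau) {
  stopifnot(is.matrix(G), nrow(G) == ncol(G), tau >= 0)
  dn <- dimnames(G)
  if (tau == 0) {
    out <- diag(nrow(G))
  } else {
    e <- eigen(G)
    P <- e$vectors
    rc <- tryCatch(rcond(P), error = function(err) 0)
    if (is.finite(rc) && rc > 1e-12) {
      out <- P %*% diag(as.complex(e$values)^tau, nrow(G)) %*% solve(P)
      if (max(abs(Im(out))) > 1e-9)
        warning("large imaginary component in matrix power; clamped to real")
      out <- Re(out)
    } else if (abs(tau - round(tau)) < 1e-9) {
      out <- diag(nrow(G))
      for (k in seq_len(round(tau))) out <- out %*% G
    } else {
      out <- Re(pracma::expm(tau * pracma::logm(G)))
    }
  }
  dimnames(out) <- dn
  out
}

#' Founder epigenotype distribution
#'
#' Most methylation-status callers emit only binary (U/M) calls, so the
#' founder's epiheterozygote fraction is not directly observed.  The
#' founder distribution over (u/u, m/u, m/m) is therefore built as
#' `pi = (p1_obs, gamma * p3_obs, (1 - gamma) * p3_obs)`: the parameter
#' `gamma` is the fraction of loci *observed* as methylated that are in
#' truth epiheterozygous.  If the caller did emit intermediate states
#' (`p1_obs + p3_obs < 1`), that residual mass is assigned directly to the
#' heterozygote class, and `gamma` still splits only the
#' observed-methylated mass.
#'
#' @param p1_obs,p3_obs observed founder proportions of u/u and m/m loci.
#' @param gamma epiheterozygosity split in `[0, 1]`.
#' @return Probability 3-vector over (u/u, m/u, m/m).
#' @export
founder_distribution <- function(p1_obs, p3_obs, gamma) {
  stopifnot(p1_obs >= 0, p1_obs <= 1, p3_obs >= 0, p3_obs <= 1,
            gamma >= 0, gamma <= 1)
  if (p1_obs + p3_obs > 1 + 1e-9)
    stop("p1_obs + p3_obs exceeds 1")
  if (p1_obs + p3_obs <= 0)
    stop("founder state proportions sum to zero")
  resid2 <- max(1 - p1_obs - p3_obs, 0)
  pi <- c(p1_obs, resid2 + gamma * p3_obs, (1 - gamma) * p3_obs)
  if (abs(sum(pi) - 1) > 1e-6)
    stop("founder distribution failed to normalize")
  pi <- pi / sum(pi)
  stats::setNames(pi, c("u/u", "m/u", "m/m"))
}

#' Expected methylome divergence between two samples under the model
#'
#' The model-implied counterpart of the observed divergence: with ancestor
#' state distribution `pi G'^(t_ij - 1)` at the most recent common
#' ancestor, the two descendant lineages evolve conditionally independently
#' through `G'^(t_i - t_ij)` and `G'^(t_j - t_ij)`, and the divergence is
#' the expectation of the state indicator over the joint descendant states:
#' \deqn{D^\ast = \sum_n [\pi G'^{t_{ij}-1}]_n \sum_{l,m} I(l,m)\,
#'   (G'^{t_i - t_{ij}})_{nl} (G'^{t_j - t_{ij}})_{nm}.}
#' Times are on the internal scale with the founder at 1.
#'
#' @inheritParams epi_kernel
#' @param t_i,t_j sample times; `t_ij` MRCA time (all `>= 1`,
#'   `t_ij <= min(t_i, t_j)`).
#' @param pi founder distribution (see [founder_distribution()]).
#' @return Expected divergence in `[0, 1]`.
#' @export
expected_divergence <- function(system, form, alpha, beta, w = 1,
                                t_i, t_j, t_ij, pi) {
  stopifnot(t_ij >= 1 - 1e-9, t_i >= t_ij - 1e-9, t_j >= t_ij - 1e-9,
            length(pi) == 3, all(pi >= 0), abs(sum(pi) - 1) < 1e-6)
  G <- epi_kernel(system, form, alpha, beta, w)
  IND <- abs(outer(c(0, 0.5, 1), c(0, 0.5, 1), "-"))
  anc <- as.numeric(pi %*% kernel_power(G, t_ij - 1))
  A <- kernel_power(G, t_i - t_ij)
  B <- kernel_power(G, t_j - t_ij)
  sum(anc * rowSums((A %*% IND) * B))
}

#' Stationary epigenotype distribution of a kernel
#'
#' The long-run distribution over (u/u, m/u, m/m) under the kernel,
#' computed as the dominant left eigenvector of `G'` normalized to unit
#' sum.  Useful e.g. as a realistic founder distribution when simulating
#' methylomes assumed to be at mutation-selection balance.
#'
#' @inheritParams epi_kernel
#' @return Probability 3-vector over (u/u, m/u, m/m).
#' @export
stationary_distribution <- function(system, form = "ABneutral",
                                    alpha, beta, w = 1) {
  if (alpha + beta <= 0)
    stop("stationary distribution undefined for alpha = beta = 0")
  G <- epi_kernel(system, form, alpha, beta, w)
  e <- eigen(t(G))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  stats::setNames(v / sum(v), c("u/u", "m/u", "m/m"))
}

#' Equilibrium proportion of u/u loci
#'
#' The stationary (t to infinity) fraction of unmethylated-homozygote loci
#' under the kernel.  For neutral kernels (`w = 1`) the closed forms are
#' used: `beta^2 / (alpha + beta)^2` for clonal systems and
#' `beta ((1-beta)^2 - (1-alpha)^2 - 1) /
#'  ((alpha+beta)((alpha+beta-1)^2 - 2))` for selfing.  Under selection
#' (`w < 1`) no closed form is available and the u/u component of the
#' dominant left eigenvector of `G'` is returned.
#'
#' @inheritParams epi_kernel
#' @return The equilibrium u/u proportion.
#' @export
equilibrium_uu <- function(system = c("selfing", "clonal"),
                           form = c("ABneutral", "ABmm", "ABuu", "ABnull"),
                           alpha, beta, w = 1) {
  system <- match.arg(system)
  form <- match.arg(form)
  if (alpha + beta <= 0)
    stop("equilibrium undefined for alpha = beta = 0")
  if (w == 1 || form %in% c("ABneutral", "ABnull")) {
    if (system == "clonal") return(beta^2 / (alpha + beta)^2)
    return(beta * ((1 - beta)^2 - (1 - alpha)^2 - 1) /
             ((alpha + beta) * ((alpha + beta - 1)^2 - 2)))
  }
  G <- epi_kernel(system, form, alpha, beta, w)
  e <- eigen(t(G))
  v <- abs(Re(e$vectors[, which.max(Re(e$values))]))
  (v / sum(v))[1]
}
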