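# Many-to-one (Dunnett) multiplicity adjustment for a balanced design under
# compound symmetry.  With k treatment conditions compared against one
# control on n subjects, the test statistics T_j = (m_j - m_0)/sqrt(2 MSE/n)
# are jointly multivariate t with equicorrelation 1/2 and the error df of
# the within-subject ANOVA.  Writing T_j = (Z_j - Z_0)/(S sqrt(2)) with iid
# standard normal Z and S^2 ~ chi^2_df/df gives
#   P(max_j |T_j| <= c) = E_{Z_0,S} [ Phi(Z_0 + sqrt(2) c S)
#                                    - Phi(Z_0 - sqrt(2) c S) ]^k,
# a smooth 2-D integral evaluated here by Gauss-Legendre quadrature.
# mvtnorm::pmvt computes the same probability by quasi-Monte Carlo and is
# used as an independent cross-check in the tests.

.dunnett_nodes <- function(n_nodes, df) {
  gz <- pracma::gaussLegendre(n_nodes, -8.5, 8.5)
  gu <- pracma::gaussLegendre(n_nodes, 1e-10, 1 - 1e-10)
  s <- sqrt(stats::qchisq(gu$x, df) / df)
  list(z = gz$x, wz = gz$w * stats::dnorm(gz$x), s = s, ws = gu$w)
}

#' Family-wise probability for many-to-one comparisons
#'
#' `dunnett_prob(crit, k, df)` returns `P(max_j |T_j| <= crit)` for `k`
#' equicorrelated (rho = 1/2) many-to-one t statistics with `df` error
#' degrees of freedom — the two-sided Dunnett acceptance probability for a
#' balanced design.  `dunnett_pvalue(t, k, df)` is the corresponding
#' single-step adjusted p-value, `1 - P(max |T| <= |t|)`.
#'
#' @param crit,t Statistic value(s); vectorised.
#' @param k Number of comparisons against the control, >= 1.
#' @param df Error degrees of freedom, > 0.
#' @param n_nodes Quadrature nodes per dimension.  Default 64.
#' @return Probabilities in `[0, 1]`.
#' @export
dunnett_prob <- function(crit, k, df, n_nodes = 64) {
  stopifnot(k >= 1, df > 0)
  nd <- .dunnett_nodes(n_nodes, df)
  out <- numeric(length(crit))
  # chunk over crit to bound the (n_crit x n_nodes) working matrices
  chunk <- max(1L, floor(2e6 / n_nodes))
  for (lo in seq(1L, length(crit), by = chunk)) {
    hi <- min(lo + chunk - 1L, length(crit))
    cc <- crit[lo:hi]
    acc <- matrix(0, nrow = length(cc), ncol = n_nodes)  # crit x z
    for (j in seq_len(n_nodes)) {                        # over S nodes
      half_width <- sqrt(2) * cc * nd$s[j]
      upper <- outer(half_width, nd$z, function(a, z) z + a)
      lower <- outer(half_width, nd$z, function(a, z) z - a)
      acc <- acc + nd$ws[j] * (stats::pnorm(upper) - stats::pnorm(lower))^k
    }
    out[lo:hi] <- pmin(1, pmax(0, as.vector(acc %*% nd$wz)))
  }
  out
}

#' @rdname dunnett_prob
#' @export
dunnett_pvalue <- function(t, k, df, n_nodes = 64) {
  1 - dunnett_prob(abs(t), k, df, n_nodes = n_nodes)
}

#' Two-sided Dunnett critical value
#'
#' Solves `P(max_j |T_j| <= c) = 1 - alpha` for `c`.
#'
#' @param alpha Family-wise error rate, in (0, 1).
#' @inheritParams dunnett_prob
#' @return The critical value `c`.
#' @export
dunnett_critical <- function(alpha, k, df, n_nodes = 64) {
  stopifnot(alpha > 0, alpha < 1)
  stats::uniroot(function(c) dunnett_prob(c, k, df, n_nodes) - (1 - alpha),
                 interval = c(0.5, 12), tol = 1e-7)$root
}
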