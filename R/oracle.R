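#' @name oracle
#' @title Independent beta-binomial oracle for the Bayes factor
#'
#' @description
#' A second, independent derivation of both marginal likelihoods so the
#' closed-form [log_bayes_factor()] can be *verified* rather than trusted.
#' Under H0 the two rows share one success probability with a uniform prior,
#' so the marginal likelihood is a single beta-binomial integral; under H1
#' the intrinsic prior is a finite Beta mixture, so the marginal likelihood
#' is the weighted sum of products of per-row beta-binomial integrals,
#' `int Bin(z|n,p) Beta(p|a,b) dp = C(n,z) B(z+a, n-z+b) / B(a,b)`.
#' The oracle log Bayes factor is their difference. A third route — direct
#' numerical quadrature of the integrands — guards against an algebra slip
#' shared between the closed form and the oracle.
#'
#' These functions are shipped (not test-only) so any reported value can be
#' audited at small scale; their cost grows with `(t1+1)(t2+1)` and the
#' quadrature versions are for small counts only.
#'
#' @param z1,z2 Reference-column counts (`0 <= z_i <= n_i`).
#' @param n1,n2 Fixed row margins, `>= 1`.
#' @param t1,t2 Non-negative integer concentration parameters.
NULL

check_rc <- function(z1, z2, n1, n2) {
  assert_count(n1, "n1", min = 1); assert_count(n2, "n2", min = 1)
  assert_count(z1, "z1"); assert_count(z2, "z2")
  if (z1 > n1 || z2 > n2) stop("row counts must satisfy z_i <= n_i", call. = FALSE)
}

#' @rdname oracle
#' @return `oracle_log_m0()`: log marginal likelihood of (z1, z2) under H0,
#'   `log[C(n1,z1) C(n2,z2) B(z1+z2+1, n1+n2-z1-z2+1)]`.
#' @export
oracle_log_m0 <- function(z1, z2, n1, n2) {
  check_rc(z1, z2, n1, n2)
  lchoose(n1, z1) + lchoose(n2, z2) + lbeta(z1 + z2 + 1, n1 + n2 - z1 - z2 + 1)
}

#' @rdname oracle
#' @return `oracle_log_m1()`: log marginal likelihood under H1 with the
#'   intrinsic prior at concentration (t1, t2).
#' @export
oracle_log_m1 <- function(z1, z2, n1, n2, t1, t2) {
  check_rc(z1, z2, n1, n2)
  assert_count(t1, "t1"); assert_count(t2, "t2")
  i <- 0:t1; j <- 0:t2
  lw <- outer(lchoose(t1, i), lchoose(t2, j), `+`) +
    outer(i, j, function(a, b) lgamma(a + b + 1) + lgamma(t1 + t2 - a - b + 1)) -
    lgamma(t1 + t2 + 2)
  l1 <- lchoose(n1, z1) + lbeta(z1 + i + 1, n1 - z1 + t1 - i + 1) -
    lbeta(i + 1, t1 - i + 1)
  l2 <- lchoose(n2, z2) + lbeta(z2 + j + 1, n2 - z2 + t2 - j + 1) -
    lbeta(j + 1, t2 - j + 1)
  logsumexp(lw + outer(l1, l2, `+`))
}

#' @rdname oracle
#' @return `oracle_log_b10()`: `oracle_log_m1 - oracle_log_m0`, the
#'   independently derived log Bayes factor.
#' @export
oracle_log_b10 <- function(z1, z2, n1, n2, t1, t2) {
  oracle_log_m1(z1, z2, n1, n2, t1, t2) - oracle_log_m0(z1, z2, n1, n2)
}

#' @rdname oracle
#' @return `oracle_quad_log_m0()`: H0 marginal by adaptive 1-D quadrature of
#'   `int Bin(z1|n1,p) Bin(z2|n2,p) dp` (absolute tolerance 1e-10).
#' @export
oracle_quad_log_m0 <- function(z1, z2, n1, n2) {
  check_rc(z1, z2, n1, n2)
  v <- stats::integrate(function(p) stats::dbinom(z1, n1, p) * stats::dbinom(z2, n2, p),
                        0, 1, rel.tol = 1e-12, abs.tol = 1e-10)
  log(v$value)
}

#' @rdname oracle
#' @return `oracle_quad_log_m1()`: H1 marginal by nested adaptive quadrature
#'   of the intrinsic-prior-weighted integrand over the unit square; small
#'   counts and concentrations only.
#' @export
oracle_quad_log_m1 <- function(z1, z2, n1, n2, t1, t2) {
  check_rc(z1, z2, n1, n2)
  inner <- function(p1) {
    vapply(p1, function(u) {
      stats::integrate(function(p2) {
        d <- vapply(p2, function(v)
          exp(intrinsic_prior_log_density(u, v, t1, t2)), numeric(1))
        stats::dbinom(z1, n1, u) * stats::dbinom(z2, n2, p2) * d
      }, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
    }, numeric(1))
  }
  v <- stats::integrate(inner, 0, 1, rel.tol = 1e-10, abs.tol = 1e-12)
  log(v$value)
}
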