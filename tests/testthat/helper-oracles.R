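## Independent oracles used to cross-check the package implementations.
## These deliberately avoid the code paths they verify: the mixed-model
## oracle maximizes the REML criterion with dense linear algebra and a
## generic optimizer, the Spearman and FDR oracles evaluate the textbook
## definitions directly.

## Brute-force REML fit of y = b0 + lambda*tau + b_case + eps on a small
## long-format data set (two rows per case). Returns the GLS fixed
## effects at the REML-optimal variance components.
bruteForceREML <- function(dat) {
  X <- cbind(1, dat$tau)
  y <- dat$y
  n <- length(y)
  Z <- outer(dat$case, levels(dat$case), `==`) * 1
  gls <- function(V) {
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    A <- XtVi %*% X
    beta <- solve(A, XtVi %*% y)
    r <- y - X %*% beta
    list(beta = beta, A = A,
         crit = as.numeric(determinant(V)$modulus +
                           determinant(A)$modulus +
                           t(r) %*% Vi %*% r))
  }
  obj <- function(par) {
    V <- exp(par[1]) * tcrossprod(Z) + exp(par[2]) * diag(n)
    gls(V)$crit
  }
  opt <- optim(c(0, -1), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  V <- exp(opt$par[1]) * tcrossprod(Z) + exp(opt$par[2]) * diag(n)
  fit <- gls(V)
  list(beta0 = fit$beta[1], lambda = fit$beta[2],
       sigma_case = sqrt(exp(opt$par[1])), sigma_resid = sqrt(exp(opt$par[2])))
}

## Textbook Spearman rho: 1 - 6*sum(d^2)/(n(n^2-1)), valid without ties.
bruteSpearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

## Benjamini-Hochberg step-up from the definition:
## q(i) = min_{j >= i} m*p(j)/j in sorted order, capped at 1.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

## Minimal model-ready record table (what fitLambda and friends need).
makeRecords <- function(caseId, cT1, cT2, deltaTH) {
  S4Vectors::DataFrame(case_id = caseId, c_t1 = cT1, c_t2 = cT2,
                       delta_t_h = deltaTH)
}

## Noise-controlled synthetic records without going through the cohort
## simulator: log c1 = b_i, log c2 = b_i + lambda_i*dt_i + noise.
makeLambdaRecords <- function(n, lambda, dtH = NULL, sigmaB = 1,
                              sigmaE = 0, lambdaSd = 0) {
  if (is.null(dtH)) dtH <- stats::runif(n, 20, 150)
  b <- stats::rnorm(n, 0, sigmaB)
  li <- stats::rnorm(n, lambda, lambdaSd)
  c1 <- exp(b + stats::rnorm(n, 0, sigmaE))
  c2 <- exp(b + li * dtH + stats::rnorm(n, 0, sigmaE))
  makeRecords(sprintf("c%03d", seq_len(n)), c1, c2, -dtH)
}
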