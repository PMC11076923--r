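# Independent oracles used across the test files. Everything here is
# deliberately written with a different algorithm than the package code it
# checks: dense matrix algebra instead of lm/sandwich, Newton iteration on
# the analytic probit score instead of proximal gradient, and quadrature
# instead of closed forms.

# ---- brute-force weighted least squares + HC1 sandwich ----------------------
# slope and sandwich SEs of y ~ x with weights w, from first principles:
# beta = (X'WX)^-1 X'Wy,  V = (X'WX)^-1 (sum w_i^2 e_i^2 x_i x_i') (X'WX)^-1
# scaled by n/(n-2) for HC1.
oracle_wls_hc1 <- function(y, x, w = NULL, hc = "HC1") {
  n <- length(y)
  if (is.null(w)) w <- rep(1, n)
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  beta <- solve(XtWX, t(X) %*% (w * y))
  e <- y - X %*% beta
  meat <- t(X) %*% ((w^2 * as.numeric(e)^2) * X)
  V <- solve(XtWX, t(solve(XtWX, t(meat))))
  if (hc == "HC1") V <- V * n / (n - 2)
  list(beta = as.numeric(beta), se = unname(sqrt(diag(V))))
}

# ---- Newton maximum-likelihood probit ---------------------------------------
# unpenalized probit MLE on a dense design, by Newton-Raphson on the
# analytic score/Hessian. Used as the lambda = 0 oracle.
oracle_probit_mle <- function(X, s, max_iter = 200, tol = 1e-12) {
  X <- cbind("(Intercept)" = 1, as.matrix(X))
  beta <- numeric(ncol(X))
  beta[1] <- qnorm(mean(s))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    lam1 <- exp(dnorm(eta, log = TRUE) - pnorm(eta, log.p = TRUE))
    lam0 <- exp(dnorm(eta, log = TRUE) - pnorm(-eta, log.p = TRUE))
    score <- as.numeric(t(X) %*% ifelse(s == 1, lam1, -lam0))
    wdiag <- ifelse(s == 1, lam1 * (lam1 + eta), lam0 * (lam0 - eta))
    H <- t(X) %*% (wdiag * X)
    step <- solve(H, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# ---- bivariate normal orthant probability by nested 1-D quadrature ----------
# P(Z1 > a, Z2 > b) with corr(Z1, Z2) = rho, via
# integral over z1 > a of phi(z1) * P(Z2 > b | z1) dz1.
oracle_orthant_prob <- function(a, b, rho) {
  f <- function(z) dnorm(z) * pnorm((b - rho * z) / sqrt(1 - rho^2),
                                    lower.tail = FALSE)
  integrate(f, lower = a, upper = Inf, rel.tol = 1e-10)$value
}

# ---- truncated bivariate normal moments by 2-D quadrature -------------------
# E-, second-moment and covariance of (V, W) jointly normal with covariance
# S (2x2, means zero), conditional on T > c where T = lv' (V,W) + e,
# e ~ N(0, se2). Implemented by integrating over the latent index instead:
# (V, W, T) are jointly normal, so condition numerically on T > c.
oracle_truncated_cov <- function(S_full, c_cut) {
  # S_full: 3x3 covariance of (V, W, T); returns Cov(V, W | T > c).
  sdT <- sqrt(S_full[3, 3])
  pT <- pnorm(c_cut / sdT, lower.tail = FALSE)
  m1 <- function(i) {                 # E[V_i | T > c]
    bi <- S_full[i, 3] / S_full[3, 3] # regression of V_i on T
    g <- function(t) bi * t * dnorm(t, sd = sdT)
    integrate(g, c_cut, Inf, rel.tol = 1e-10)$value / pT
  }
  m2 <- function(i, j) {              # E[V_i V_j | T > c]
    bi <- S_full[i, 3] / S_full[3, 3]
    bj <- S_full[j, 3] / S_full[3, 3]
    resid_cov <- S_full[i, j] - bi * bj * S_full[3, 3]
    g <- function(t) (resid_cov + bi * bj * t^2) * dnorm(t, sd = sdT)
    integrate(g, c_cut, Inf, rel.tol = 1e-10)$value / pT
  }
  m2(1, 2) - m1(1) * m1(2)
}

# ---- standard normal CDF via the error function -----------------------------
# an independent route to Phi(x) for the Z-statistic oracle (pracma::erf).
oracle_phi <- function(x) 0.5 * (1 + pracma::erf(x / sqrt(2)))

# ---- small test fixtures ----------------------------------------------------
tiny_codebook <- function() {
  codebook(list(
    cb_variable("health", c("good", "fair", "poor"),
                numeric = c(good = 1, fair = 2, poor = 3)),
    cb_variable("work", c("yes", "no"))))
}

# a random codebook with k variables of random level counts (for the
# combinatorial column-count invariant)
random_codebook <- function(k, max_levels = 4L) {
  vars <- lapply(seq_len(k), function(i) {
    L <- sample(2:max_levels, 1L)
    cb_variable(paste0("v", i), paste0("l", seq_len(L)))
  })
  codebook(vars)
}

# random person table over a codebook's levels
random_table <- function(cb, n) {
  out <- data.frame(person_id = as.character(seq_len(n)),
                    stringsAsFactors = FALSE)
  for (v in cb$variables) {
    out[[v$name]] <- sample(v$levels, n, replace = TRUE)
  }
  out
}
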