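# L1-penalized probit participation model.
#
# The participation decision is modelled as membership in the cohort (1)
# versus the representative reference sample (0) on concatenated data.
# The negative average log-likelihood
#   f(b0, b) = -(1/N) sum_i [ s_i log Phi(eta_i) + (1-s_i) log Phi(-eta_i) ]
# is minimized plus lambda * ||b||_1 (intercept unpenalized) by an
# accelerated proximal-gradient method (FISTA) with backtracking line
# search and adaptive restart, wrapped in an active-set outer loop: the
# subproblem is solved on the working set of columns, then the full KKT
# conditions are checked and violating columns are added until none
# remain. For the probit likelihood the per-observation curvature in eta
# is bounded by 1, so ||X||_2^2 / N bounds the Lipschitz constant of the
# smooth part; backtracking is a safety net only.

# value and eta-gradient of the smooth part, numerically stable in the tails
.probit_nll <- function(eta, s) {
  lp <- stats::pnorm(eta, log.p = TRUE)
  lq <- stats::pnorm(-eta, log.p = TRUE)
  -mean(ifelse(s == 1, lp, lq))
}

.probit_eta_grad <- function(eta, s) {
  # d/d eta of the per-observation NLL (before the 1/N factor)
  r <- numeric(length(eta))
  pos <- s == 1
  r[pos] <- -.mills(eta[pos])
  r[!pos] <- .mills(-eta[!pos])
  r
}

.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# largest eigenvalue of [1 X]'[1 X] / N via a few power iterations
.lipschitz_bound <- function(X) {
  n <- nrow(X)
  v <- rep(1, ncol(X) + 1L)
  v <- v / sqrt(sum(v^2))
  nv <- 1
  for (it in 1:12) {
    u <- v[1L] + as.numeric(X %*% v[-1L])
    w <- c(sum(u), as.numeric(Matrix::crossprod(X, u)))
    nv <- sqrt(sum(w^2))
    if (nv == 0) return(1 / n)
    v <- w / nv
  }
  1.05 * nv / n  # small safety margin; backtracking covers the rest
}

# FISTA on a fixed column set; returns the updated iterate
.fista_probit <- function(X, s, lambda, b0, b, tol, max_iter) {
  n <- nrow(X); p <- ncol(X)
  t0 <- 1 / .lipschitz_bound(X)
  yb0 <- b0; yb <- b
  theta <- 1
  eta_b <- b0 + as.numeric(X %*% b)
  eta_y <- eta_b
  f_y <- .probit_nll(eta_y, s)
  n_bt <- 0L
  kkt <- Inf
  obj_prev <- Inf
  sep_warned <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    r <- .probit_eta_grad(eta_y, s) / n
    g0 <- sum(r)
    g <- as.numeric(Matrix::crossprod(X, r))
    t <- t0
    repeat {
      nb0 <- yb0 - t * g0
      nb <- .soft(yb - t * g, t * lambda)
      d0 <- nb0 - yb0; d <- nb - yb
      eta_n <- nb0 + as.numeric(X %*% nb)
      f_n <- .probit_nll(eta_n, s)
      quad <- f_y + g0 * d0 + sum(g * d) + (d0^2 + sum(d^2)) / (2 * t)
      if (f_n <= quad + 1e-12 || t < 1e-14) break
      t <- t / 2; n_bt <- n_bt + 1L
    }
    obj <- f_n + lambda * sum(abs(nb))
    if (obj > obj_prev + 1e-12) {   # adaptive restart
      theta <- 1
      yb0 <- b0; yb <- b
      eta_y <- eta_b
      f_y <- .probit_nll(eta_y, s)
      obj_prev <- Inf
      next
    }
    theta_n <- (1 + sqrt(1 + 4 * theta^2)) / 2
    mom <- (theta - 1) / theta_n
    yb0 <- nb0 + mom * (nb0 - b0)
    yb <- nb + mom * (nb - b)
    # eta at the momentum point by linearity; saves a matvec per iteration
    eta_y <- eta_n + mom * (eta_n - eta_b)
    eta_b <- eta_n
    b0 <- nb0; b <- nb
    theta <- theta_n
    obj_prev <- obj
    f_y <- .probit_nll(eta_y, s)
    if (it %% 5L == 0L || it == max_iter) {
      rb <- .probit_eta_grad(eta_b, s) / n
      gb0 <- sum(rb)
      gb <- as.numeric(Matrix::crossprod(X, rb))
      viol <- pmax(abs(gb) - lambda, 0)
      act <- b != 0
      viol[act] <- abs(gb[act] + lambda * sign(b[act]))
      kkt <- max(abs(gb0), if (p) max(viol) else 0)
      if (kkt <= tol) break
      if (lambda == 0 && !sep_warned && length(b) && max(abs(b)) > 30) {
        warning("coefficients diverging at lambda = 0; ",
                "possible perfect separation")
        sep_warned <- TRUE
      }
    }
  }
  list(b0 = b0, b = b, eta = eta_b, iterations = it, kkt = kkt,
       backtracks = n_bt)
}

#' Fit an L1-penalized probit participation model at one penalty
#'
#' Minimizes the average probit negative log-likelihood of cohort-versus-
#' reference membership plus an L1 penalty on the slopes (intercept
#' unpenalized) by accelerated proximal gradient with backtracking, using
#' an active-set strategy: the problem is solved on a working set of
#' columns, the full Karush-Kuhn-Tucker conditions are then verified on all
#' columns, and violating columns are added until none remain. The fit is
#' declared converged when zero coefficients satisfy
#' `|grad_j| <= lambda + tol`, active coefficients satisfy
#' `|grad_j + lambda sign(b_j)| <= tol`, and the intercept gradient is
#' below `tol`.
#'
#' @param design an `ipw_design` (see [build_design_matrix()]) or a matrix.
#' @param labels binary vector: 1 = cohort member, 0 = reference member.
#' @param lambda penalty level, >= 0.
#' @param warm_start optional list with `intercept` and `beta` to start from.
#' @param tol KKT tolerance (default 1e-6).
#' @param max_iter inner-iteration cap per subproblem.
#' @return an object of class `participation_fit` with elements
#'   `intercept`, `coefficients` (named, dense; nonzero only on the active
#'   set), `lambda`, `n_selected`, and `convergence` (iterations, final KKT
#'   violation, backtracking count).
#' @export
fit_penalized_probit <- function(design, labels, lambda,
                                 warm_start = NULL, tol = 1e-6,
                                 max_iter = 5000L) {
  X <- if (inherits(design, "ipw_design")) design$X else design
  s <- as.numeric(labels)
  if (length(s) != nrow(X)) stop("labels length must match design rows")
  if (!all(s %in% c(0, 1))) stop("labels must be 0/1")
  if (!any(s == 1) || !any(s == 0)) {
    stop("labels must contain both classes (cohort and reference)")
  }
  if (lambda < 0) stop("lambda must be >= 0")
  n <- nrow(X); p <- ncol(X)
  b0 <- warm_start$intercept %||% stats::qnorm(mean(s))
  b <- numeric(p)
  if (!is.null(warm_start$beta)) {
    b[seq_along(warm_start$beta)] <- warm_start$beta
  }
  total_it <- 0L; total_bt <- 0L
  kkt <- Inf
  if (lambda == 0) {
    res <- .fista_probit(X, s, 0, b0, b, tol, max_iter)
    b0 <- res$b0; b <- res$b
    total_it <- res$iterations; total_bt <- res$backtracks
    kkt <- res$kkt
  } else {
    active <- which(b != 0)
    for (outer in 1:50) {
      # full KKT check at the current iterate
      eta <- rep(b0, n) + if (length(active))
        as.numeric(X[, active, drop = FALSE] %*% b[active]) else 0
      r <- .probit_eta_grad(eta, s) / n
      g0 <- sum(r)
      g <- as.numeric(Matrix::crossprod(X, r))
      viol <- pmax(abs(g) - lambda, 0)
      act <- b != 0
      viol[act] <- abs(g[act] + lambda * sign(b[act]))
      kkt <- max(abs(g0), if (p) max(viol) else 0)
      if (kkt <= tol) break
      active <- sort(union(which(act), which(viol > tol)))
      if (!length(active)) {
        # intercept-only optimum is closed form: Phi(b0) = mean(s)
        b0 <- stats::qnorm(mean(s))
        next
      }
      res <- .fista_probit(X[, active, drop = FALSE], s, lambda,
                           b0, b[active], tol, max_iter)
      b0 <- res$b0
      b[] <- 0; b[active] <- res$b
      total_it <- total_it + res$iterations
      total_bt <- total_bt + res$backtracks
      kkt <- res$kkt
    }
  }
  names(b) <- colnames(X)
  structure(list(intercept = b0, coefficients = b, lambda = lambda,
                 n_selected = sum(b != 0),
                 convergence = list(iterations = total_it, kkt = kkt,
                                    backtracks = total_bt, tol = tol)),
            class = "participation_fit")
}

#' Penalty grid for the participation model
#'
#' `lambda_max` is the smallest penalty at which all slopes are zero
#' (the largest absolute score-gradient component at the intercept-only
#' fit); the grid is log-spaced down to `lambda_max * min_ratio`.
#'
#' @param design an `ipw_design` or matrix.
#' @param labels binary membership labels.
#' @param n_lambda grid length.
#' @param min_ratio smallest/largest penalty ratio.
#' @return decreasing numeric vector.
#' @export
lambda_grid <- function(design, labels, n_lambda = 20L, min_ratio = 1e-3) {
  X <- if (inherits(design, "ipw_design")) design$X else design
  s <- as.numeric(labels)
  n <- nrow(X)
  b0 <- stats::qnorm(mean(s))
  r <- .probit_eta_grad(rep(b0, n), s) / n
  lmax <- max(abs(as.numeric(Matrix::crossprod(X, r))))
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

# path fit with warm starts; returns list of participation_fit
.fit_path <- function(X, s, lambdas, tol = 1e-6, max_iter = 5000L) {
  fits <- vector("list", length(lambdas))
  ws <- NULL
  for (i in seq_along(lambdas)) {
    fits[[i]] <- fit_penalized_probit(X, s, lambdas[i], warm_start = ws,
                                      tol = tol, max_iter = max_iter)
    ws <- list(intercept = fits[[i]]$intercept, beta = fits[[i]]$coefficients)
  }
  fits
}

# held-out mean deviance (2 x average NLL contribution)
.heldout_deviance <- function(fit, X, s) {
  eta <- fit$intercept + as.numeric(X %*% fit$coefficients)
  2 * .probit_nll(eta, s)
}

#' Choose the penalty by stratified cross-validation
#'
#' K-fold cross-validation stratified on the membership label, warm-started
#' along a decreasing penalty path; the chosen penalty minimizes the mean
#' held-out deviance (minimum rule). The final model is refit on all data at
#' the chosen penalty.
#'
#' @inheritParams fit_penalized_probit
#' @param lambdas decreasing penalty grid (default [lambda_grid()]).
#' @param folds number of folds (>= 2; default 10).
#' @param seed integer seed for fold assignment.
#' @param cv_tol KKT tolerance used inside CV refits (the final fit uses
#'   `tol`).
#' @return a `participation_fit` with additional elements `lambda_grid`,
#'   `cv_deviance` (mean held-out deviance per penalty), `cv_se`,
#'   `chosen_lambda` and `folds`.
#' @export
cross_validate_lambda <- function(design, labels, lambdas = NULL,
                                  folds = 10L, seed = 1L,
                                  tol = 1e-6, cv_tol = 1e-3,
                                  max_iter = 5000L) {
  X <- if (inherits(design, "ipw_design")) design$X else design
  s <- as.numeric(labels)
  if (folds < 2L) stop("folds must be >= 2")
  if (is.null(lambdas)) lambdas <- lambda_grid(X, s)
  if (is.unsorted(rev(lambdas), strictly = TRUE)) {
    stop("lambda grid must be strictly decreasing")
  }
  set.seed(stream_seed(seed, "folds"))
  fold_id <- integer(length(s))
  for (cls in c(0, 1)) {
    idx <- which(s == cls)
    if (length(idx) < folds) {
      stop("a class has fewer members than folds; cannot stratify")
    }
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  dev <- matrix(NA_real_, nrow = folds, ncol = length(lambdas))
  for (k in seq_len(folds)) {
    tr <- fold_id != k
    if (length(unique(s[!tr])) < 2L || length(unique(s[tr])) < 2L) {
      stop("fold ", k, " is missing a class after stratification")
    }
    fits <- .fit_path(X[tr, , drop = FALSE], s[tr], lambdas,
                      tol = cv_tol, max_iter = max_iter)
    for (i in seq_along(lambdas)) {
      dev[k, i] <- .heldout_deviance(fits[[i]], X[!tr, , drop = FALSE],
                                     s[!tr])
    }
  }
  mean_dev <- colMeans(dev)
  se_dev <- apply(dev, 2L, stats::sd) / sqrt(folds)
  best <- which.min(mean_dev)
  # final fit on all data: warm-start down the path at the CV tolerance,
  # then polish the chosen-penalty fit to the full KKT tolerance
  path <- .fit_path(X, s, lambdas[seq_len(best)], tol = cv_tol,
                    max_iter = max_iter)
  fit <- fit_penalized_probit(
    X, s, lambdas[best],
    warm_start = list(intercept = path[[best]]$intercept,
                      beta = path[[best]]$coefficients),
    tol = tol, max_iter = max_iter)
  fit$lambda_grid <- lambdas
  fit$cv_deviance <- mean_dev
  fit$cv_se <- se_dev
  fit$chosen_lambda <- lambdas[best]
  fit$folds <- folds
  fit
}

#' @export
print.participation_fit <- function(x, ...) {
  cat("L1-penalized probit participation fit\n")
  if (!is.null(x$chosen_lambda)) {
    cat(sprintf("  lambda = %.6g (chosen by %d-fold CV over %d penalties)\n",
                x$chosen_lambda, x$folds, length(x$lambda_grid)))
  } else {
    cat(sprintf("  lambda = %.6g\n", x$lambda))
  }
  cat(sprintf("  intercept = %.4f; %d of %d slopes selected\n",
              x$intercept, x$n_selected, length(x$coefficients)))
  cat(sprintf("  converged in %d iterations (KKT violation %.2e)\n",
              x$convergence$iterations, x$convergence$kkt))
  invisible(x)
}

#' @export
coef.participation_fit <- function(object, all = FALSE, ...) {
  cf <- c("(Intercept)" = object$intercept, object$coefficients)
  if (all) cf else cf[c(TRUE, object$coefficients != 0)]
}

#' Predicted participation probabilities
#'
#' Computes `Phi(intercept + x' beta)` for each row of a design matrix and
#' clips to `[eps, 1 - eps]`; the number of clipped values is attached as
#' attribute `n_clipped`.
#'
#' @param fit a `participation_fit`.
#' @param design an `ipw_design` or matrix whose columns cover the fit's
#'   active set (matched by name).
#' @param eps clipping bound (default 1e-8).
#' @return numeric vector of probabilities, strictly inside (0, 1).
#' @export
predict_probability <- function(fit, design, eps = 1e-8) {
  X <- if (inherits(design, "ipw_design")) design$X else design
  active <- names(fit$coefficients)[fit$coefficients != 0]
  missing_cols <- setdiff(active, colnames(X))
  if (length(missing_cols)) {
    stop("design lacks active column(s): ",
         paste(utils::head(missing_cols, 5L), collapse = ", "),
         if (length(missing_cols) > 5L) ", ...")
  }
  eta <- fit$intercept
  if (length(active)) {
    eta <- eta + as.numeric(X[, active, drop = FALSE] %*%
                              fit$coefficients[active])
  } else {
    eta <- rep(eta, nrow(X))
  }
  p <- stats::pnorm(eta)
  n_clip <- sum(p < eps | p > 1 - eps)
  p <- pmin(pmax(p, eps), 1 - eps)
  attr(p, "n_clipped") <- n_clip
  p
}
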