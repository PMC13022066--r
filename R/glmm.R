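#' Gauss-Hermite quadrature rule
#'
#' Nodes and weights for \eqn{\int e^{-v^2} h(v) dv \approx \sum_j w_j
#' h(v_j)}, computed by the Golub-Welsch eigen-decomposition of the
#' Jacobi matrix. Used (after adaptive recentring and rescaling at the
#' conditional mode) to integrate the class random intercept out of the
#' Gamma likelihood; one node reproduces the Laplace approximation.
#'
#' @param k Number of nodes.
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(k) {
  if (k == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(k - 1L)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1L)] <- J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

# Per-class sufficient statistics of the weighted Gamma log-likelihood.
# Conditional on a class intercept u, the weighted log-likelihood of
# class c collapses to A_c - nu*W0_c*u - T_c*exp(-u), with
#   A_c = (nu log nu - lgamma(nu)) W0_c + (nu - 1) Lw_c - nu R_c
#   T_c = nu * sum_c w y exp(-eta)
# so the inner optimisation and quadrature cost O(#classes) per node.
glmm_class_stats <- function(eta, y, w, ci, nC, nu) {
  sums <- rowsum(cbind(w * y * exp(-eta), w * eta), ci)
  # rowsum drops absent groups; map back to 1..nC
  S <- R <- numeric(nC)
  gi <- as.integer(rownames(sums))
  S[gi] <- sums[, 1]; R[gi] <- sums[, 2]
  list(S = S, R = R)
}

# Negative marginal log-likelihood and its analytic gradient at
# theta = (beta, sigma, log nu) [random = TRUE] or (beta, log nu)
# [random = FALSE]. sigma is parameterised on its natural scale with a
# boundary at 0 (the likelihood is analytic in sigma^2, so the gradient
# vanishes smoothly at a singular fit). The gradient differentiates
# through the adaptive quadrature exactly: the conditional modes u-hat
# and the scale s = sqrt(2/H) are functions of theta via the implicit
# function theorem, so no envelope approximation is involved.
glmm_nll_core <- function(theta, pc, random = TRUE, nagq = 7L, gh = NULL,
                          want_grad = FALSE) {
  p <- pc$p
  beta <- theta[seq_len(p)]
  if (random) {
    sigma <- theta[p + 1L]; nu <- exp(theta[p + 2L])
  } else {
    nu <- exp(theta[p + 1L])
  }
  eta <- drop(pc$X %*% beta)
  yex <- pc$w * pc$y * exp(-eta)            # w y e^-eta, per row
  sums <- rowsum(cbind(yex, pc$w * eta), pc$ci)
  S <- R <- numeric(pc$nC)
  gi <- as.integer(rownames(sums))
  S[gi] <- sums[, 1]; R[gi] <- sums[, 2]
  dAdnu <- (log(nu) + 1 - digamma(nu)) * pc$W0 + pc$Lw - R
  A <- (nu * log(nu) - lgamma(nu)) * pc$W0 + (nu - 1) * pc$Lw - nu * R
  Tc <- nu * S
  Wnu <- nu * pc$W0

  if (!random || sigma < 1e-10) {
    nll <- -sum(A - Tc)
    if (!want_grad) return(nll)
    gb <- -drop(crossprod(pc$X, nu * (yex - pc$w)))
    gnu <- -nu * sum(dAdnu - S)
    # at the sigma = 0 boundary dL/dsigma = 0 (L analytic in sigma^2)
    grad <- if (random) c(gb, 0, gnu) else c(gb, gnu)
    return(list(nll = nll, grad = grad))
  }

  s2 <- sigma^2
  # conditional mode: T exp(-u) - Wnu - u/s2 = 0 (damped Newton)
  u <- numeric(pc$nC)
  for (it in 1:60) {
    eu <- Tc * exp(-u)
    g <- eu - Wnu - u / s2
    step <- pmin(pmax(g / (eu + 1 / s2), -3), 3)
    u <- u + step
    if (max(abs(step)) < 1e-13) break
  }
  Teu <- Tc * exp(-u)
  H <- Teu + 1 / s2
  if (is.null(gh)) gh <- gauss_hermite(nagq)
  k <- length(gh$nodes)
  s <- sqrt(2 / H)
  # nodes u_j = u-hat + s v_j; log L_c = log s + logsumexp_j[
  #   phi(u_j) + v_j^2 + log w_j ]
  U <- outer(u, rep(1, k)) + outer(s, gh$nodes)      # C x k
  EU <- exp(-U)
  PHI <- A - Wnu * U - Tc * EU - U^2 / (2 * s2) - 0.5 * log(2 * pi * s2)
  M <- PHI + matrix(gh$nodes^2 + log(gh$weights), pc$nC, k, byrow = TRUE)
  mx <- apply(M, 1L, max)
  Zs <- rowSums(exp(M - mx))
  nll <- -sum(log(s) + mx + log(Zs))
  if (!want_grad) return(nll)

  P <- exp(M - mx) / Zs                               # posterior node weights
  DPHI <- -Wnu + Tc * EU - U / s2                     # phi'(u_j)
  q1 <- rowSums(P * EU)
  q2 <- rowSums(P * DPHI)
  q3 <- 1 / s + rowSums(P * DPHI * matrix(gh$nodes, pc$nC, k, byrow = TRUE))
  r <- Teu / H

  # beta: dL_c/dbeta = -nu U_c + gamma_c V_c, with U_c = sum_c w x and
  # V_c = nu sum_c w y e^-eta x; both collapse into one cross-product.
  du_db <- -exp(-u) / H                               # times V_c
  ds_db <- s * exp(-u) * (1 - r) / (2 * H)            # times V_c
  gamma <- q1 + q2 * du_db + q3 * ds_db
  zrow <- -nu * pc$w + (gamma[pc$ci] * nu) * yex
  gb <- drop(crossprod(pc$X, zrow))

  # sigma (natural scale: d/dsigma = d/dlog(sigma) / sigma)
  du_ds <- (2 * u / s2) / H
  dH_ds <- -Teu * du_ds - 2 / s2
  ds_ds <- -(s / (2 * H)) * dH_ds
  gs <- sum(rowSums(P * (U^2 / s2 - 1)) + q2 * du_ds + q3 * ds_ds) / sigma

  # log nu
  du_dn <- (-nu * pc$W0 + Teu) / H
  dH_dn <- Teu * (1 - du_dn)
  ds_dn <- -(s / (2 * H)) * dH_dn
  gn <- sum(rowSums(P * (nu * dAdnu - nu * pc$W0 * U - Tc * EU)) +
              q2 * du_dn + q3 * ds_dn)

  list(nll = nll, grad = -c(gb, gs, gn))
}

# Back-compatible objective-only wrapper.
glmm_nll <- function(theta, pc, random = TRUE, nagq = 7L, gh = NULL) {
  glmm_nll_core(theta, pc, random = random, nagq = nagq, gh = gh,
                want_grad = FALSE)
}

# Objective/gradient pair sharing one evaluation via a cache.
glmm_objective <- function(pc, random = TRUE, gh) {
  cache_theta <- NULL; cache <- NULL
  ev <- function(theta) {
    if (is.null(cache_theta) || !identical(theta, cache_theta)) {
      cache <<- glmm_nll_core(theta, pc, random = random, gh = gh,
                              want_grad = TRUE)
      cache_theta <<- theta
    }
    cache
  }
  list(fn = function(theta) ev(theta)$nll,
       gr = function(theta) ev(theta)$grad)
}

# Conditional modes of the class intercepts at given parameters.
glmm_modes <- function(beta, sigma, nu, pc) {
  eta <- drop(pc$X %*% beta)
  st <- glmm_class_stats(eta, pc$y, pc$w, pc$ci, pc$nC, nu)
  Tc <- nu * st$S; Wnu <- nu * pc$W0
  if (sigma <= 0) return(numeric(pc$nC))
  u <- numeric(pc$nC)
  for (it in 1:50) {
    eu <- Tc * exp(-u)
    g <- eu - Wnu - u / sigma^2
    step <- pmin(pmax(g / (eu + 1 / sigma^2), -3), 3)
    u <- u + step
    if (max(abs(step)) < 1e-12) break
  }
  u
}

glmm_precompute <- function(design, weights, rescale = TRUE) {
  X <- design$X; y <- design$y
  w <- as.numeric(weights)
  if (length(w) != length(y)) stop("weights length mismatch")
  if (any(w <= 0)) stop("weights must be positive")
  if (rescale) w <- w * length(w) / sum(w)
  ci <- as.integer(design$group)
  nC <- nlevels(design$group)
  W0 <- Lw <- numeric(nC)
  sums <- rowsum(cbind(w, w * log(y)), ci)
  gi <- as.integer(rownames(sums))
  W0[gi] <- sums[, 1]; Lw[gi] <- sums[, 2]
  list(X = X, y = y, w = w, ci = ci, nC = nC, p = ncol(X),
       W0 = W0, Lw = Lw)
}

#' Control parameters for the GLMM fitter
#'
#' @param nagq Number of adaptive Gauss-Hermite nodes (1 = Laplace).
#' @param maxit Maximum outer iterations of the PORT optimiser.
#' @param singular_tol Singularity threshold: the fit is flagged
#'   singular when the estimated class SD falls below
#'   `singular_tol * sd(log y)`.
#' @param rel_tol Relative convergence tolerance of the optimiser.
#' @return List of control parameters.
#' @export
glmm_control <- function(nagq = 7L, maxit = 400L, singular_tol = 1e-4,
                         rel_tol = 1e-10) {
  list(nagq = as.integer(nagq), maxit = as.integer(maxit),
       singular_tol = singular_tol, rel_tol = rel_tol)
}

#' Fit the weighted Gamma log-link mixed model
#'
#' Maximises the weighted marginal likelihood of a Gamma GLMM with log
#' link and a single (class) random intercept. Observation weights act
#' as likelihood multipliers and are internally rescaled to mean 1, a
#' convention that leaves the coefficient estimates unchanged (only the
#' reported shape depends on the weight scale) while keeping shape
#' estimation numerically stable. The class intercepts are integrated
#' out by adaptive Gauss-Hermite quadrature centred at the conditional
#' modes (`nagq = 1` gives the Laplace approximation).
#'
#' @param design A `divshift_design` from [build_design()].
#' @param weights Positive per-observation weights (e.g. from
#'   [compute_weights()]).
#' @param control See [glmm_control()].
#' @param start Optional warm start: a previously fitted model or a
#'   parameter vector `(beta, log sigma, log nu)`.
#' @param random Set `FALSE` to drop the random intercept and fit a
#'   plain weighted Gamma GLM.
#' @param se If `TRUE`, standard errors are computed from the numerical
#'   Hessian of the marginal log-likelihood.
#' @return An object of class `divshift_glmm` with elements
#'   `coefficients`, `class_intercepts`, `class_sd`, `class_variance`,
#'   `gamma_shape`, `log_likelihood`, `converged`, `singular`, `n_obs`,
#'   `n_params`, `fitted_eta` and (optionally) `se`.
#' @export
fit_glmm <- function(design, weights, control = glmm_control(),
                     start = NULL, random = TRUE, se = FALSE) {
  pc <- glmm_precompute(design, weights)
  p <- pc$p
  if (any(pc$y <= 0)) stop("non-positive response values")
  qrX <- qr(pc$X)
  if (qrX$rank < p)
    stop(sprintf("rank-deficient fixed-effect design (rank %d < %d columns)",
                 qrX$rank, p))
  sd_logy <- stats::sd(log(pc$y))

  if (inherits(start, "divshift_glmm")) {
    # never warm-start exactly at the sigma = 0 boundary, where the
    # gradient vanishes and the optimiser could not leave it
    theta0 <- c(start$coefficients, max(start$class_sd, 0.02),
                log(start$gamma_shape))
    if (!random) theta0 <- c(start$coefficients, log(start$gamma_shape))
  } else if (is.numeric(start)) {
    theta0 <- start
  } else {
    fit0 <- stats::lm.wfit(pc$X, log(pc$y), pc$w)
    beta0 <- fit0$coefficients
    beta0[is.na(beta0)] <- 0
    r <- log(pc$y) - drop(pc$X %*% beta0)
    s2 <- sum(pc$w * r^2) / sum(pc$w)
    nu0 <- min(max(1 / max(expm1(s2), 1e-3), 0.05), 50)
    if (random) {
      um <- tapply(r, pc$ci, mean)
      sig0 <- min(max(stats::sd(um), 0.05), 2)
      if (is.na(sig0)) sig0 <- 0.1
      theta0 <- c(beta0, sig0, log(nu0))
    } else {
      theta0 <- c(beta0, log(nu0))
    }
  }

  gh <- gauss_hermite(control$nagq)
  lower <- c(rep(-Inf, p), if (random) 0, log(1e-3))
  upper <- c(rep(Inf, p), if (random) 20, log(1e4))
  obj <- glmm_objective(pc, random = random, gh = gh)
  opt <- stats::nlminb(theta0, obj$fn, gradient = obj$gr,
                       lower = lower, upper = upper,
                       control = list(iter.max = control$maxit,
                                      eval.max = 5L * control$maxit,
                                      rel.tol = control$rel_tol))
  beta <- opt$par[seq_len(p)]
  sigma <- if (random) opt$par[p + 1L] else 0
  singular <- random && sigma < control$singular_tol * sd_logy
  if (singular) {
    # snap to the boundary: with sigma this small the random intercept
    # is indistinguishable from zero and the profile is essentially
    # flat, so refine (beta, shape) with the fixed-effects likelihood
    sigma <- 0
    obj <- glmm_objective(pc, random = FALSE, gh = gh)
    opt <- stats::nlminb(c(beta, opt$par[p + 2L]), obj$fn,
                         gradient = obj$gr,
                         lower = c(rep(-Inf, p), log(1e-3)),
                         upper = c(rep(Inf, p), log(1e4)),
                         control = list(iter.max = control$maxit,
                                        eval.max = 5L * control$maxit,
                                        rel.tol = control$rel_tol))
    beta <- opt$par[seq_len(p)]
  }
  names(beta) <- colnames(design$X)
  nu <- exp(opt$par[length(opt$par)])
  u <- if (random && sigma > 0) glmm_modes(beta, sigma, nu, pc)
       else numeric(pc$nC)
  names(u) <- levels(design$group)
  fit <- list(coefficients = beta,
              class_intercepts = u,
              class_sd = sigma,
              class_variance = sigma^2,
              gamma_shape = nu,
              log_likelihood = -opt$objective,
              converged = opt$convergence == 0,
              singular = singular,
              n_obs = length(pc$y),
              n_params = length(opt$par),
              fitted_eta = drop(pc$X %*% beta) + u[pc$ci],
              random = random,
              message = opt$message,
              iterations = opt$iterations)
  if (se) {
    Hs <- stats::optimHess(opt$par, obj$fn, obj$gr)
    V <- try(solve(Hs), silent = TRUE)
    if (!inherits(V, "try-error")) {
      fit$vcov <- V[seq_len(p), seq_len(p), drop = FALSE]
      fit$se <- structure(sqrt(pmax(diag(V)[seq_len(p)], 0)),
                          names = names(beta))
    }
  }
  class(fit) <- "divshift_glmm"
  fit
}

#' @export
print.divshift_glmm <- function(x, ...) {
  cat(sprintf("Weighted Gamma log-link %s (n = %d)\n",
              if (x$random) "GLMM, class random intercept" else "GLM",
              x$n_obs))
  cat(sprintf("  logLik %.3f | shape %.3f | class SD %.4f%s%s\n",
              x$log_likelihood, x$gamma_shape, x$class_sd,
              if (x$singular) " [singular]" else "",
              if (!x$converged) " [NOT CONVERGED]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Evaluate the weighted marginal log-likelihood at given parameters
#'
#' Exposes the quadrature-based marginal log-likelihood of the Gamma
#' mixed model at user-supplied parameter values, for cross-checking
#' against brute-force integration over the random intercept.
#'
#' @param design A `divshift_design`.
#' @param weights Positive observation weights (rescaled to mean 1, as
#'   in fitting, unless `rescale = FALSE`).
#' @param coefficients Fixed-effect vector (design column order).
#' @param class_sd Random-intercept SD (0 collapses to the fixed-effect
#'   likelihood).
#' @param shape Gamma shape.
#' @param nagq Quadrature nodes (1 = Laplace).
#' @param rescale Rescale weights to mean 1 (default `TRUE`).
#' @return The marginal log-likelihood.
#' @export
glmm_loglik <- function(design, weights, coefficients, class_sd, shape,
                        nagq = 7L, rescale = TRUE) {
  pc <- glmm_precompute(design, weights, rescale = rescale)
  if (class_sd <= 0)
    return(-glmm_nll(c(coefficients, log(shape)), pc, random = FALSE))
  -glmm_nll(c(coefficients, class_sd, log(shape)), pc,
            random = TRUE, nagq = nagq)
}

#' Variance inflation factors of a fixed-effect design
#'
#' For each non-intercept column j, `VIF_j = 1 / (1 - R2_j)` where
#' `R2_j` is from the least-squares regression of column j on all other
#' columns (intercept included). A perfectly collinear column yields
#' `Inf` rather than an error.
#'
#' @param design A `divshift_design`, or a numeric matrix whose first
#'   column may be an intercept.
#' @return Named numeric vector of VIFs for the non-intercept columns.
#' @export
variance_inflation <- function(design) {
  X <- if (inherits(design, "divshift_design")) design$X else design
  keep <- colnames(X) != "intercept"
  if (sum(keep) < 2L) stop("need at least two non-intercept columns")
  out <- numeric(0)
  for (j in which(keep)) {
    xj <- X[, j]
    fit <- stats::lm.fit(X[, -j, drop = FALSE], xj)
    rss <- sum(fit$residuals^2)
    tss <- sum((xj - mean(xj))^2)
    r2 <- if (tss <= 0) 1 else 1 - rss / tss
    out[colnames(X)[j]] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}

#' Lognormal-method marginal R-squared components
#'
#' `R2m = s2_f / (s2_f + s2_class + s2_d)`, where `s2_f` is the
#' variance of the fixed-effect linear predictor over observations,
#' `s2_class` the random-intercept variance, and
#' `s2_d = log(1 + 1/shape)` the lognormal-approximation
#' observation-level variance of a Gamma log-link model.
#'
#' @param sigma2_fixed Variance of the fixed-effect linear predictor.
#' @param sigma2_class Class random-intercept variance.
#' @param shape Gamma shape.
#' @return The marginal R-squared.
#' @export
lognormal_r2 <- function(sigma2_fixed, sigma2_class, shape) {
  if (shape <= 0) stop("shape must be positive")
  sigma2_fixed / (sigma2_fixed + sigma2_class + log1p(1 / shape))
}

#' Marginal R-squared of a fitted model (lognormal method)
#'
#' @param fit A `divshift_glmm`.
#' @param design The design the model was fitted to.
#' @return The marginal R-squared.
#' @export
marginal_r2_lognormal <- function(fit, design) {
  eta_f <- drop(design$X %*% fit$coefficients)
  s2f <- mean((eta_f - mean(eta_f))^2)
  lognormal_r2(s2f, fit$class_variance, fit$gamma_shape)
}
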