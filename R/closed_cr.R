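#' Specify one of the four closed capture-recapture models
#'
#' The model set contains exactly four members: detection probability `p`
#' constant or time-dependent (one value per flyover), and equal between
#' colonies or differing by an additive offset on the logit scale. The
#' never-detected count `f0` is always colony-specific on a log link, so
#' abundance `N_g = n_g + f0_g` is estimated per colony under every model.
#'
#' Parameter count: `K = (1 or T) + (0 or G-1) + G` for G colonies and T
#' occasions, in the order (p intercepts, colony offsets, log-f0 per colony).
#'
#' @param p_structure `"constant"` or `"time"`.
#' @param colony_effect `"none"` or `"additive"` (offset on logit p; the
#'   first colony in sorted label order is the reference).
#' @return An object of class `closed_model_spec`.
#' @examples
#' closed_model_spec("time", "additive")
#' @export
closed_model_spec <- function(p_structure = c("constant", "time"),
                              colony_effect = c("none", "additive")) {
  p_structure <- match.arg(p_structure)
  colony_effect <- match.arg(colony_effect)
  name <- paste0("p(", if (p_structure == "constant") "." else "t", ")",
                 if (colony_effect == "additive") "+colony" else "")
  structure(list(p_structure = p_structure, colony_effect = colony_effect,
                 name = name),
            class = "closed_model_spec")
}

#' The four-model set, in canonical order
#'
#' Order: constant before time-dependent, no colony effect before additive.
#' This order also breaks AIC ties in [rank_models()].
#' @return list of four [closed_model_spec()] objects.
#' @export
closed_model_set <- function() {
  list(closed_model_spec("constant", "none"),
       closed_model_spec("constant", "additive"),
       closed_model_spec("time", "none"),
       closed_model_spec("time", "additive"))
}

#' @export
print.closed_model_spec <- function(x, ...) {
  cat("Closed model spec:", x$name, "\n")
  invisible(x)
}

spec_n_par <- function(spec, T, G) {
  kp <- if (spec$p_structure == "constant") 1L else T
  kc <- if (spec$colony_effect == "additive") G - 1L else 0L
  as.integer(kp + kc + G)
}

# Map the beta vector to the T x G matrix of logit-scale linear predictors
# and the per-colony log f0. Returns the design matrix rows implicitly via
# index bookkeeping used by both the likelihood and the delta method.
spec_design <- function(spec, T, G) {
  kp <- if (spec$p_structure == "constant") 1L else T
  kc <- if (spec$colony_effect == "additive") G - 1L else 0L
  K <- kp + kc + G
  # X: (T*G) x (kp + kc); row order is occasion within colony (column-major
  # on the T x G eta matrix)
  X <- matrix(0, T * G, kp + kc)
  for (g in seq_len(G)) {
    for (t in seq_len(T)) {
      r <- (g - 1L) * T + t
      X[r, if (kp == 1L) 1L else t] <- 1
      if (kc > 0L && g > 1L) X[r, kp + g - 1L] <- 1
    }
  }
  list(X = X, kp = kp, kc = kc, K = as.integer(K),
       idx_p = seq_len(kp + kc), idx_f0 = kp + kc + seq_len(G))
}

ETA_CAP <- 35        # |logit p| cap: plogis(35) is 1 to machine precision
LOGF0_CAP <- 25      # f0 cap ~ 7.2e10, far above any colony size
P_EPS <- 1e-12
F0_BOUNDARY <- 1e-6
P_BOUNDARY <- 1e-6

#' Negative log-likelihood of a closed model
#'
#' Full (unconditional) closed-population likelihood. For colony `g` with
#' occasions `t = 1..T`, `p[t,g] = plogis(eta[t,g])` with `eta` built from
#' the model spec, `f0_g = exp(beta_f0_g)` and `N_g = n_g + f0_g`; the
#' colony's contribution is
#' `lgamma(N_g+1) - lgamma(f0_g+1) + sum_t [ x[t,g] log p[t,g] +
#' (N_g - x[t,g]) log(1 - p[t,g]) ]`,
#' with `x[t,g]` the number of colony-g nests detected on occasion `t`.
#' `f0` is treated as continuous through the gamma function, as in standard
#' closed-model software, so the surface is smooth in `beta`.
#'
#' @param spec a [closed_model_spec()].
#' @param beta numeric vector of length `K` (p coefficients on the logit
#'   scale, then one log-f0 per colony in sorted colony order).
#' @param dataset a [capture_dataset()].
#' @return The negative total log-likelihood (finite for finite `beta`).
#' @export
negloglik_full <- function(spec, beta, dataset) {
  stopifnot(inherits(spec, "closed_model_spec"),
            inherits(dataset, "capture_dataset"))
  ss <- suff_stats(dataset)
  des <- spec_design(spec, ss$T, ss$G)
  if (!is.numeric(beta) || length(beta) != des$K) {
    stop_contract("'beta' must have length ", des$K, " for model ", spec$name)
  }
  if (any(!is.finite(beta))) stop_contract("'beta' must be finite")
  nll_from_stats(beta, ss, des)
}

nll_from_stats <- function(beta, ss, des) {
  eta <- pmin(pmax(des$X %*% beta[des$idx_p], -ETA_CAP), ETA_CAP)
  p <- matrix(stats::plogis(eta), ss$T, ss$G)
  p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
  f0 <- exp(pmin(beta[des$idx_f0], LOGF0_CAP))
  N <- ss$n + f0
  Nmat <- matrix(N, ss$T, ss$G, byrow = TRUE)
  ll <- sum(lgamma(N + 1) - lgamma(f0 + 1)) +
    sum(ss$x * log(p)) + sum((Nmat - ss$x) * log1p(-p))
  -ll
}

# analytic gradient of nll_from_stats; beta_p via the chain rule through the
# logit link (d ll / d eta = x - N p cellwise), beta_f0 via digamma terms
nll_grad_stats <- function(beta, ss, des) {
  eta <- pmin(pmax(des$X %*% beta[des$idx_p], -ETA_CAP), ETA_CAP)
  p <- matrix(stats::plogis(eta), ss$T, ss$G)
  p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
  f0 <- exp(pmin(beta[des$idx_f0], LOGF0_CAP))
  N <- ss$n + f0
  Nmat <- matrix(N, ss$T, ss$G, byrow = TRUE)
  d_eta <- ss$x - Nmat * p                       # d ll / d eta, T x G
  g_p <- -as.numeric(crossprod(des$X, as.numeric(d_eta)))
  d_f0 <- digamma(N + 1) - digamma(f0 + 1) + colSums(log1p(-p))
  g_f0 <- -f0 * d_f0
  c(g_p, g_f0)
}

#' Fit a closed capture-recapture model
#'
#' Maximizes the full likelihood by multi-start quasi-Newton (BFGS)
#' optimization with numerical gradients. The first start is moment-based
#' (overall detection frequency and the implied never-detected count); the
#' remaining starts jitter it with seeded standard-normal noise on the link
#' scales. The variance-covariance matrix of `beta` comes from the numerical
#' Hessian at the optimum. Boundary solutions (`p_hat > 1 - 1e-6` or
#' `f0_hat < 1e-6`) are detected and reported with degenerate intervals.
#'
#' @param dataset a [capture_dataset()] with at least 2 occasions and every
#'   colony observed at least once.
#' @param spec a [closed_model_spec()]; default constant p, no colony effect.
#' @param options list: `n_starts` (default 3), `tol` (relative convergence
#'   tolerance, default 1e-10), `max_iter` (default 500), `seed` for the
#'   jittered starts (default 1).
#' @return An object of class `closed_fit`: the model spec, `beta`, `vcov`,
#'   `p_hat`/`p_lower`/`p_upper` (T x G), `f0_hat`, `se_f0`, per-colony
#'   `n`, `N_hat` with 95% CI, `logLik`, `K`, `AIC`, `converged`,
#'   `n_starts_used`, boundary flags.
#' @examples
#' d <- capture_dataset(c("111", "110", "101", "011", "100"), rep("A", 5))
#' fit_closed(d)
#' @export
fit_closed <- function(dataset, spec = closed_model_spec(), options = list()) {
  stopifnot(inherits(dataset, "capture_dataset"))
  if (nrow(dataset$histories) == 0L) {
    stop_contract("empty dataset: no observed nests to fit")
  }
  if (dataset$occasions < 2L) {
    stop_contract("closed models need at least 2 occasions (T = ",
                  dataset$occasions, " is not identifiable)")
  }
  ss <- suff_stats(dataset)
  if (any(ss$n < 1L)) {
    stop_contract("every colony must have at least one observed nest")
  }
  des <- spec_design(spec, ss$T, ss$G)
  opts <- utils::modifyList(
    list(n_starts = 3L, tol = 1e-10, max_iter = 500L, seed = 1L), options)

  fn <- function(b) nll_from_stats(b, ss, des)

  # moment-based start: pooled per-occasion detection frequency and the
  # implied f0 per colony
  p0 <- sum(ss$x) / (ss$T * ss$n_total)
  p0 <- min(max(p0, 0.05), 0.95)
  pstar0 <- 1 - (1 - p0)^ss$T
  f00 <- pmax(ss$n * (1 - pstar0) / pstar0, 0.05)
  base <- c(rep(logit(p0), des$kp), rep(0, des$kc), log(f00))

  starts <- list(base)
  if (opts$n_starts > 1L) {
    jit <- with_seed(opts$seed, lapply(seq_len(opts$n_starts - 1L), function(s) {
      base + stats::rnorm(des$K)
    }))
    starts <- c(starts, jit)
  }

  gr <- function(b) nll_grad_stats(b, ss, des)
  run_bfgs <- function(st) {
    tryCatch(
      stats::optim(st, fn, gr, method = "BFGS",
                   control = list(maxit = opts$max_iter,
                                  reltol = max(opts$tol, 1e-14))),
      error = function(e) NULL)
  }
  best <- NULL
  for (st in starts) {
    res <- run_bfgs(st)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop_contract("all optimizer starts failed")

  # Boundary polish: BFGS approaches an f0 = 0 boundary along log f0 only
  # geometrically, stalling a likelihood sliver short of the supremum. Pin
  # small f0 components at (numerical) zero, re-optimize, keep if better.
  small <- best$par[des$idx_f0] < log(0.5)
  if (any(small)) {
    pinned <- best$par
    pinned[des$idx_f0][small] <- -30
    res <- run_bfgs(pinned)
    if (!is.null(res) && res$value < best$value) best <- res
  }
  # one restart from the optimum guards against premature reltol stops
  res <- run_bfgs(best$par)
  if (!is.null(res) && res$value < best$value) best <- res

  # profile polish: the likelihood can have a very shallow interior optimum
  # in a log-f0 coordinate (order 1e-6 above the boundary value) that a
  # quasi-Newton line search steps over; a 1-D Brent pass per colony,
  # followed by a BFGS restart, recovers it
  for (round in 1:2) {
    par <- best$par
    for (g in seq_len(ss$G)) {
      j <- des$idx_f0[g]
      o <- stats::optimize(function(v) { pp <- par; pp[j] <- v; fn(pp) },
                           c(-35, log(2 * ss$n[g] + 10)), tol = 1e-9)
      if (o$objective < fn(par)) par[j] <- o$minimum
    }
    val <- fn(par)
    if (val >= best$value - 1e-12) break
    best <- list(par = par, value = val, convergence = 0L)
    res <- run_bfgs(par)
    if (!is.null(res) && res$value < best$value) best <- res
  }

  beta <- as.numeric(best$par)
  ll <- -best$value
  grad <- gr(beta)
  converged <- (best$convergence == 0L) ||
    (max(abs(grad)) < 1e-4 * (1 + abs(best$value)))

  f0_hat <- exp(pmin(beta[des$idx_f0], LOGF0_CAP))
  f0_boundary <- f0_hat < F0_BOUNDARY
  f0_hat[f0_boundary] <- 0

  # p on the probability scale
  eta <- as.numeric(des$X %*% beta[des$idx_p])
  p_hat <- matrix(stats::plogis(pmin(pmax(eta, -ETA_CAP), ETA_CAP)), ss$T, ss$G,
                  dimnames = list(NULL, ss$labels))
  p_boundary <- p_hat > 1 - P_BOUNDARY

  # vcov from the numerical Hessian of the free (non-boundary) parameters:
  # a colony at the f0 = 0 boundary (or a saturated p) contributes a flat
  # likelihood direction that would make the full Hessian singular, so
  # those coordinates are held fixed and the rest inverted blockwise
  free <- rep(TRUE, des$K)
  free[des$idx_f0][f0_boundary] <- FALSE
  if (all(p_boundary)) free[des$idx_p] <- FALSE
  V <- matrix(NA_real_, des$K, des$K)
  if (any(free)) {
    H <- tryCatch(stats::optimHess(beta, fn, gr), error = function(e) NULL)
    if (!is.null(H)) {
      Vf <- tryCatch(solve(H[free, free, drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(Vf) && all(is.finite(diag(Vf)))) V[free, free] <- Vf
    }
  }

  v_logf0 <- diag(V)[des$idx_f0]
  se_logf0 <- ifelse(is.finite(v_logf0) & v_logf0 > 0, sqrt(v_logf0), NA_real_)
  se_f0 <- f0_hat * se_logf0
  se_f0[f0_boundary] <- 0

  # delta-method CI for p on the logit scale, back-transformed
  p_lower <- p_upper <- matrix(NA_real_, ss$T, ss$G,
                               dimnames = list(NULL, ss$labels))
  Vp <- V[des$idx_p, des$idx_p, drop = FALSE]
  if (all(is.finite(diag(Vp)))) {
    se_eta <- sqrt(pmax(rowSums((des$X %*% Vp) * des$X), 0))
    z <- stats::qnorm(0.975)
    p_lower[] <- stats::plogis(eta - z * se_eta)
    p_upper[] <- stats::plogis(eta + z * se_eta)
  }
  p_lower[p_boundary] <- p_hat[p_boundary]
  p_upper[p_boundary] <- p_hat[p_boundary]

  fit <- structure(
    list(spec = spec, beta = beta, vcov = V,
         colony = ss$labels, n = stats::setNames(as.numeric(ss$n), ss$labels),
         p_hat = p_hat, p_lower = p_lower, p_upper = p_upper,
         f0_hat = stats::setNames(f0_hat, ss$labels),
         se_f0 = stats::setNames(se_f0, ss$labels),
         f0_boundary = stats::setNames(f0_boundary, ss$labels),
         N_hat = stats::setNames(as.numeric(ss$n) + f0_hat, ss$labels),
         logLik = ll, K = des$K, AIC = -2 * ll + 2 * des$K,
         converged = converged, n_starts_used = length(starts),
         occasions = ss$T),
    class = "closed_fit")
  ci <- abundance_ci(fit)
  fit$N_lower <- stats::setNames(ci$lower, ss$labels)
  fit$N_upper <- stats::setNames(ci$upper, ss$labels)
  fit
}

#' @export
print.closed_fit <- function(x, digits = 3, ...) {
  cat("Closed capture-recapture fit:", x$spec$name, "\n")
  cat(sprintf("logLik = %.3f  K = %d  AIC = %.2f  converged = %s\n",
              x$logLik, x$K, x$AIC, x$converged))
  cat("\nDetection probability (occasion x colony):\n")
  print(round(x$p_hat, digits))
  cat("\nAbundance:\n")
  print(data.frame(colony = x$colony, n = x$n,
                   N_hat = round(x$N_hat, 1),
                   lower = round(x$N_lower, 1), upper = round(x$N_upper, 1),
                   row.names = NULL))
  invisible(x)
}

#' Lognormal confidence interval for per-colony abundance
#'
#' Standard closed-captures interval: a lognormal interval on the
#' never-detected count `f0`, bounded below by the observed count `n_g`.
#' With `C = exp(z * sqrt(log(1 + cv(f0)^2)))` and `cv(f0) = SE(f0)/f0`, the
#' interval is `[n_g + f0/C, n_g + f0*C]`. When `f0_hat = 0` (boundary, all
#' nests seen) the interval degenerates to `[n_g, n_g]`; when `SE(f0) = 0`
#' it degenerates to the point estimate.
#'
#' @param fit a `closed_fit` from [fit_closed()].
#' @param level confidence level in (0, 1); default 0.95.
#' @return data.frame with columns `colony`, `n`, `N_hat`, `lower`, `upper`.
#' @export
abundance_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "closed_fit"))
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop_contract("'level' must be a probability strictly between 0 and 1")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  G <- length(fit$colony)
  lower <- upper <- numeric(G)
  for (g in seq_len(G)) {
    n <- fit$n[g]; f0 <- fit$f0_hat[g]; se <- fit$se_f0[g]
    if (fit$f0_boundary[g] || f0 == 0) {
      lower[g] <- upper[g] <- n
    } else if (is.na(se)) {
      lower[g] <- upper[g] <- NA_real_
    } else if (se == 0) {
      lower[g] <- upper[g] <- n + f0
    } else {
      C <- exp(z * sqrt(log(1 + (se / f0)^2)))
      lower[g] <- max(n + f0 / C, n)
      upper[g] <- n + f0 * C
    }
  }
  data.frame(colony = fit$colony, n = as.numeric(fit$n),
             N_hat = as.numeric(fit$N_hat), lower = lower, upper = upper,
             row.names = NULL)
}

#' Probability of detecting a nest at least once in a session
#'
#' For per-flyover detection probabilities `p_1..p_T`, the chance a nest is
#' detected on at least one flyover is `1 - prod(1 - p_t)`: the effective
#' sampling fraction of a multi-flyover session.
#'
#' @param p_vector per-occasion detection probabilities, all in \[0, 1\].
#' @return a probability.
#' @examples
#' session_detection(c(0.6, 0.6, 0.6))  # 0.936
#' @export
session_detection <- function(p_vector) {
  if (!is.numeric(p_vector) || length(p_vector) < 1L || !is_prob(p_vector)) {
    stop_contract("'p_vector' must be probabilities in [0, 1]")
  }
  1 - prod(1 - p_vector)
}

#' Fit and rank the four closed models by AIC
#'
#' Fits all four members of [closed_model_set()] and sorts by AIC
#' (ascending). `AIC = -2 logLik + 2 K`. Ties are broken by smaller `K`,
#' then by the canonical model-set order (constant before time-dependent,
#' no colony effect before additive).
#'
#' @param dataset a [capture_dataset()].
#' @param options passed to [fit_closed()].
#' @return An object of class `closed_model_ranking`: list with `fits`
#'   (sorted), and `table` (data.frame: model, K, logLik, AIC, dAIC,
#'   converged).
#' @export
rank_models <- function(dataset, options = list()) {
  specs <- closed_model_set()
  fits <- lapply(specs, function(s) fit_closed(dataset, s, options))
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  K <- vapply(fits, `[[`, numeric(1), "K")
  ord <- order(aic, K, seq_along(fits))
  fits <- fits[ord]
  aic <- aic[ord]
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$name, character(1)),
    K = vapply(fits, `[[`, numeric(1), "K"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AIC = aic,
    dAIC = aic - min(aic),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  structure(list(fits = fits, table = tab), class = "closed_model_ranking")
}

#' @export
print.closed_model_ranking <- function(x, ...) {
  cat("Closed-model AIC ranking:\n")
  tab <- x$table
  tab$logLik <- round(tab$logLik, 3)
  tab$AIC <- round(tab$AIC, 2)
  tab$dAIC <- round(tab$dAIC, 2)
  print(tab)
  invisible(x)
}
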