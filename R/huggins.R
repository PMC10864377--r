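#' Huggins conditional-likelihood fit with Horvitz-Thompson abundance
#'
#' Independent cross-check for [fit_closed()]: detection parameters are
#' estimated from the likelihood conditional on a nest being detected at
#' least once, which does not involve `f0`, and abundance follows by
#' Horvitz-Thompson: `N_hat_g = n_g / (1 - prod_t(1 - p_hat[t,g]))`.
#'
#' For observed nest `i` with history `y_it` the conditional likelihood is
#' `prod_t p_t^y (1-p_t)^(1-y) / (1 - prod_t (1 - p_t))`; the same logit
#' linear predictor structures as in [closed_model_spec()] apply.
#'
#' @param dataset a [capture_dataset()] with `T >= 2`.
#' @param spec a [closed_model_spec()]; its `f0` block is ignored.
#' @param options list with `n_starts`, `tol`, `max_iter`, `seed` as in
#'   [fit_closed()].
#' @return list with `p_hat` (T x G matrix), `N_hat` (per colony),
#'   `pstar` (per-colony session detection probability), `logLik`
#'   (conditional), `converged`.
#' @export
huggins_fit <- function(dataset, spec = closed_model_spec(), options = list()) {
  stopifnot(inherits(dataset, "capture_dataset"))
  if (nrow(dataset$histories) == 0L) {
    stop_contract("empty dataset: no observed nests to fit")
  }
  if (dataset$occasions < 2L) {
    stop_contract("closed models need at least 2 occasions")
  }
  ss <- suff_stats(dataset)
  if (any(ss$n < 1L)) {
    stop_contract("every colony must have at least one observed nest")
  }
  des <- spec_design(spec, ss$T, ss$G)
  opts <- utils::modifyList(
    list(n_starts = 3L, tol = 1e-10, max_iter = 500L, seed = 1L), options)
  kpar <- des$kp + des$kc

  fn <- function(b) {
    eta <- pmin(pmax(des$X %*% b, -ETA_CAP), ETA_CAP)
    p <- matrix(stats::plogis(eta), ss$T, ss$G)
    p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
    log_q <- colSums(log1p(-p))            # log prod (1-p) per colony
    log_pstar <- log1p(-exp(log_q))
    nmat <- matrix(ss$n, ss$T, ss$G, byrow = TRUE)
    ll <- sum(ss$x * log(p) + (nmat - ss$x) * log1p(-p)) -
      sum(ss$n * log_pstar)
    -ll
  }
  gr <- function(b) {
    eta <- pmin(pmax(des$X %*% b, -ETA_CAP), ETA_CAP)
    p <- matrix(stats::plogis(eta), ss$T, ss$G)
    p <- pmin(pmax(p, P_EPS), 1 - P_EPS)
    q <- exp(colSums(log1p(-p)))           # prod (1-p) per colony
    pstar <- 1 - q
    nmat <- matrix(ss$n, ss$T, ss$G, byrow = TRUE)
    qmat <- matrix(q / pstar, ss$T, ss$G, byrow = TRUE)
    d_eta <- ss$x - nmat * p - nmat * qmat * p
    -as.numeric(crossprod(des$X, as.numeric(d_eta)))
  }

  p0 <- min(max(sum(ss$x) / (ss$T * ss$n_total), 0.05), 0.95)
  base <- c(rep(logit(p0), des$kp), rep(0, des$kc))
  starts <- list(base)
  if (opts$n_starts > 1L) {
    starts <- c(starts, with_seed(opts$seed, lapply(
      seq_len(opts$n_starts - 1L), function(s) base + stats::rnorm(kpar))))
  }
  best <- NULL
  for (st in starts) {
    res <- tryCatch(
      stats::optim(st, fn, gr, method = "BFGS",
                   control = list(maxit = opts$max_iter,
                                  reltol = max(opts$tol, 1e-14))),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop_contract("all optimizer starts failed")

  eta <- as.numeric(des$X %*% best$par)
  p_hat <- matrix(stats::plogis(pmin(pmax(eta, -ETA_CAP), ETA_CAP)), ss$T, ss$G,
                  dimnames = list(NULL, ss$labels))
  pstar <- apply(p_hat, 2L, session_detection)
  N_hat <- as.numeric(ss$n) / pstar
  list(p_hat = p_hat,
       N_hat = stats::setNames(N_hat, ss$labels),
       pstar = stats::setNames(pstar, ss$labels),
       n = stats::setNames(as.numeric(ss$n), ss$labels),
       logLik = -best$value,
       converged = best$convergence == 0L)
}
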