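#' Configuration of the simulation power analysis
#'
#' Defines the grid of survey designs to evaluate: per-flyover detection
#' probability, numbers of flyovers, colony sizes, replicates per cell, the
#' decline grid, confidence level and power threshold. Defaults follow the
#' canonical design question for drone-surveyed heron colonies: p = 0.60,
#' 2-5 flyovers, 50-200 nests, 100 replicates per cell, declines of 1-20%,
#' 95% intervals and an 80% power bar.
#'
#' @param p per-flyover detection probability in (0, 1).
#' @param flyover_counts integer vector of occasion numbers (each >= 2).
#' @param colony_sizes integer vector of true colony sizes.
#' @param n_sim replicates per (flyovers, size) cell.
#' @param decline_grid percent declines to test, each in (0, 100).
#' @param ci_level,power_threshold probabilities in (0, 1).
#' @param seed root seed; every cell and replicate uses a deterministic
#'   substream so results are bit-reproducible.
#' @return object of class `power_config`.
#' @export
power_config <- function(p = 0.60, flyover_counts = 2:5,
                         colony_sizes = c(50L, 100L, 150L, 200L),
                         n_sim = 100L, decline_grid = 1:20,
                         ci_level = 0.95, power_threshold = 0.80,
                         seed = 1L) {
  if (!is_prob(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop_contract("'p' must be strictly between 0 and 1")
  }
  if (length(flyover_counts) == 0L || any(flyover_counts < 2) ||
      any(flyover_counts != floor(flyover_counts))) {
    stop_contract("'flyover_counts' must be integers >= 2")
  }
  if (length(colony_sizes) == 0L || any(colony_sizes < 1) ||
      any(colony_sizes != floor(colony_sizes))) {
    stop_contract("'colony_sizes' must be positive integers")
  }
  if (!is_count(n_sim)) stop_contract("'n_sim' must be a positive integer")
  if (length(decline_grid) == 0L || any(decline_grid <= 0) ||
      any(decline_grid >= 100)) {
    stop_contract("'decline_grid' must be percentages in (0, 100)")
  }
  for (nm in c("ci_level", "power_threshold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      stop_contract("'", nm, "' must be strictly between 0 and 1")
    }
  }
  structure(list(p = p, flyover_counts = as.integer(sort(flyover_counts)),
                 colony_sizes = as.integer(sort(colony_sizes)),
                 n_sim = as.integer(n_sim),
                 decline_grid = sort(as.numeric(decline_grid)),
                 ci_level = ci_level, power_threshold = power_threshold,
                 seed = as.integer(seed)),
            class = "power_config")
}

#' Simulate one capture-history dataset at constant detection probability
#'
#' Independent Bernoulli(p) detections for `N` nests over `T` occasions;
#' all-zero rows (never-detected nests) are dropped, as in the field. The
#' expected record count is `N * (1 - (1-p)^T)`.
#'
#' @param N true number of nests (>= 1).
#' @param T number of occasions (>= 2).
#' @param p per-occasion detection probability in (0, 1).
#' @param seed integer seed; identical seeds give identical datasets.
#' @return a [capture_dataset()] (possibly with zero records for tiny
#'   `N * p`).
#' @export
simulate_histories <- function(N, T, p, seed = 1L) {
  if (!is_count(N)) stop_contract("'N' must be a positive integer")
  if (!is_count(T) || T < 2) stop_contract("'T' must be an integer >= 2")
  if (!is_prob(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop_contract("'p' must be strictly between 0 and 1")
  }
  det <- with_seed(seed, matrix(stats::rbinom(N * T, 1L, p), N, T))
  keep <- rowSums(det) > 0L
  capture_dataset(det[keep, , drop = FALSE],
                  colony = rep("sim", sum(keep)),
                  nest_id = sprintf("sim_%05d", which(keep)),
                  colony_levels = "sim")
}

#' Simulate and fit replicate surveys of one design cell
#'
#' Draws `n_sim` independent datasets with [simulate_histories()] (each on
#' its own deterministic substream of `seed`) and fits the constant
#' one-colony closed model to each. Failed fits (optimizer failure, empty
#' dataset, unusable Hessian off the boundary) are flagged, never silently
#' dropped.
#'
#' @inheritParams simulate_histories
#' @param n_sim number of replicates.
#' @param fit_options options for [fit_closed()]; default single
#'   moment-based start (ample for the two-parameter constant model).
#' @return list of length `n_sim`; each element has `fit` (a `closed_fit`
#'   or `NULL`) and `converged` (logical).
#' @export
replicate_fits <- function(N, T, p, n_sim, seed = 1L,
                           fit_options = list(n_starts = 1L)) {
  if (!is_count(n_sim)) stop_contract("'n_sim' must be a positive integer")
  seeds <- substream_seeds(seed, n_sim)
  spec <- closed_model_spec("constant", "none")
  lapply(seq_len(n_sim), function(i) {
    fit <- tryCatch({
      d <- simulate_histories(N, T, p, seed = seeds[i])
      fit_closed(d, spec, options = c(fit_options, list(seed = seeds[i])))
    }, error = function(e) NULL)
    ok <- !is.null(fit) && isTRUE(fit$converged) &&
      (all(fit$f0_boundary) || all(is.finite(fit$se_f0)))
    list(fit = fit, converged = ok)
  })
}

rep_fits_only <- function(reps) {
  lapply(Filter(function(r) r$converged, reps), `[[`, "fit")
}

#' Mean coefficient of variation of the abundance estimate
#'
#' Default (`mode = "expected"`): the mean over converged replicates of
#' `SE(N_hat) / N_hat`, with `SE(N_hat) = SE(f0_hat)` since the observed
#' count is fixed — the precision a practitioner would see from a single
#' survey. `mode = "empirical"` instead returns `sd(N_hat) / mean(N_hat)`
#' across replicates. For multi-colony fits the total abundance and the
#' independence-based SE of the total are used.
#'
#' @param fits list of `closed_fit` objects, or the output of
#'   [replicate_fits()] (non-converged replicates are excluded).
#' @param mode `"expected"` or `"empirical"`.
#' @return a single CV value.
#' @export
mean_cv <- function(fits, mode = c("expected", "empirical")) {
  mode <- match.arg(mode)
  fits <- as_fit_list(fits)
  if (length(fits) == 0L) stop_contract("no converged fits to summarize")
  Nh <- vapply(fits, function(f) sum(f$N_hat), numeric(1))
  se <- vapply(fits, function(f) sqrt(sum(f$se_f0^2)), numeric(1))
  if (mode == "expected") mean(se / Nh) else stats::sd(Nh) / mean(Nh)
}

as_fit_list <- function(fits) {
  if (length(fits) > 0L && is.list(fits[[1L]]) &&
      !inherits(fits[[1L]], "closed_fit") && "converged" %in% names(fits[[1L]])) {
    fits <- rep_fits_only(fits)
  }
  stopifnot(all(vapply(fits, inherits, logical(1), "closed_fit")))
  fits
}

#' Power to detect a decline by CI exclusion
#'
#' Proportion of converged replicates whose abundance confidence interval
#' excludes the declined value `N_true * (1 - decline/100)`. The default
#' rule is one-sided in the decline direction: the interval's lower bound
#' must exceed the declined value (the survey would not mistake the current
#' population for one `decline`% smaller). `rule = "two_sided"` also counts
#' replicates whose upper bound falls below the declined value.
#'
#' @param fits as in [mean_cv()].
#' @param N_true true (reference) abundance the data were simulated at.
#' @param decline percent decline(s), each in (0, 100); vectorized.
#' @param ci_level confidence level for the interval.
#' @param rule `"one_sided"` (default) or `"two_sided"`.
#' @return named numeric vector of power values, one per decline.
#' @export
decline_power <- function(fits, N_true, decline, ci_level = 0.95,
                          rule = c("one_sided", "two_sided")) {
  rule <- match.arg(rule)
  fits <- as_fit_list(fits)
  if (length(fits) == 0L) stop_contract("no converged fits to summarize")
  if (any(decline <= 0 | decline >= 100)) {
    stop_contract("'decline' must be in (0, 100) percent")
  }
  ci <- lapply(fits, function(f) {
    a <- abundance_ci(f, level = ci_level)
    c(lower = sum(a$lower), upper = sum(a$upper))
  })
  lo <- vapply(ci, `[[`, numeric(1), "lower")
  hi <- vapply(ci, `[[`, numeric(1), "upper")
  out <- vapply(decline, function(d) {
    val <- N_true * (1 - d / 100)
    excl <- lo > val
    if (rule == "two_sided") excl <- excl | (hi < val)
    mean(excl)
  }, numeric(1))
  stats::setNames(out, paste0(decline, "%"))
}

#' Minimum detectable decline at a power threshold
#'
#' Smallest decline on the evaluated grid whose CI-exclusion power reaches
#' the threshold; `NA` if none does ("none within grid").
#'
#' @param power_by_decline named numeric vector as returned by
#'   [decline_power()] (names `"d%"`) or with plain numeric names.
#' @param threshold power threshold, default 0.80.
#' @return the decline percentage, or `NA_real_`.
#' @examples
#' min_detectable_decline(c("15%" = 0.78, "16%" = 0.85, "17%" = 0.9))  # 16
#' @export
min_detectable_decline <- function(power_by_decline, threshold = 0.80) {
  if (length(power_by_decline) == 0L) {
    stop_contract("'power_by_decline' must be non-empty")
  }
  d <- as.numeric(sub("%", "", names(power_by_decline) %||%
                        seq_along(power_by_decline), fixed = TRUE))
  if (anyNA(d)) stop_contract("decline names must be numeric percentages")
  ord <- order(d)
  d <- d[ord]; pw <- as.numeric(power_by_decline)[ord]
  hit <- which(pw >= threshold)
  if (length(hit) == 0L) NA_real_ else d[hit[1L]]
}

#' Run the full simulation power grid
#'
#' For every (flyovers, colony size) cell: simulate `n_sim` surveys at the
#' configured detection probability, fit the constant closed model, and
#' summarize the mean CV of the abundance estimate, the CI-exclusion power
#' curve over the decline grid, and the minimum detectable decline at the
#' power threshold. Cells where more than half the fits fail are flagged.
#'
#' @param config a [power_config()].
#' @param rule decline-exclusion rule, see [decline_power()].
#' @return object of class `power_grid_result`: list with `summary`
#'   (data.frame: flyovers, colony_size, n_converged, mean_cv,
#'   min_detectable_decline, flagged), `curves` (data.frame: flyovers,
#'   colony_size, decline_pct, power) and `config`.
#' @export
power_grid <- function(config = power_config(), rule = "one_sided") {
  stopifnot(inherits(config, "power_config"))
  cells <- expand.grid(T = config$flyover_counts, N = config$colony_sizes,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- substream_seeds(config$seed, nrow(cells))
  summ <- vector("list", nrow(cells))
  curves <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    T <- cells$T[i]; N <- cells$N[i]
    reps <- replicate_fits(N, T, config$p, config$n_sim, seed = seeds[i])
    fits <- rep_fits_only(reps)
    ncv <- length(fits)
    if (ncv == 0L) {
      summ[[i]] <- data.frame(flyovers = T, colony_size = N, n_converged = 0L,
                              mean_cv = NA_real_,
                              min_detectable_decline = NA_real_,
                              flagged = TRUE)
      next
    }
    cv <- mean_cv(fits)
    pw <- decline_power(fits, N_true = N, decline = config$decline_grid,
                        ci_level = config$ci_level, rule = rule)
    mdd <- min_detectable_decline(pw, config$power_threshold)
    summ[[i]] <- data.frame(flyovers = T, colony_size = N, n_converged = ncv,
                            mean_cv = cv, min_detectable_decline = mdd,
                            flagged = ncv < config$n_sim / 2)
    curves[[i]] <- data.frame(flyovers = T, colony_size = N,
                              decline_pct = config$decline_grid,
                              power = as.numeric(pw))
  }
  structure(list(summary = do.call(rbind, summ),
                 curves = do.call(rbind, curves),
                 config = config),
            class = "power_grid_result")
}

#' @export
print.power_grid_result <- function(x, ...) {
  cat("Simulation power grid (p =", x$config$p, ",", x$config$n_sim,
      "replicates/cell):\n")
  s <- x$summary
  s$mean_cv <- round(s$mean_cv, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write tidy CSV tables of a power-grid result
#' @param result a `power_grid_result`.
#' @param dir output directory (created if needed).
#' @return paths of `power_summary.csv` and `power_curves.csv`, invisibly.
#' @export
write_power_tables <- function(result, dir) {
  stopifnot(inherits(result, "power_grid_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "power_summary.csv")
  p2 <- file.path(dir, "power_curves.csv")
  utils::write.csv(result$summary, p1, row.names = FALSE)
  utils::write.csv(result$curves, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
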