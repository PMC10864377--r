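CAUSE_LEVELS <- c("cut", "absence", "occlusion", "misidentification",
                  "observer_miss")

#' Configuration of a synthetic breeding colony
#'
#' Describes the staged detection process of one colony over the flyovers of
#' a closed session. At each occasion a nest is detected only if every stage
#' succeeds, in order: the nest is not cut off when the flyover's photos are
#' stitched into one image (probability `1 - cut_prob`); a bird is present
#' on the active nest (`presence_prob`, possibly occasion-specific to mimic
#' diurnal attendance variation); the nest is available, i.e. not hidden by
#' image luminosity or tree branches (`availability_prob`); the bird is
#' distinguishable from a co-occurring look-alike species such as the cattle
#' egret (`identify_prob`); and the image interpreter actually detects it
#' (`observer_prob`). The implied per-occasion detection probability is
#' `p_t = (1 - cut_prob) * presence_prob_t * availability_prob *
#' identify_prob * observer_prob`.
#'
#' @param n_nests true number of active nests (the quantity the closed
#'   models try to recover).
#' @param presence_prob scalar or per-occasion vector of attendance
#'   probabilities; its length sets the number of occasions unless
#'   `occasion_labels` is given.
#' @param availability_prob,identify_prob,observer_prob,cut_prob scalar
#'   stage probabilities in \[0, 1\].
#' @param occasion_labels optional labels (e.g. hours or days), one per
#'   flyover.
#' @param persistent_occlusion if `TRUE`, availability is drawn once per
#'   nest and held fixed across occasions (a branch-hidden nest stays
#'   hidden), inducing detection heterogeneity that violates the closed
#'   models' independence assumption; default `FALSE` redraws it per
#'   occasion.
#' @param seed integer seed for [simulate_colony()].
#' @return object of class `colony_config`.
#' @seealso [calibrate_cause_config()] for a config whose non-detection
#'   cause mix matches target proportions.
#' @export
colony_config <- function(n_nests, presence_prob, availability_prob = 1,
                          identify_prob = 1, observer_prob = 1, cut_prob = 0,
                          occasion_labels = NULL, persistent_occlusion = FALSE,
                          seed = 1L) {
  if (!is_count(n_nests)) stop_contract("'n_nests' must be a positive integer")
  if (!is.null(occasion_labels)) {
    T <- length(occasion_labels)
    if (length(presence_prob) == 1L) presence_prob <- rep(presence_prob, T)
    if (length(presence_prob) != T) {
      stop_contract("'presence_prob' must have one entry per occasion label")
    }
  } else {
    T <- length(presence_prob)
    occasion_labels <- as.character(seq_len(T))
  }
  if (T < 1L) stop_contract("at least one occasion is required")
  for (nm in c("presence_prob", "availability_prob", "identify_prob",
               "observer_prob", "cut_prob")) {
    v <- get(nm)
    if (!is_prob(v)) stop_contract("'", nm, "' must be in [0, 1]")
  }
  if (length(availability_prob) != 1L || length(identify_prob) != 1L ||
      length(observer_prob) != 1L || length(cut_prob) != 1L) {
    stop_contract("stage probabilities other than presence must be scalars")
  }
  structure(list(n_nests = as.integer(n_nests),
                 occasion_labels = occasion_labels,
                 presence_prob = as.numeric(presence_prob),
                 availability_prob = availability_prob,
                 identify_prob = identify_prob,
                 observer_prob = observer_prob,
                 cut_prob = cut_prob,
                 persistent_occlusion = isTRUE(persistent_occlusion),
                 seed = as.integer(seed)),
            class = "colony_config")
}

#' Per-occasion detection probability implied by a colony config
#' @param config a [colony_config()].
#' @return numeric vector `p_t = (1 - c) * pi_t * a * q * o`.
#' @export
implied_detection <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  (1 - config$cut_prob) * config$presence_prob * config$availability_prob *
    config$identify_prob * config$observer_prob
}

#' Analytic non-detection cause probabilities of a config
#'
#' Conditional on a (nest, occasion) non-detection event, the probability of
#' each cause under first-failed-stage attribution, averaged over occasions
#' weighted by each occasion's non-detection probability. Stages fail in
#' the fixed order cut, absence, occlusion, misidentification,
#' observer_miss, so the cause mix is analytic in the stage probabilities.
#'
#' @param config a [colony_config()].
#' @return named numeric vector over the five causes, summing to 1 (all
#'   `NaN` if detection is perfect).
#' @export
analytic_cause_props <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  c0 <- config$cut_prob; a <- config$availability_prob
  q <- config$identify_prob; o <- config$observer_prob
  pi_t <- config$presence_prob
  # per occasion, unconditional cause probabilities
  probs <- vapply(pi_t, function(pi) {
    c(cut = c0,
      absence = (1 - c0) * (1 - pi),
      occlusion = (1 - c0) * pi * (1 - a),
      misidentification = (1 - c0) * pi * a * (1 - q),
      observer_miss = (1 - c0) * pi * a * q * (1 - o))
  }, numeric(5))
  tot <- rowSums(probs)           # summed over occasions (equal nest weight)
  tot / sum(tot)
}

#' Calibrate a colony config to target cause proportions
#'
#' Solves for the five stage probabilities so that (i) the per-occasion
#' detection probability equals `target_p` and (ii) the analytic
#' non-detection cause mix equals `cause_props`. The system solves
#' sequentially: with `q0 = 1 - target_p`, `cut = prop_cut * q0`, then each
#' downstream stage's failure probability follows from its target share of
#' `q0` divided by the probability of reaching that stage.
#'
#' @param target_p per-occasion detection probability the config should
#'   imply (default 0.60, a typical drone-survey value for canopy-breeding
#'   colonies).
#' @param cause_props named proportions for `cut`, `absence`, `occlusion`,
#'   `misidentification`, `observer_miss`; must sum to 1. Default 5/20/33/31/11%.
#' @param n_nests,n_occasions,seed passed through to [colony_config()].
#' @return a [colony_config()] with constant presence probability.
#' @export
calibrate_cause_config <- function(target_p = 0.60,
                                   cause_props = c(cut = 0.05, absence = 0.20,
                                                   occlusion = 0.33,
                                                   misidentification = 0.31,
                                                   observer_miss = 0.11),
                                   n_nests = 100L, n_occasions = 3L,
                                   seed = 1L) {
  if (!is_prob(target_p) || length(target_p) != 1L || target_p <= 0 ||
      target_p >= 1) {
    stop_contract("'target_p' must be strictly between 0 and 1")
  }
  if (!all(CAUSE_LEVELS %in% names(cause_props))) {
    stop_contract("'cause_props' must be named with: ",
                  paste(CAUSE_LEVELS, collapse = ", "))
  }
  cause_props <- cause_props[CAUSE_LEVELS]
  if (abs(sum(cause_props) - 1) > 1e-9 || any(cause_props < 0)) {
    stop_contract("'cause_props' must be non-negative and sum to 1")
  }
  q0 <- 1 - target_p
  cut <- cause_props[["cut"]] * q0
  reach <- 1 - cut                       # P(not cut)
  pi <- 1 - cause_props[["absence"]] * q0 / reach
  reach <- reach * pi
  a <- 1 - cause_props[["occlusion"]] * q0 / reach
  reach <- reach * a
  q <- 1 - cause_props[["misidentification"]] * q0 / reach
  reach <- reach * q
  o <- 1 - cause_props[["observer_miss"]] * q0 / reach
  stages <- c(cut = cut, presence = pi, availability = a, identify = q,
              observer = o)
  if (!is_prob(stages)) {
    stop_contract("cause proportions are not attainable at target_p = ",
                  target_p)
  }
  colony_config(n_nests = n_nests, presence_prob = rep(pi, n_occasions),
                availability_prob = a, identify_prob = q, observer_prob = o,
                cut_prob = cut, seed = seed)
}

#' Diurnal nest-attendance profile with a late-morning dip
#'
#' Gaussian-dip attendance curve
#' `pi(h) = base * (1 - dip_depth * exp(-(h - dip_center)^2 /
#' (2 * dip_width^2)))`, emulating the drop in colony attendance (and hence
#' nest availability for detection) typically seen in late morning when
#' adults forage away from the colony.
#'
#' @param hour numeric hour(s) of day in \[0, 24\].
#' @param profile list with `base` and `dip_depth` in \[0, 1\],
#'   `dip_center` (hour) and `dip_width` (> 0, hours).
#' @return presence probability(ies) in \[0, base\].
#' @examples
#' diurnal_presence(10, list(base = 0.9, dip_depth = 0.3,
#'                           dip_center = 10, dip_width = 1.5))  # 0.63
#' @export
diurnal_presence <- function(hour, profile) {
  need <- c("base", "dip_center", "dip_depth", "dip_width")
  if (!all(need %in% names(profile))) {
    stop_contract("'profile' needs: ", paste(need, collapse = ", "))
  }
  if (!is_prob(profile$base) || !is_prob(profile$dip_depth)) {
    stop_contract("'base' and 'dip_depth' must be in [0, 1]")
  }
  if (!is.numeric(profile$dip_width) || profile$dip_width <= 0) {
    stop_contract("'dip_width' must be positive")
  }
  if (!is.numeric(hour) || any(hour < 0 | hour > 24)) {
    stop_contract("'hour' must be in [0, 24]")
  }
  profile$base * (1 - profile$dip_depth *
                    exp(-(hour - profile$dip_center)^2 /
                          (2 * profile$dip_width^2)))
}

#' Simulate a colony's latent detection process
#'
#' Draws the five stage outcomes for every (nest, occasion) cell and derives
#' detections and cause-labelled non-detections. All stages are drawn
#' independently per cell (availability per nest instead when
#' `persistent_occlusion` is set) and a cell is detected only when every
#' stage succeeds; each non-detection is attributed to the first failed
#' stage in the order cut, absence, occlusion, misidentification,
#' observer_miss, giving every non-detection exactly one cause.
#'
#' @param config a [colony_config()].
#' @return object of class `synthetic_colony`: list with `config`, `truth`
#'   (true nest count), `detected` (n x T 0/1 matrix), `stages` (list of
#'   n x T logical matrices: `cut`, `present`, `available`, `identifiable`,
#'   `observed`), and `cause` (n x T character matrix, `NA` where detected).
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "colony_config"))
  n <- config$n_nests
  T <- length(config$presence_prob)
  with_seed(config$seed, {
    cut <- matrix(stats::runif(n * T) < config$cut_prob, n, T)
    present <- matrix(stats::runif(n * T) <
                        rep(config$presence_prob, each = n), n, T)
    if (config$persistent_occlusion) {
      avail <- matrix(stats::runif(n) < config$availability_prob, n, T)
    } else {
      avail <- matrix(stats::runif(n * T) < config$availability_prob, n, T)
    }
    ident <- matrix(stats::runif(n * T) < config$identify_prob, n, T)
    obs <- matrix(stats::runif(n * T) < config$observer_prob, n, T)

    detected <- (!cut) & present & avail & ident & obs
    cause <- matrix(NA_character_, n, T)
    cause[!detected & cut] <- "cut"
    cause[!detected & !cut & !present] <- "absence"
    cause[!detected & !cut & present & !avail] <- "occlusion"
    cause[!detected & !cut & present & avail & !ident] <- "misidentification"
    cause[!detected & !cut & present & avail & ident & !obs] <- "observer_miss"

    structure(list(config = config, truth = n,
                   detected = matrix(as.integer(detected), n, T),
                   stages = list(cut = cut, present = present,
                                 available = avail, identifiable = ident,
                                 observed = obs),
                   cause = cause),
              class = "synthetic_colony")
  })
}

#' @export
print.synthetic_colony <- function(x, ...) {
  seen <- sum(rowSums(x$detected) > 0)
  cat("Synthetic colony: true N =", x$truth, "| occasions =",
      ncol(x$detected), "| nests detected >= once:", seen, "\n")
  cat("Implied per-occasion p:",
      paste(round(implied_detection(x$config), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the observable capture dataset from simulated colonies
#'
#' Applies the field definition of an active nest: only nests detected on at
#' least one flyover enter the capture dataset; the rest are the latent `f0`
#' the closed models estimate. Returns the true per-colony nest counts
#' alongside, for recovery checks.
#'
#' @param colonies a `synthetic_colony` or list of them, sharing the same
#'   number of occasions.
#' @param colony_labels labels, one per colony; default `"A"`, `"B"`, ...
#' @return list with `dataset` (a [capture_dataset()]; it may contain zero
#'   records if nothing was detected, in which case fitting refuses it) and
#'   `truth` (named numeric vector of true N per colony).
#' @export
extract_dataset <- function(colonies, colony_labels = NULL) {
  if (inherits(colonies, "synthetic_colony")) colonies <- list(colonies)
  stopifnot(length(colonies) >= 1L,
            all(vapply(colonies, inherits, logical(1), "synthetic_colony")))
  Ts <- vapply(colonies, function(z) ncol(z$detected), integer(1))
  if (length(unique(Ts)) != 1L) {
    stop_contract("all colonies must share the same number of occasions")
  }
  if (is.null(colony_labels)) {
    colony_labels <- make.unique(LETTERS[(seq_along(colonies) - 1L) %% 26L + 1L])
  }
  if (length(colony_labels) != length(colonies)) {
    stop_contract("'colony_labels' must have one label per colony")
  }
  hist <- NULL; col <- character(); ids <- character()
  for (i in seq_along(colonies)) {
    det <- colonies[[i]]$detected
    keep <- rowSums(det) > 0L
    if (any(keep)) {
      h <- det[keep, , drop = FALSE]
      hist <- rbind(hist, h)
      col <- c(col, rep(colony_labels[i], nrow(h)))
      ids <- c(ids, sprintf("%s_%04d", colony_labels[i], which(keep)))
    }
  }
  if (is.null(hist)) hist <- matrix(integer(), 0L, Ts[1L])
  truth <- stats::setNames(vapply(colonies, `[[`, numeric(1), "truth"),
                           colony_labels)
  list(dataset = capture_dataset(hist, colony = col, nest_id = ids,
                                 colony_levels = colony_labels),
       truth = truth)
}

#' Tabulate non-detection events by cause
#'
#' Counts the (nest, occasion) non-detection events of a simulated colony by
#' attributed cause. With `restrict_to_observed = TRUE` (the field
#' situation: causes can only be assessed for nests whose location is known
#' from some flyover) only nests detected at least once contribute events.
#'
#' @param colony a `synthetic_colony`.
#' @param restrict_to_observed logical; default `TRUE`.
#' @return object of class `nondetection_table`: list with `counts` and
#'   `proportions` (named over the five causes), `total`, and
#'   `proportions_defined` (`FALSE` with `NA` proportions when there are no
#'   events).
#' @export
tabulate_nondetection_causes <- function(colony, restrict_to_observed = TRUE) {
  stopifnot(inherits(colony, "synthetic_colony"))
  cause <- colony$cause
  if (restrict_to_observed) {
    cause <- cause[rowSums(colony$detected) > 0L, , drop = FALSE]
  }
  events <- cause[!is.na(cause)]
  counts <- table(factor(events, levels = CAUSE_LEVELS))
  total <- sum(counts)
  props <- if (total > 0L) as.numeric(counts) / total else rep(NA_real_, 5L)
  structure(list(counts = stats::setNames(as.integer(counts), CAUSE_LEVELS),
                 proportions = stats::setNames(props, CAUSE_LEVELS),
                 total = as.integer(total),
                 proportions_defined = total > 0L),
            class = "nondetection_table")
}

#' @export
print.nondetection_table <- function(x, ...) {
  cat("Non-detection events by cause (n =", x$total, "):\n")
  df <- data.frame(cause = CAUSE_LEVELS, count = x$counts,
                   proportion = round(x$proportions, 3), row.names = NULL)
  print(df)
  if (!x$proportions_defined) cat("(no events: proportions undefined)\n")
  invisible(x)
}

#' Select the reproduction peak session
#'
#' Given raw per-flyover nest counts for several candidate sessions, returns
#' the session whose single best flyover counted the most nests — the
#' "reproduction peak session" retained for capture-recapture analysis.
#' Ties go to the earliest session.
#'
#' @param session_counts list with one numeric vector of per-flyover counts
#'   per session.
#' @return integer session index.
#' @examples
#' select_peak_session(list(c(40, 55, 50), c(60, 48), c(20, 30, 25)))  # 2
#' @export
select_peak_session <- function(session_counts) {
  if (!is.list(session_counts) || length(session_counts) == 0L) {
    stop_contract("'session_counts' must be a non-empty list")
  }
  maxima <- vapply(session_counts, function(v) {
    if (!is.numeric(v) || length(v) == 0L) {
      stop_contract("each session needs at least one flyover count")
    }
    max(v)
  }, numeric(1))
  which.max(maxima)   # earliest index on ties
}
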