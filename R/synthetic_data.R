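#' Specify a synthetic survival network
#'
#' Describes a multi-design trial network with known truth: per-trial Weibull
#' (or explicit spline) baseline cumulative hazards, fixed true log hazard
#' ratios on the basic contrasts, optional treatment-ln(time) drift
#' (non-proportional hazards applied on the cumulative-hazard scale, exactly
#' as the fitted model assumes), between-trial heterogeneity, per-loop
#' inconsistency offsets, and administrative plus exponential-dropout
#' censoring.
#'
#' @param network an [network_spec()].
#' @param trials data.frame with columns `trial`, and `design` (index into
#'   `network$designs`); or an integer vector of trial counts per design.
#' @param n_per_arm patients per arm (scalar or per-trial vector).
#' @param baseline list per trial: `list(lambda=, p=)` for Weibull H0 =
#'   lambda * t^p, or `list(gamma=, knots=)` for an explicit raw-basis spline
#'   log H0; recycled if length 1.
#' @param true_beta numeric length q: true log hazard ratios on the basic
#'   contrasts.
#' @param true_alpha numeric length q: treatment-ln(time) drift coefficients.
#' @param heterogeneity q x q between-trial covariance of the trial effect
#'   vectors (0 for none).
#' @param inconsistency named numeric: per-loop offset delta added to the
#'   loop-closing design's non-reference arm.
#' @param censor_horizon administrative censoring time (same unit as the
#'   baseline scale).
#' @param dropout_rate exponential dropout rate.
#' @param seed integer; per-trial substreams are derived deterministically.
#' @return list of class `rp_sim_spec`.
#' @export
sim_spec <- function(network, trials, n_per_arm = 50,
                     baseline = list(list(lambda = 0.2, p = 1.2)),
                     true_beta = numeric(n_basic(network)),
                     true_alpha = numeric(n_basic(network)),
                     heterogeneity = NULL, inconsistency = NULL,
                     censor_horizon = 5, dropout_rate = 0.02, seed = 1L) {
  if (is.numeric(trials) && is.null(dim(trials))) {
    stopifnot(length(trials) == length(network$designs))
    if (any(trials < 0)) stop("negative trial count", call. = FALSE)
    trials <- data.frame(
      trial = paste0("T", seq_len(sum(trials))),
      design = rep(seq_along(network$designs), trials))
  }
  q <- n_basic(network)
  stopifnot(length(true_beta) == q, length(true_alpha) == q)
  if (is.null(heterogeneity)) heterogeneity <- matrix(0, q, q)
  ev <- eigen(heterogeneity, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("heterogeneity covariance is not positive semi-definite",
         call. = FALSE)
  if (censor_horizon <= 0) stop("censor_horizon must be > 0", call. = FALSE)
  n_per_arm <- rep(n_per_arm, length.out = nrow(trials))
  if (any(n_per_arm < 1)) stop("n_per_arm must be >= 1", call. = FALSE)
  baseline <- rep(baseline, length.out = nrow(trials))
  for (b in baseline)
    if (!is.null(b$lambda) && (b$lambda <= 0 || b$p <= 0))
      stop("Weibull baseline needs lambda > 0 and p > 0", call. = FALSE)
  structure(list(network = network, trials = trials, n_per_arm = n_per_arm,
                 baseline = baseline, true_beta = true_beta,
                 true_alpha = true_alpha, heterogeneity = heterogeneity,
                 inconsistency = inconsistency,
                 censor_horizon = censor_horizon,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "rp_sim_spec")
}

#' Simulate an IPD survival network with known truth
#'
#' Per trial j, a trial effect vector beta_j ~ MVN(true_beta, heterogeneity)
#' is drawn; each patient's cumulative hazard is H(t) = H0_j(t) *
#' exp(c'beta_j + inconsistency) * t^(c'alpha) with c the arm's contrast
#' vector, and the event time is found by inversion of H(T) = -ln U
#' (closed form for Weibull baselines, bracketed bisection on ln t otherwise,
#' tolerance 1e-10). Censoring is the minimum of the administrative horizon
#' and an exponential dropout time. Reproducible given the seed; per-trial
#' substreams are derived deterministically from it.
#'
#' @param spec an `rp_sim_spec`.
#' @return an `rp_ipd` with attribute `truth` recording every drawn
#'   parameter.
#' @export
simulate_network <- function(spec) {
  net <- spec$network
  q <- n_basic(net)
  chol_T <- if (max(abs(spec$heterogeneity)) > 0) {
    ev <- eigen(spec$heterogeneity, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q) %*% t(ev$vectors)
  } else NULL
  rows <- list()
  truth <- list(true_beta = spec$true_beta, true_alpha = spec$true_alpha,
                inconsistency = spec$inconsistency, beta_trial = list(),
                baseline = list())
  loop_design_keys <- vapply(net$loops, function(lp)
    paste(sort(lp[2:3]), collapse = "|"), "")
  for (r in seq_len(nrow(spec$trials))) {
    tid <- as.character(spec$trials$trial[r])
    set.seed((spec$seed %% 100000L) * 7919L + r * 104729L)
    d <- net$designs[[spec$trials$design[r]]]
    bj <- spec$true_beta
    if (!is.null(chol_T)) bj <- bj + drop(chol_T %*% stats::rnorm(q))
    truth$beta_trial[[tid]] <- bj
    bl <- spec$baseline[[r]]
    truth$baseline[[tid]] <- bl
    key <- paste(sort(d$treatments), collapse = "|")
    delta_arm <- 0
    if (!is.null(spec$inconsistency) && key %in% loop_design_keys) {
      li <- which(loop_design_keys == key)[1]
      lname <- paste(net$loops[[li]], collapse = "-")
      delta_arm <- spec$inconsistency[[lname]] %||%
        spec$inconsistency[[li]] %||% 0
    }
    n <- spec$n_per_arm[r]
    for (arm in d$treatments) {
      cvec <- build_contrasts(net, d$treatments, arm)
      lhr <- sum(cvec * bj) +
        if (arm != d$reference && delta_arm != 0) delta_arm else 0
      drift <- sum(cvec * spec$true_alpha)
      u <- stats::runif(n)
      tt <- invert_cumhaz(-log(u), bl, lhr, drift)
      cens <- pmin(spec$censor_horizon,
                   if (spec$dropout_rate > 0)
                     stats::rexp(n, spec$dropout_rate) else Inf)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tid, treatment = arm, time = pmin(tt, cens),
        event = as.numeric(tt <= cens))
    }
  }
  df <- do.call(rbind, rows)
  df$time <- pmax(df$time, 1e-12)
  out <- ipd_data(df, net)
  attr(out, "truth") <- truth
  out
}

# solve H(t) = target where ln H(t) = ln H0(t) + lhr + drift * ln t
invert_cumhaz <- function(target, baseline, lhr, drift) {
  if (!is.null(baseline$lambda)) {
    # Weibull: H(t) = lambda * t^(p + drift) * exp(lhr), closed form
    shape <- baseline$p + drift
    if (shape <= 0)
      stop("non-monotone cumulative hazard: p + c'alpha must be > 0",
           call. = FALSE)
    return((target / (baseline$lambda * exp(lhr)))^(1 / shape))
  }
  kn <- baseline$knots
  g <- baseline$gamma
  logH <- function(lx)
    drop(cbind(1, rcs_raw(lx, kn)) %*% g) + lhr + drift * lx
  vapply(target, function(tg) {
    lt <- log(tg)
    lo <- kn$boundary_min - 20; hi <- kn$boundary_max + 20
    if (logH(lo) > lt || logH(hi) < lt)
      stop("root-finding failure: target cumulative hazard ", signif(tg, 4),
           " outside the bracket", call. = FALSE)
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      if (logH(mid) < lt) lo <- mid else hi <- mid
      if (hi - lo < 1e-10) break
    }
    exp((lo + hi) / 2)
  }, 0)
}

#' Default synthetic network shaped like a cervical-cancer-style dataset
#'
#' Four treatments (RT, CTRT, CT+RT, CT+S) in four designs — three pairwise
#' comparisons against RT plus one loop-closing CT+RT vs CT+S design — with
#' scaled-down trial counts (6/5/3/1), one three-treatment loop
#' (RT, CT+RT, CT+S), and roughly `n_total` patients in all.
#'
#' @param n_total approximate total patients (split equally over arms).
#' @param trials_per_design integer vector of length 4.
#' @param true_beta true log hazard ratios (CTRT, CT+RT, CT+S vs RT).
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_spec()].
#' @return an `rp_sim_spec`.
#' @export
default_cervical_like_spec <- function(n_total = 1500,
                                       trials_per_design = c(6, 5, 3, 1),
                                       true_beta = c(-0.2, 0.1, -0.4),
                                       seed = 1L, ...) {
  stopifnot(length(trials_per_design) == 4)
  if (n_total < 2 * sum(trials_per_design))
    stop("n_total too small: some arms would have 0 patients",
         call. = FALSE)
  net <- network_spec(
    treatments = c("RT", "CTRT", "CT+RT", "CT+S"), reference = "RT",
    designs = list(c("RT", "CTRT"), c("RT", "CT+RT"), c("RT", "CT+S"),
                   list(treatments = c("CT+RT", "CT+S"),
                        reference = "CT+RT")),
    loops = list(c("RT", "CT+RT", "CT+S")))
  n_trials <- sum(trials_per_design)
  n_arm <- max(1, round(n_total / (2 * n_trials)))
  # per-trial Weibull baselines spread over plausible scales and shapes
  lam <- rep(c(0.12, 0.2, 0.3), length.out = n_trials)
  shp <- rep(c(0.9, 1.1, 1.3), length.out = n_trials)
  sim_spec(net, trials = trials_per_design, n_per_arm = n_arm,
           baseline = lapply(seq_len(n_trials), function(i)
             list(lambda = lam[i], p = shp[i])),
           true_beta = true_beta, seed = seed, ...)
}
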