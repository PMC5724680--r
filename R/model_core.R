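#' Specify a one-step survival (network) meta-analysis model
#'
#' The model gives every trial its own restricted-cubic-spline baseline log
#' cumulative hazard in ln(time), plus a treatment term coded through the
#' network's basic contrasts. Treatment effects are fixed (one log hazard
#' ratio per basic contrast) or random (trial-specific effect vectors drawn
#' from MVN(mu, T)). Proportional hazards can be relaxed through
#' treatment-ln(time) interaction coefficients, optionally with a random
#' trial-level deviation u_j added to every interaction coefficient within
#' trial j. Named treatment loops get a fixed inconsistency offset coded as
#' minus omega times the product of the two basic-contrast variables that
#' co-occur only in the loop-closing design.
#'
#' @param network an [network_spec()].
#' @param effect `"fixed"` or `"random"` treatment effects.
#' @param interactions `"none"`, `"fixed"`, or `"random"` (random-by-trial
#'   deviations on top of fixed interaction coefficients).
#' @param inconsistency list of loops (length-3 character vectors) to
#'   parameterise; each must be declared in `network$loops`.
#' @param knots optional named list, trial id -> `rp_knots`, overriding the
#'   default per-trial knot placement.
#' @param n_interior default number of interior knots per trial when `knots`
#'   does not name the trial.
#' @return object of class `rp_model`.
#' @export
model_spec <- function(network, effect = c("fixed", "random"),
                       interactions = c("none", "fixed", "random"),
                       inconsistency = list(), knots = NULL,
                       n_interior = 2L) {
  effect <- match.arg(effect)
  interactions <- match.arg(interactions)
  for (lp in inconsistency) {
    declared <- any(vapply(network$loops, identical, TRUE, y = as.character(lp)))
    if (!declared)
      stop("inconsistency loop ", paste(lp, collapse = "-"),
           " is not declared in the network's loops", call. = FALSE)
  }
  structure(list(network = network, effect = effect,
                 interactions = interactions,
                 inconsistency = inconsistency, knots = knots,
                 n_interior = as.integer(n_interior)),
            class = "rp_model")
}

#' Prior specification
#'
#' Defaults: spline coefficients gamma ~ N(0, var 10000); fixed treatment and
#' interaction coefficients ~ N(0, var 1000); inconsistency omega ~ N(0, var
#' 10); sigma_u half-normal with variance 1000; random-effect means mu ~ N(0,
#' var 1000); between-study covariance T ~ Inverse-Wishart(I_q, q).
#'
#' @param gamma_var,beta_var,beta_int_var,omega_var,sigma_u_var,mu_var prior
#'   variances.
#' @param T_df Inverse-Wishart degrees of freedom; default q (the smallest
#'   proper choice), resolved at fit time when NULL.
#' @param T_scale Inverse-Wishart scale matrix; default identity, resolved at
#'   fit time when NULL.
#' @return list of class `rp_priors`.
#' @export
prior_spec <- function(gamma_var = 10000, beta_var = 1000,
                       beta_int_var = 1000, omega_var = 10,
                       sigma_u_var = 1000, mu_var = 1000,
                       T_df = NULL, T_scale = NULL) {
  structure(list(gamma_var = gamma_var, beta_var = beta_var,
                 beta_int_var = beta_int_var, omega_var = omega_var,
                 sigma_u_var = sigma_u_var, mu_var = mu_var,
                 T_df = T_df, T_scale = T_scale),
            class = "rp_priors")
}

#' Precompute per-trial model matrices
#'
#' Evaluates each trial's spline basis (and its ln-time derivative) at that
#' trial's observation times, builds the treatment-contrast matrix from the
#' network's consistency equations, and the loop-product columns for any
#' inconsistency parameters.
#'
#' @param data an `rp_ipd` dataset.
#' @param spec an `rp_model`.
#' @param basis `"ortho"` (default) or `"raw"`: whether the spline columns
#'   are Gram-Schmidt orthogonalised per trial or left raw. Fits are invariant
#'   to this choice; orthogonalisation is a numerical-conditioning device.
#' @return list of class `rp_model_data` with per-trial blocks.
#' @export
build_model_data <- function(data, spec, basis = c("ortho", "raw")) {
  basis <- match.arg(basis)
  network <- spec$network
  q <- n_basic(network)
  L <- length(spec$inconsistency)
  loop_cols <- lapply(spec$inconsistency,
                      function(lp) loop_closing_design(network, lp)$cols)
  trial_ids <- unique(data$trial)
  trials <- vector("list", length(trial_ids))
  names(trials) <- trial_ids
  for (tid in trial_ids) {
    rows <- data[data$trial == tid, , drop = FALSE]
    lnt <- log(rows$time)
    kn <- spec$knots[[tid]]
    if (is.null(kn)) kn <- place_knots(rows, spec$n_interior)
    bs <- orthogonalise(lnt, kn)
    if (basis == "ortho") {
      B <- cbind(1, bs$ortho); dB <- cbind(0, bs$ortho_deriv)
    } else {
      B <- cbind(1, bs$raw); dB <- cbind(0, rcs_raw_deriv(lnt, kn))
    }
    design <- unique(rows$treatment)
    arm_c <- lapply(design, function(a) build_contrasts(network, design, a))
    names(arm_c) <- design
    C <- t(vapply(rows$treatment, function(a) arm_c[[a]], numeric(q)))
    if (q == 1) C <- matrix(C, ncol = 1)
    P <- matrix(0, nrow(rows), L)
    if (L > 0)
      for (l in seq_len(L))
        P[, l] <- C[, loop_cols[[l]][1]] * C[, loop_cols[[l]][2]]
    trials[[tid]] <- list(id = tid, lnt = lnt,
                          event = as.integer(rows$event), B = B, dB = dB,
                          C = C, P = P, basis = bs, knots = kn,
                          n = nrow(rows))
  }
  structure(list(trials = trials, q = q, L = L, spec = spec,
                 basis_kind = basis, n = nrow(data)),
            class = "rp_model_data")
}

# effective treatment coefficient vector for trial j
trial_b <- function(state, spec, tid) {
  if (spec$effect == "fixed") state[["beta"]] else state$beta_trial[[tid]]
}

# effective interaction coefficient vector for trial j (length 0 if none)
trial_a <- function(state, spec, tid) {
  if (spec$interactions == "none") return(numeric(0))
  a <- state$beta_int
  if (spec$interactions == "random") a <- a + state$u[[tid]]
  a
}

#' Linear predictor and its ln-time derivative for single patients
#'
#' eta is the model's log cumulative hazard: spline baseline + contrast-coded
#' treatment term + treatment-ln(time) interaction + inconsistency offset.
#' deta is d(eta)/d(ln t): the gamma-weighted basis derivative plus the
#' interaction coefficient (all non-time terms contribute zero).
#'
#' @param state parameter state (see [init_state()]).
#' @param spec an `rp_model`.
#' @param md an `rp_model_data`.
#' @param trial trial id.
#' @param rows integer row indices within the trial (default all).
#' @return list with numeric vectors `eta` and `deta`.
#' @export
linear_predictor <- function(state, spec, md, trial, rows = NULL) {
  tr <- md$trials[[trial]]
  if (is.null(rows)) rows <- seq_len(tr$n)
  b <- trial_b(state, spec, trial)
  a <- trial_a(state, spec, trial)
  eta <- drop(tr$B[rows, , drop = FALSE] %*% state$gamma[[trial]])
  deta <- drop(tr$dB[rows, , drop = FALSE] %*% state$gamma[[trial]])
  Cr <- tr$C[rows, , drop = FALSE]
  eta <- eta + drop(Cr %*% b)
  if (length(a)) {
    ca <- drop(Cr %*% a)
    eta <- eta + ca * tr$lnt[rows]
    deta <- deta + ca
  }
  if (md$L > 0)
    eta <- eta - drop(tr$P[rows, , drop = FALSE] %*% state$omega)
  list(eta = eta, deta = deta)
}

#' Exact individual-data log likelihood
#'
#' Sum over patients of `log(deta) + eta - exp(eta)` for events and
#' `-exp(eta)` for right-censored observations (the flexible parametric
#' likelihood on the ln-time scale). Returns `-Inf` when any event row has
#' non-positive deta, so samplers can reject.
#'
#' @inheritParams linear_predictor
#' @return scalar log likelihood.
#' @export
log_likelihood <- function(state, spec, md) {
  ll <- 0
  for (tid in names(md$trials)) {
    tr <- md$trials[[tid]]
    ll <- ll + rp_trial_loglik(tr$B, tr$dB, tr$lnt, tr$event, tr$C, tr$P,
                               state$gamma[[tid]], trial_b(state, spec, tid),
                               trial_a(state, spec, tid),
                               state$omega %||% numeric(0))
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

# pure-R per-patient contributions; independent of the compiled path and the
# production entry point for diagnostics needing per-patient values
loglik_contributions <- function(state, spec, md) {
  unlist(lapply(names(md$trials), function(tid) {
    tr <- md$trials[[tid]]
    lp <- linear_predictor(state, spec, md, tid)
    ifelse(tr$event == 1,
           ifelse(lp$deta > 0, log(lp$deta) + lp$eta - exp(lp$eta), -Inf),
           -exp(lp$eta))
  }))
}

#' Log prior density
#'
#' Sum of the prior log densities of every parameter in the state under the
#' model variant's priors (see [prior_spec()]). `-Inf` outside the support
#' (negative sigma_u, non-positive-definite T).
#'
#' @inheritParams linear_predictor
#' @param priors an `rp_priors`.
#' @return scalar log prior (up to no dropped terms; densities are complete).
#' @export
log_prior <- function(state, spec, priors = prior_spec()) {
  lp <- 0
  for (g in state$gamma)
    lp <- lp + sum(stats::dnorm(g, 0, sqrt(priors$gamma_var), log = TRUE))
  if (spec$effect == "fixed") {
    lp <- lp + sum(stats::dnorm(state$beta, 0, sqrt(priors$beta_var),
                                log = TRUE))
  } else {
    q <- length(state$mu)
    Tm <- state$T
    ch <- tryCatch(chol(Tm), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    for (bt in state$beta_trial)
      lp <- lp + dmvnorm_chol(bt, state$mu, ch)
    lp <- lp + sum(stats::dnorm(state$mu, 0, sqrt(priors$mu_var), log = TRUE))
    V <- priors$T_scale %||% diag(q)
    df <- priors$T_df %||% q
    lp <- lp + dinvwishart_log(Tm, V, df, chol_T = ch)
  }
  if (spec$interactions != "none") {
    lp <- lp + sum(stats::dnorm(state$beta_int, 0, sqrt(priors$beta_int_var),
                                log = TRUE))
    if (spec$interactions == "random") {
      if (is.null(state$sigma_u) || state$sigma_u < 0) return(-Inf)
      if (state$sigma_u == 0) return(-Inf)
      lp <- lp + log(2) + stats::dnorm(state$sigma_u, 0,
                                       sqrt(priors$sigma_u_var), log = TRUE)
      lp <- lp + sum(stats::dnorm(unlist(state$u), 0, state$sigma_u,
                                  log = TRUE))
    }
  }
  if (length(state$omega))
    lp <- lp + sum(stats::dnorm(state$omega, 0, sqrt(priors$omega_var),
                                log = TRUE))
  lp
}

dmvnorm_chol <- function(x, mean, ch) {
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * sum(z^2) - sum(log(diag(ch))) - 0.5 * length(x) * log(2 * pi)
}

# log multivariate gamma function
lmvgamma <- function(a, p) {
  0.25 * p * (p - 1) * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# inverse-Wishart log density, complete with constants
dinvwishart_log <- function(Tm, V, df, chol_T = NULL) {
  p <- nrow(Tm)
  ch <- chol_T %||% tryCatch(chol(Tm), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  ldetT <- 2 * sum(log(diag(ch)))
  ldetV <- as.numeric(determinant(V, logarithm = TRUE)$modulus)
  Tinv <- chol2inv(ch)
  0.5 * df * ldetV - 0.5 * df * p * log(2) - lmvgamma(df / 2, p) -
    0.5 * (df + p + 1) * ldetT - 0.5 * sum(diag(V %*% Tinv))
}

#' Initial parameter state
#'
#' Spline coefficients start at a least-squares fit of the Nelson-Aalen log
#' cumulative hazard on the trial's basis; treatment, interaction and
#' inconsistency coefficients at zero; T at the identity. Further chains are
#' jittered with twice the base dispersion to give overdispersed starts.
#'
#' @inheritParams linear_predictor
#' @param data the `rp_ipd` the model data were built from.
#' @param chain chain index (1 = unjittered).
#' @return parameter state list.
#' @export
init_state <- function(spec, md, data, chain = 1L) {
  q <- md$q
  state <- list(gamma = list())
  for (tid in names(md$trials)) {
    tr <- md$trials[[tid]]
    rows <- data[data$trial == tid, , drop = FALSE]
    na <- nelson_aalen(rows$time, rows$event)
    g <- rep(0, ncol(tr$B))
    if (length(na$time) >= 1) {
      keep <- na$hazard > 0
      if (sum(keep) >= 1) {
        Bna <- rcs_eval(tr$basis, log(na$time[keep]))
        if (md$basis_kind == "raw")
          Bna <- cbind(1, rcs_raw(log(na$time[keep]), tr$knots))
        y <- log(na$hazard[keep])
        g <- tryCatch(qr.solve(qr(Bna, LAPACK = TRUE), y),
                      error = function(e) rep(0, ncol(Bna)))
        if (length(g) != ncol(tr$B) || any(!is.finite(g)))
          g <- rep(0, ncol(tr$B))
      }
    }
    # ensure a positive baseline slope so the initial state is in-support
    lp0 <- drop(tr$dB %*% g)
    if (any(tr$event == 1 & lp0 <= 0)) g <- c(g[1], 1, rep(0, ncol(tr$B) - 2))
    state$gamma[[tid]] <- g
  }
  if (spec$effect == "fixed") {
    state$beta <- rep(0, q)
  } else {
    state$beta_trial <- lapply(md$trials, function(tr) rep(0, q))
    state$mu <- rep(0, q)
    state$T <- diag(q)
  }
  if (spec$interactions != "none") {
    state$beta_int <- rep(0, q)
    if (spec$interactions == "random") {
      state$u <- lapply(md$trials, function(tr) 0)
      state$sigma_u <- 0.1
    }
  }
  if (md$L > 0) state$omega <- rep(0, md$L)
  if (chain > 1L) {
    jit <- function(x) x + stats::rnorm(length(x), 0, 0.2 * (chain - 1))
    for (nm in c("beta", "beta_int", "omega"))
      if (!is.null(state[[nm]])) state[[nm]] <- jit(state[[nm]])
    if (!is.null(state[["beta_trial"]]))
      state$beta_trial <- lapply(state$beta_trial, jit)
    for (tid in names(md$trials)) {
      tr <- md$trials[[tid]]
      base <- state$gamma[[tid]]
      g <- jit(base)
      ca <- if (is.null(state[["beta_int"]])) 0
            else drop(tr$C %*% (state$beta_int + (state$u[[tid]] %||% 0)))
      # pull the jittered start back toward the base until deta is positive
      # at every event time (likelihood support)
      for (k in 1:30) {
        if (all((drop(tr$dB %*% g) + ca)[tr$event == 1] > 0)) break
        g <- base + (g - base) / 2
        if (k == 30) g <- base
      }
      state$gamma[[tid]] <- g
    }
  }
  state
}
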