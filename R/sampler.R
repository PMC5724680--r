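#' MCMC settings
#'
#' Defaults mirror the headline analysis settings (2 chains, 20000 burn-in,
#' 20000 stored iterations). Desk-scale work and the command-line front end
#' use [mcmc_desk()] (2 chains, 2000/2000).
#'
#' @param chains number of chains (>= 2 recommended).
#' @param burnin adaptation/burn-in iterations per chain (discarded).
#' @param iter stored iterations per chain.
#' @param seed integer seed; every source of randomness derives from it.
#' @return list of class `rp_mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 2L, burnin = 20000L, iter = 20000L,
                          seed = 1L) {
  stopifnot(chains >= 1, burnin >= 0, iter >= 1)
  structure(list(chains = as.integer(chains), burnin = as.integer(burnin),
                 iter = as.integer(iter), seed = as.integer(seed)),
            class = "rp_mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
mcmc_desk <- function(seed = 1L)
  mcmc_settings(chains = 2L, burnin = 2000L, iter = 2000L, seed = seed)

# ---- parameter layout ------------------------------------------------------

par_layout <- function(spec, md) {
  labs <- basic_labels(spec$network)
  nm <- character(0)
  for (tid in names(md$trials))
    nm <- c(nm, paste0("gamma[", tid, ",", seq_len(ncol(md$trials[[tid]]$B)),
                       "]"))
  if (spec$effect == "fixed") {
    nm <- c(nm, paste0("beta[", labs, "]"))
  } else {
    for (tid in names(md$trials))
      nm <- c(nm, paste0("beta_trial[", tid, ",", labs, "]"))
    nm <- c(nm, paste0("mu[", labs, "]"))
    q <- md$q
    for (i in seq_len(q)) for (j in i:q)
      nm <- c(nm, paste0("T[", i, ",", j, "]"))
  }
  if (spec$interactions != "none") {
    nm <- c(nm, paste0("beta_int[", labs, "]"))
    if (spec$interactions == "random")
      nm <- c(nm, paste0("u[", names(md$trials), "]"), "sigma_u")
  }
  if (md$L > 0)
    nm <- c(nm, paste0("omega[", vapply(spec$inconsistency, paste,
                                        "", collapse = "-"), "]"))
  nm
}

flatten_state <- function(state, spec, md) {
  out <- unlist(state$gamma, use.names = FALSE)
  if (spec$effect == "fixed") {
    out <- c(out, state$beta)
  } else {
    out <- c(out, unlist(state$beta_trial, use.names = FALSE), state$mu,
             state$T[upper.tri(state$T, diag = TRUE)])
  }
  if (spec$interactions != "none") {
    out <- c(out, state$beta_int)
    if (spec$interactions == "random")
      out <- c(out, unlist(state$u, use.names = FALSE), state$sigma_u)
  }
  if (md$L > 0) out <- c(out, state$omega)
  out
}

unflatten_state <- function(v, spec, md) {
  q <- md$q
  state <- list(gamma = list())
  pos <- 0L
  for (tid in names(md$trials)) {
    m <- ncol(md$trials[[tid]]$B)
    state$gamma[[tid]] <- v[pos + seq_len(m)]; pos <- pos + m
  }
  if (spec$effect == "fixed") {
    state$beta <- v[pos + seq_len(q)]; pos <- pos + q
  } else {
    state$beta_trial <- list()
    for (tid in names(md$trials)) {
      state$beta_trial[[tid]] <- v[pos + seq_len(q)]; pos <- pos + q
    }
    state$mu <- v[pos + seq_len(q)]; pos <- pos + q
    Tm <- matrix(0, q, q)
    Tm[upper.tri(Tm, diag = TRUE)] <- v[pos + seq_len(q * (q + 1) / 2)]
    pos <- pos + q * (q + 1) / 2
    state$T <- Tm + t(Tm) - diag(diag(Tm), q)
  }
  if (spec$interactions != "none") {
    state$beta_int <- v[pos + seq_len(q)]; pos <- pos + q
    if (spec$interactions == "random") {
      state$u <- as.list(v[pos + seq_along(md$trials)])
      names(state$u) <- names(md$trials)
      pos <- pos + length(md$trials)
      state$sigma_u <- v[pos + 1L]; pos <- pos + 1L
    }
  }
  if (md$L > 0) state$omega <- v[pos + seq_len(md$L)]
  state
}

# ---- sampler ---------------------------------------------------------------

#' Sample the posterior by adaptive blockwise Metropolis
#'
#' Blocks: one random-walk block per trial for the spline coefficients, a
#' global block for fixed treatment effects (or per-trial blocks plus
#' conjugate Gibbs updates of mu and T for random effects), a global block
#' for interaction coefficients, scalar blocks for per-trial interaction
#' deviations, sigma_u and each inconsistency parameter. Proposal scales
#' adapt toward standard acceptance targets during burn-in only, so the
#' post-burn-in chain is a valid Markov chain on the stated posterior.
#' Deterministic given seed, settings and data ordering.
#'
#' @param spec an `rp_model`.
#' @param data an `rp_ipd`.
#' @param priors an `rp_priors`.
#' @param settings an `rp_mcmc_settings`.
#' @param md optional prebuilt [build_model_data()] (e.g. with a raw basis).
#' @param use_likelihood set FALSE to sample the prior (likelihood switched
#'   off), used for prior-predictive sampler checks.
#' @param trial_loglik optional replacement per-trial log-likelihood
#'   `function(trial, gamma, b, a, omega, md)`, used to validate the sampler
#'   against closed-form posteriors.
#' @return object of class `rp_chains`.
#' @export
run_mcmc <- function(spec, data, priors = prior_spec(),
                     settings = mcmc_settings(), md = NULL,
                     use_likelihood = TRUE, trial_loglik = NULL) {
  if (is.null(md)) md <- build_model_data(data, spec)
  q <- md$q
  tids <- names(md$trials)
  trs <- md$trials
  J <- length(tids)
  pnames <- par_layout(spec, md)
  V_T <- priors$T_scale %||% diag(q)
  df_T <- priors$T_df %||% q
  fixed <- spec$effect == "fixed"
  ints <- spec$interactions            # "none" / "fixed" / "random"
  gv <- priors$gamma_var; bv <- priors$beta_var
  av <- priors$beta_int_var; wv <- priors$omega_var
  sv <- priors$sigma_u_var
  no_a <- numeric(0); no_w <- numeric(0)

  tlj <- function(j, gamma, b, a, omega) {
    if (!use_likelihood) return(0)
    if (!is.null(trial_loglik))
      return(trial_loglik(tids[j], gamma, b, a, omega, md))
    tr <- trs[[j]]
    rp_trial_loglik(tr$B, tr$dB, tr$lnt, tr$event, tr$C, tr$P,
                    gamma, b, a, if (is.null(omega)) no_w else omega)
  }
  accept <- function(delta) {
    if (is.na(delta)) return(FALSE)           # -Inf minus -Inf
    delta >= 0 || log(stats::runif(1)) < delta
  }
  omega_trials <- lapply(seq_len(md$L), function(l)
    which(vapply(trs, function(tr) any(tr$P[, l] != 0), TRUE)))

  ## integer block ids into the proposal-scale / acceptance vectors
  bnames <- paste0("gamma.", tids)
  ib_gamma <- seq_len(J)
  if (fixed) {
    ib_beta <- J + 1L; bnames <- c(bnames, "beta"); nb <- J + 1L
  } else {
    ib_bt <- J + seq_len(J)
    bnames <- c(bnames, paste0("beta_trial.", tids)); nb <- 2L * J
  }
  ib_int <- ib_sigma <- NA_integer_; ib_u <- integer(0)
  if (ints != "none") {
    ib_int <- nb + 1L; bnames <- c(bnames, "beta_int"); nb <- nb + 1L
    if (ints == "random") {
      ib_u <- nb + seq_len(J); ib_sigma <- nb + J + 1L
      bnames <- c(bnames, paste0("u.", tids), "sigma_u"); nb <- nb + J + 1L
    }
  }
  ib_omega <- if (md$L > 0) nb + seq_len(md$L) else integer(0)
  if (md$L > 0) { bnames <- c(bnames, paste0("omega.", seq_len(md$L)))
                  nb <- nb + md$L }

  draws <- vector("list", settings$chains)
  acc_report <- vector("list", settings$chains)

  for (chn in seq_len(settings$chains)) {
    set.seed(settings$seed + (chn - 1L) * 1000003L)
    state <- init_state(spec, md, data, chain = chn)
    gam <- state$gamma
    beta <- state[["beta"]]
    btl <- state[["beta_trial"]]
    mu <- state[["mu"]]; Tm <- state[["T"]]
    bint <- state[["beta_int"]]
    uvec <- if (ints == "random") unlist(state$u) else NULL
    sigu <- state[["sigma_u"]]
    omg <- state[["omega"]]
    chT <- if (!fixed) chol(Tm) else NULL
    a_of <- function(j) {
      if (ints == "none") no_a
      else if (ints == "fixed") bint
      else bint + uvec[j]
    }
    b_of <- function(j) if (fixed) beta else btl[[j]]
    ll <- vapply(seq_len(J), function(j)
      tlj(j, gam[[j]], b_of(j), a_of(j), omg), 0)

    sc <- rep(0.1, nb)
    if (length(ib_omega)) sc[ib_omega] <- 0.3
    n_acc <- n_try <- rep(0, nb)
    batch <- 0L
    total_iter <- settings$burnin + settings$iter
    out <- matrix(NA_real_, settings$iter, length(pnames) + 1L,
                  dimnames = list(NULL, c(pnames, "deviance")))
    ut <- if (!fixed) upper.tri(Tm, diag = TRUE) else NULL

    for (it in seq_len(total_iter)) {
      ## per-trial spline coefficients
      for (j in seq_len(J)) {
        g <- gam[[j]]
        gp <- g + sc[j] * stats::rnorm(length(g))
        llp <- tlj(j, gp, b_of(j), a_of(j), omg)
        delta <- llp - ll[j] - (sum(gp * gp) - sum(g * g)) / (2 * gv)
        n_try[j] <- n_try[j] + 1
        if (accept(delta)) {
          gam[[j]] <- gp; ll[j] <- llp; n_acc[j] <- n_acc[j] + 1
        }
      }

      ## treatment effects
      if (fixed) {
        bp <- beta + sc[ib_beta] * stats::rnorm(q)
        llp <- ll
        for (j in seq_len(J)) llp[j] <- tlj(j, gam[[j]], bp, a_of(j), omg)
        delta <- sum(llp) - sum(ll) -
          (sum(bp * bp) - sum(beta * beta)) / (2 * bv)
        n_try[ib_beta] <- n_try[ib_beta] + 1
        if (accept(delta)) {
          beta <- bp; ll <- llp; n_acc[ib_beta] <- n_acc[ib_beta] + 1
        }
      } else {
        for (j in seq_len(J)) {
          bl <- ib_bt[j]
          bt <- btl[[j]]
          btp <- bt + sc[bl] * stats::rnorm(q)
          llp <- tlj(j, gam[[j]], btp, a_of(j), omg)
          delta <- llp - ll[j] +
            dmvnorm_chol(btp, mu, chT) - dmvnorm_chol(bt, mu, chT)
          n_try[bl] <- n_try[bl] + 1
          if (accept(delta)) {
            btl[[j]] <- btp; ll[j] <- llp; n_acc[bl] <- n_acc[bl] + 1
          }
        }
        # Gibbs: mu | beta_trial, T  (normal prior, MVN likelihood)
        Tinv <- chol2inv(chT)
        Vmu <- chol2inv(chol(J * Tinv + diag(q) / priors$mu_var))
        bbar <- Reduce(`+`, btl)
        mu <- drop(Vmu %*% (Tinv %*% bbar) +
                     t(chol(Vmu)) %*% stats::rnorm(q))
        # Gibbs: T | beta_trial, mu  (conjugate inverse-Wishart)
        S <- matrix(0, q, q)
        for (j in seq_len(J)) {
          d <- btl[[j]] - mu
          S <- S + tcrossprod(d)
        }
        W <- stats::rWishart(1, df_T + J, chol2inv(chol(V_T + S)))[, , 1]
        Tm <- chol2inv(chol(W))
        chT <- chol(Tm)
      }

      ## treatment-ln(time) interaction coefficients (global block)
      if (ints != "none") {
        ap <- bint + sc[ib_int] * stats::rnorm(q)
        llp <- ll
        if (ints == "fixed") {
          for (j in seq_len(J)) llp[j] <- tlj(j, gam[[j]], b_of(j), ap, omg)
        } else {
          for (j in seq_len(J))
            llp[j] <- tlj(j, gam[[j]], b_of(j), ap + uvec[j], omg)
        }
        delta <- sum(llp) - sum(ll) -
          (sum(ap * ap) - sum(bint * bint)) / (2 * av)
        n_try[ib_int] <- n_try[ib_int] + 1
        if (accept(delta)) {
          bint <- ap; ll <- llp; n_acc[ib_int] <- n_acc[ib_int] + 1
        }

        if (ints == "random") {
          for (j in seq_len(J)) {
            bl <- ib_u[j]
            up <- uvec[j] + sc[bl] * stats::rnorm(1)
            llp1 <- tlj(j, gam[[j]], b_of(j), bint + up, omg)
            delta <- llp1 - ll[j] -
              (up * up - uvec[j] * uvec[j]) / (2 * sigu * sigu)
            n_try[bl] <- n_try[bl] + 1
            if (accept(delta)) {
              uvec[j] <- up; ll[j] <- llp1; n_acc[bl] <- n_acc[bl] + 1
            }
          }
          sp <- sigu + sc[ib_sigma] * stats::rnorm(1)
          n_try[ib_sigma] <- n_try[ib_sigma] + 1
          if (sp > 0) {
            su2 <- sum(uvec * uvec)
            delta <- -J * (log(sp) - log(sigu)) -
              su2 / 2 * (1 / (sp * sp) - 1 / (sigu * sigu)) -
              (sp * sp - sigu * sigu) / (2 * sv)
            if (accept(delta)) {
              sigu <- sp; n_acc[ib_sigma] <- n_acc[ib_sigma] + 1
            }
          }
        }
      }

      ## inconsistency parameters
      for (l in seq_along(ib_omega)) {
        bl <- ib_omega[l]
        wp <- omg
        wp[l] <- wp[l] + sc[bl] * stats::rnorm(1)
        aff <- omega_trials[[l]]
        llp <- ll[aff]
        for (k in seq_along(aff)) {
          j <- aff[k]
          llp[k] <- tlj(j, gam[[j]], b_of(j), a_of(j), wp)
        }
        delta <- sum(llp) - sum(ll[aff]) -
          (wp[l] * wp[l] - omg[l] * omg[l]) / (2 * wv)
        n_try[bl] <- n_try[bl] + 1
        if (accept(delta)) {
          omg <- wp; ll[aff] <- llp; n_acc[bl] <- n_acc[bl] + 1
        }
      }

      ## adapt proposal scales during burn-in only
      if (it <= settings$burnin && it %% 50 == 0) {
        batch <- batch + 1L
        rate <- n_acc / pmax(n_try, 1)
        step <- min(0.5, 1 / sqrt(batch))
        sc <- sc * exp(step * (rate - 0.3))
        n_acc[] <- 0; n_try[] <- 0
      }

      if (it > settings$burnin) {
        k <- it - settings$burnin
        row <- unlist(gam, use.names = FALSE)
        row <- if (fixed) c(row, beta)
               else c(row, unlist(btl, use.names = FALSE), mu, Tm[ut])
        if (ints != "none") {
          row <- c(row, bint)
          if (ints == "random") row <- c(row, uvec, sigu)
        }
        if (md$L > 0) row <- c(row, omg)
        out[k, ] <- c(row, -2 * sum(ll))
      }
    }
    if (!is.finite(sum(ll)) && use_likelihood)
      warning("chain ", chn, " ended outside the likelihood support; ",
              "check initial values and data", call. = FALSE)
    draws[[chn]] <- out
    acc_report[[chn]] <- stats::setNames(
      ifelse(n_try > 0, n_acc / n_try, NA_real_), bnames)
  }

  structure(list(draws = draws, param_names = pnames,
                 n_chains = settings$chains, n_burnin = settings$burnin,
                 n_iter = settings$iter, seed = settings$seed,
                 spec = spec, priors = priors, md = md,
                 accept_rates = acc_report,
                 use_likelihood = use_likelihood),
            class = "rp_chains")
}

#' @export
print.rp_chains <- function(x, ...) {
  cat("MCMC draws:", x$n_chains, "chains x", x$n_iter, "iterations (burn-in",
      paste0(x$n_burnin, ")"), "over", length(x$param_names),
      "parameters; seed", x$seed, "\n")
  invisible(x)
}

# all post-burn-in draws, chains stacked
all_draws <- function(chains, pars = chains$param_names) {
  do.call(rbind, lapply(chains$draws, function(m) m[, pars, drop = FALSE]))
}

#' Posterior summaries for a set of parameters
#'
#' @param chains an `rp_chains`.
#' @param pars parameter names (default all).
#' @return data.frame with mean, sd and 2.5/50/97.5 centiles per parameter.
#' @export
posterior_summary <- function(chains, pars = chains$param_names) {
  m <- all_draws(chains, pars)
  data.frame(parameter = pars, mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q2.5 = apply(m, 2, stats::quantile, 0.025),
             q50 = apply(m, 2, stats::quantile, 0.5),
             q97.5 = apply(m, 2, stats::quantile, 0.975),
             row.names = NULL)
}

#' Deviance information criterion
#'
#' D(theta) = -2 log likelihood; Dbar is its posterior mean, pD = Dbar -
#' D(posterior mean of the parameters), DIC = Dbar + pD. A negative pD is
#' flagged with a warning but returned.
#'
#' @param chains an `rp_chains` from [run_mcmc()].
#' @return list of class `rp_dic` with `dbar`, `pd`, `dic`.
#' @seealso [dic_summary()] for combining externally reported components.
#' @export
dic <- function(chains) {
  dev <- all_draws(chains, "deviance")
  dbar <- mean(dev)
  mstate <- unflatten_state(colMeans(all_draws(chains)), chains$spec,
                            chains$md)
  dhat <- -2 * log_likelihood(mstate, chains$spec, chains$md)
  if (!is.finite(dhat)) {
    warning("posterior-mean state lies outside the likelihood support",
            call. = FALSE)
    return(structure(list(dbar = dbar, pd = NA_real_, dic = NA_real_),
                     class = "rp_dic"))
  }
  pd <- dbar - dhat
  if (pd < 0) warning("negative pD (", signif(pd, 4),
                      "): posterior mean fits worse than the average draw",
                      call. = FALSE)
  dic_summary(dbar, pd)
}

#' Combine deviance components into a DIC
#'
#' The arithmetic identity DIC = Dbar + pD, applicable to reported model-fit
#' components as well as to components computed from chains.
#'
#' @param dbar posterior mean deviance.
#' @param pd effective number of parameters.
#' @return list of class `rp_dic` with `dbar`, `pd`, `dic = dbar + pd`.
#' @export
dic_summary <- function(dbar, pd) {
  structure(list(dbar = dbar, pd = pd, dic = dbar + pd), class = "rp_dic")
}

#' @export
print.rp_dic <- function(x, ...) {
  cat("Dbar =", format(x$dbar), " pD =", format(x$pd),
      " DIC =", format(x$dic), "\n")
  invisible(x)
}

#' Convergence diagnostics
#'
#' Split-chain potential scale reduction (each chain halved, variance-ratio
#' statistic across the resulting half-chains) and effective sample size from
#' the initial positive sequence of averaged autocorrelations, per scalar
#' parameter. Parameters exceeding the 1.05 threshold are flagged; a
#' parameter constant across all draws has an undefined statistic and is
#' reported as such.
#'
#' @param chains an `rp_chains`.
#' @param threshold flag parameters with scale reduction above this.
#' @return data.frame with parameter, rhat, ess, flag, note.
#' @export
convergence_report <- function(chains, threshold = 1.05) {
  pars <- chains$param_names
  res <- lapply(pars, function(p) {
    mats <- lapply(chains$draws, function(m) m[, p])
    halves <- list()
    for (v in mats) {
      n2 <- floor(length(v) / 2)
      halves <- c(halves, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
    }
    if (all(vapply(halves, function(h) stats::var(h) == 0, TRUE)) &&
        stats::var(unlist(halves)) == 0)
      return(data.frame(parameter = p, rhat = NA_real_, ess = NA_real_,
                        flag = FALSE, note = "constant across draws"))
    n <- length(halves[[1]]); m <- length(halves)
    means <- vapply(halves, mean, 0)
    vars <- vapply(halves, stats::var, 0)
    W <- mean(vars)
    B <- n * stats::var(means)
    rhat <- if (W > 0) sqrt(((n - 1) / n * W + B / n) / W) else NA_real_
    # ESS: averaged autocorrelations, initial positive sequence
    varplus <- (n - 1) / n * W + B / n
    maxlag <- min(n - 1, 200)
    acov <- vapply(halves, function(v)
      drop(stats::acf(v, lag.max = maxlag, type = "covariance",
                      plot = FALSE, demean = TRUE)$acf)[-1],
      numeric(maxlag))
    rho <- 1 - (W - rowMeans(acov)) / varplus
    pos <- which(rho < 0)
    if (length(pos)) rho <- rho[seq_len(pos[1] - 1)]
    ess <- m * n / (1 + 2 * sum(rho))
    data.frame(parameter = p, rhat = rhat, ess = min(ess, m * n),
               flag = is.finite(rhat) && rhat > threshold, note = "")
  })
  do.call(rbind, res)
}

#' Export draws in long format
#'
#' @param chains an `rp_chains`.
#' @return data.frame (chain, iteration, parameter, value) suitable for
#'   external diagnostics tooling.
#' @export
chains_long <- function(chains) {
  do.call(rbind, lapply(seq_len(chains$n_chains), function(ch) {
    m <- chains$draws[[ch]]
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
}
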