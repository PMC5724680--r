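#' Fit the one-step network meta-analysis model
#'
#' Runs the sampler and summarises the basic contrasts, all derived pairwise
#' treatment comparisons (computed per draw through the consistency
#' equations, never by differencing summaries), model fit (Dbar, pD, DIC) and
#' convergence diagnostics.
#'
#' @param data an `rp_ipd`.
#' @param spec an `rp_model`.
#' @param priors an `rp_priors`.
#' @param settings an `rp_mcmc_settings`.
#' @param md optional prebuilt model data.
#' @return object of class `rp_fit` with elements `summaries` (basic and
#'   derived contrasts), `parameters` (all-parameter summaries), `dic`,
#'   `diagnostics`, `chains`.
#' @export
fit_nma <- function(data, spec, priors = prior_spec(),
                    settings = mcmc_settings(), md = NULL) {
  check_connected(data, spec$network)
  chains <- run_mcmc(spec, data, priors, settings, md = md)
  build_fit(chains)
}

#' One-step pairwise meta-analysis of a single comparison
#'
#' All trials must share one two-treatment design. Fits the per-trial spline
#' baselines with a single fixed (or random) log hazard ratio; adding a
#' treatment-ln(time) interaction provides the global non-PH test for the
#' comparison.
#'
#' @param data `rp_ipd` rows for the comparison.
#' @param effect `"fixed"` or `"random"`.
#' @param interactions `"none"`, `"fixed"` or `"random"`.
#' @param priors,settings,n_interior,knots passed through to the model.
#' @return an `rp_fit`.
#' @export
fit_pairwise_ma <- function(data, effect = "fixed", interactions = "none",
                            priors = prior_spec(),
                            settings = mcmc_settings(), n_interior = 2L,
                            knots = NULL) {
  designs <- unique(lapply(unique(data$trial), function(tid)
    sort(unique(data$treatment[data$trial == tid]))))
  if (length(designs) != 1)
    stop("mixed designs: pairwise MA needs all trials to share one design",
         call. = FALSE)
  arms <- designs[[1]]
  if (length(arms) != 2)
    stop("pairwise MA needs a two-treatment design", call. = FALSE)
  net0 <- attr(data, "network")
  ref <- if (!is.null(net0) && net0$reference %in% arms) net0$reference
         else arms[1]
  net <- network_spec(c(ref, setdiff(arms, ref)), reference = ref,
                      designs = list(arms))
  d2 <- ipd_data(as.data.frame(data), net)
  spec <- model_spec(net, effect = effect, interactions = interactions,
                     knots = knots, n_interior = n_interior)
  fit_nma(d2, spec, priors, settings)
}

build_fit <- function(chains) {
  spec <- chains$spec
  net <- spec$network
  labs <- basic_labels(net)
  q <- chains$md$q
  base_pars <- if (spec$effect == "fixed") paste0("beta[", labs, "]")
               else paste0("mu[", labs, "]")
  bdraws <- all_draws(chains, base_pars)
  # per-draw treatment effects vs the network reference
  eff <- treatment_effects(bdraws, net)
  trts <- setdiff(net$treatments, net$reference)
  derived <- list()
  for (i in seq_along(trts)) {
    derived[[paste0(net$reference, ":", trts[i])]] <- eff[, i]
    if (i < length(trts))
      for (j in (i + 1):length(trts))
        derived[[paste0(trts[i], ":", trts[j])]] <- eff[, j] - eff[, i]
  }
  summ <- do.call(rbind, lapply(names(derived), function(nm) {
    v <- derived[[nm]]
    data.frame(comparison = nm, mean = mean(v), sd = stats::sd(v),
               q2.5 = stats::quantile(v, 0.025, names = FALSE),
               q50 = stats::quantile(v, 0.5, names = FALSE),
               q97.5 = stats::quantile(v, 0.975, names = FALSE))
  }))
  structure(list(summaries = summ, parameters = posterior_summary(chains),
                 dic = dic(chains),
                 diagnostics = convergence_report(chains),
                 chains = chains), class = "rp_fit")
}

# draws of each non-reference treatment's effect vs the network reference,
# solved from the basic-contrast draws through the consistency equations
treatment_effects <- function(bdraws, network) {
  trts <- setdiff(network$treatments, network$reference)
  M <- vapply(network$basic_contrasts, function(bc) {
    v <- numeric(length(trts))
    if (bc[2] %in% trts) v[match(bc[2], trts)] <- 1
    if (bc[1] %in% trts) v[match(bc[1], trts)] <- -1
    v
  }, numeric(length(trts)))
  # basic contrast k = M[,k] . effect-vector  =>  effects = solve over basics
  out <- t(solve(t(M), t(bdraws)))
  colnames(out) <- trts
  out
}

#' @export
print.rp_fit <- function(x, ...) {
  cat("One-step Royston-Parmar", x$chains$spec$effect, "treatment effect",
      if (length(x$chains$spec$inconsistency)) "(+inconsistency)", "fit\n")
  print(x$summaries, row.names = FALSE, digits = 3)
  print(x$dic)
  nf <- sum(x$diagnostics$flag, na.rm = TRUE)
  if (nf) cat(nf, "parameter(s) with scale reduction > 1.05\n")
  invisible(x)
}

check_connected <- function(data, network) {
  trts <- unique(data$treatment)
  edges <- unique(do.call(rbind, lapply(unique(data$trial), function(tid) {
    a <- sort(unique(data$treatment[data$trial == tid]))
    t(utils::combn(a, 2))
  })))
  comp <- stats::setNames(seq_along(trts), trts)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- comp[edges[r, 1]]; b <- comp[edges[r, 2]]
      if (a != b) { comp[comp == max(a, b)] <- min(a, b); changed <- TRUE }
    }
    if (!changed) break
  }
  if (length(unique(comp)) > 1)
    stop("disconnected network: treatments ",
         paste(names(comp)[comp != comp[1]], collapse = ", "),
         " are not linked to ", names(comp)[1], call. = FALSE)
  invisible(TRUE)
}

#' Global Wald test for non-proportional hazards
#'
#' W = m' V^{-1} m with m the posterior means and V the posterior covariance
#' of the treatment-ln(time) interaction coefficients (plus sigma_u when
#' `include_variance` and the interactions are random by trial), compared to
#' a chi-squared distribution with df equal to the number of tested
#' parameters. Testing sigma_u at its zero boundary is conservative.
#'
#' @param fit an `rp_fit` (or `rp_chains`) whose model includes interactions.
#' @param include_variance include sigma_u in the tested block.
#' @return list of class `rp_wald` with `statistic`, `df`, `p_value`,
#'   `parameters`.
#' @export
wald_global_nonph <- function(fit, include_variance = FALSE) {
  chains <- if (inherits(fit, "rp_fit")) fit$chains else fit
  spec <- chains$spec
  if (spec$interactions == "none")
    stop("model has no treatment-ln(time) interactions", call. = FALSE)
  pars <- grep("^beta_int\\[", chains$param_names, value = TRUE)
  if (include_variance) {
    if (spec$interactions != "random")
      stop("include_variance needs random-by-trial interactions",
           call. = FALSE)
    pars <- c(pars, "sigma_u")
  }
  m <- all_draws(chains, pars)
  if (nrow(m) < 100) stop("need >= 100 draws for the Wald test",
                          call. = FALSE)
  mhat <- colMeans(m)
  V <- stats::cov(m)
  Vinv <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vinv)) {
    warning("singular posterior covariance; using pseudo-inverse",
            call. = FALSE)
    Vinv <- MASS::ginv(V)
  }
  W <- drop(t(mhat) %*% Vinv %*% mhat)
  df <- length(pars)
  structure(list(statistic = W, df = df,
                 p_value = stats::pchisq(W, df, lower.tail = FALSE),
                 parameters = pars), class = "rp_wald")
}

#' @export
print.rp_wald <- function(x, ...) {
  cat("Global non-PH Wald test: chi-squared =", signif(x$statistic, 4),
      "on", x$df, "df, p =", signif(x$p_value, 3), "\n")
  invisible(x)
}

#' Separate direct and indirect evidence in a loop
#'
#' Fits the model with the loop's inconsistency parameter and, per draw,
#' computes the direct and indirect estimate of every comparison in the loop
#' (the loop-closing design's direct effect is the consistency value plus
#' omega; each other comparison's indirect estimate routes through the third
#' treatment). The omega-free network estimates come from a second fit
#' without the inconsistency parameter.
#'
#' @param data an `rp_ipd`.
#' @param spec an `rp_model` whose `inconsistency` names exactly one loop.
#' @param priors,settings passed to the sampler.
#' @return list of class `rp_evidence` with `table` (comparison, source in
#'   direct/indirect/network, estimate, lower, upper), `omega` summary, and
#'   the two fits.
#' @export
separate_direct_indirect <- function(data, spec, priors = prior_spec(),
                                     settings = mcmc_settings()) {
  if (length(spec$inconsistency) != 1)
    stop("specify exactly one loop in spec$inconsistency", call. = FALSE)
  lp <- spec$inconsistency[[1]]
  lc <- loop_closing_design(spec$network, lp)
  present <- unique(lapply(unique(data$trial), function(tid)
    sort(unique(data$treatment[data$trial == tid]))))
  if (!any(vapply(present, identical, TRUE,
                  y = sort(lc$design$treatments))))
    stop("no loop: the loop-closing design ",
         paste(lc$design$treatments, collapse = " vs "),
         " has no trials in the data", call. = FALSE)

  fit_w <- fit_nma(data, spec, priors, settings)
  spec0 <- spec; spec0$inconsistency <- list()
  fit_0 <- fit_nma(data, spec0, priors, settings)

  net <- spec$network
  labs <- basic_labels(net)
  base_pars <- if (spec$effect == "fixed") paste0("beta[", labs, "]")
               else paste0("mu[", labs, "]")
  ch <- fit_w$chains
  bd <- all_draws(ch, base_pars)
  om <- drop(all_draws(ch, grep("^omega\\[", ch$param_names, value = TRUE)))
  eff <- treatment_effects(bd, net)
  apex <- lp[1]; b <- lp[2]; cc <- lp[3]
  effcol <- function(tr) if (tr == net$reference) 0 else eff[, tr]
  # direct effects under the omega model
  d_ab <- effcol(b) - effcol(apex)
  d_ac <- effcol(cc) - effcol(apex)
  d_bc <- effcol(cc) - effcol(b) + om
  rows <- list(
    list(paste0(apex, ":", b), "direct", d_ab),
    list(paste0(apex, ":", b), "indirect", d_ab - om),
    list(paste0(apex, ":", cc), "direct", d_ac),
    list(paste0(apex, ":", cc), "indirect", d_ac + om),
    list(paste0(b, ":", cc), "direct", d_bc),
    list(paste0(b, ":", cc), "indirect", d_bc - om))
  tab <- do.call(rbind, lapply(rows, function(r)
    data.frame(comparison = r[[1]], source = r[[2]], estimate = mean(r[[3]]),
               lower = stats::quantile(r[[3]], 0.025, names = FALSE),
               upper = stats::quantile(r[[3]], 0.975, names = FALSE))))
  netrows <- fit_0$summaries
  netrows <- netrows[netrows$comparison %in% unique(tab$comparison), ]
  tab <- rbind(tab, data.frame(comparison = netrows$comparison,
                               source = "network", estimate = netrows$mean,
                               lower = netrows$q2.5, upper = netrows$q97.5))
  structure(list(table = tab,
                 omega = data.frame(mean = mean(om), sd = stats::sd(om),
                                    q2.5 = stats::quantile(om, 0.025,
                                                           names = FALSE),
                                    q97.5 = stats::quantile(om, 0.975,
                                                            names = FALSE)),
                 fit_omega = fit_w, fit_network = fit_0),
            class = "rp_evidence")
}

#' @export
print.rp_evidence <- function(x, ...) {
  cat("Direct / indirect / network evidence separation\n")
  print(x$table, row.names = FALSE, digits = 3)
  cat("omega:", signif(x$omega$mean, 3), "(",
      signif(x$omega$q2.5, 3), ",", signif(x$omega$q97.5, 3), ")\n")
  invisible(x)
}

#' Cochran Q decomposition for a design-grouped network
#'
#' Q is the dispersion of per-trial estimates around the network estimates;
#' it splits exactly into within-design heterogeneity (around the
#' inverse-variance pooled design estimates) and between-design
#' inconsistency (pooled design estimates around the network estimates, with
#' pooled variances), Q = Qinc + Qhet. Degrees of freedom: sum of (trials per
#' design - 1) within; number of designs minus the number of basic
#' parameters identified by the designs between.
#'
#' @param trial_estimates data.frame with columns `design`, `trial`, `theta`,
#'   `se` (per-trial treatment effect estimates and standard errors).
#' @param network_estimates data.frame with columns `design`, `theta` (the
#'   network model's estimate of each design's comparison).
#' @param q_star number of basic parameters identified by the designs;
#'   computed from `network` when supplied, else defaults to the number of
#'   distinct treatments in the designs minus one is NOT assumed — it must be
#'   supplied one way or the other.
#' @param network optional `rp_network` used to derive `q_star` as the rank
#'   of the designs' contrast matrix.
#' @return object of class `rp_q` with q_total/q_inc/q_het, degrees of
#'   freedom, p-values, and per-design contributions.
#' @export
q_decomposition <- function(trial_estimates, network_estimates,
                            q_star = NULL, network = NULL) {
  te <- trial_estimates
  if (any(te$se <= 0)) stop("non-positive standard error", call. = FALSE)
  designs <- unique(te$design)
  if (!all(network_estimates$design %in% designs) ||
      !all(designs %in% network_estimates$design))
    stop("designs of the two tables do not match", call. = FALSE)
  if (is.null(q_star)) {
    if (!is.null(network)) {
      rowsC <- do.call(rbind, lapply(network$designs, function(d) {
        t(vapply(setdiff(d$treatments, d$reference), function(a)
          build_contrasts(network, d$treatments, a),
          numeric(n_basic(network))))
      }))
      q_star <- qr(rowsC)$rank
    } else {
      stop("supply q_star or a network to derive it from", call. = FALSE)
    }
  }
  per <- lapply(designs, function(dj) {
    rows <- te[te$design == dj, ]
    w <- 1 / rows$se^2
    theta_j <- sum(w * rows$theta) / sum(w)
    var_j <- 1 / sum(w)
    theta_N <- network_estimates$theta[network_estimates$design == dj][1]
    list(design = dj, n = nrow(rows),
         q = sum((rows$theta - theta_N)^2 * w),
         q_het = sum((rows$theta - theta_j)^2 * w),
         q_inc = (theta_j - theta_N)^2 / var_j)
  })
  q_total <- sum(vapply(per, `[[`, 0, "q"))
  q_het <- sum(vapply(per, `[[`, 0, "q_het"))
  q_inc <- sum(vapply(per, `[[`, 0, "q_inc"))
  df_het <- sum(vapply(per, `[[`, 0, "n") - 1)
  df_inc <- length(designs) - q_star
  df_total <- df_het + df_inc
  structure(list(
    q_total = q_total, q_inc = q_inc, q_het = q_het,
    df_total = df_total, df_inc = df_inc, df_het = df_het,
    p_total = stats::pchisq(q_total, max(df_total, 1), lower.tail = FALSE),
    p_inc = if (df_inc > 0) stats::pchisq(q_inc, df_inc, lower.tail = FALSE)
            else NA_real_,
    p_het = if (df_het > 0) stats::pchisq(q_het, df_het, lower.tail = FALSE)
            else NA_real_,
    per_design = do.call(rbind, lapply(per, function(p)
      data.frame(design = p$design, trials = p$n, q = p$q, q_het = p$q_het,
                 q_inc = p$q_inc)))), class = "rp_q")
}

#' @export
print.rp_q <- function(x, ...) {
  cat("Q decomposition: Q =", signif(x$q_total, 4), "(", x$df_total,
      "df, p =", signif(x$p_total, 3), ")\n")
  cat("  between designs (inconsistency): Qinc =", signif(x$q_inc, 4), "(",
      x$df_inc, "df )\n")
  cat("  within designs (heterogeneity):  Qhet =", signif(x$q_het, 4), "(",
      x$df_het, "df )\n")
  invisible(x)
}

#' Per-trial treatment effect estimates for the Q decomposition
#'
#' Estimates every non-reference arm against the trial's design reference,
#' trial by trial. The default estimator is a frequentist Cox fit (Breslow
#' ties) — cheap, standard, and consistent with the model under proportional
#' hazards; `estimator = "rp"` instead fits the single-trial flexible
#' parametric model by MCMC and uses its posterior mean and sd. Multiarm
#' trials enter through their constituent contrasts (one row per
#' non-reference arm), ignoring the within-trial correlation of those
#' contrasts.
#'
#' @param data an `rp_ipd`.
#' @param network an `rp_network` (defaults to the attached one).
#' @param estimator `"cox"` (default) or `"rp"`.
#' @param settings sampler settings for `estimator = "rp"`.
#' @param n_interior interior knots for `estimator = "rp"`.
#' @return data.frame (design, trial, comparison, theta, se).
#' @export
trial_effect_estimates <- function(data, network = attr(data, "network"),
                                   estimator = c("cox", "rp"),
                                   settings = mcmc_desk(),
                                   n_interior = 1L) {
  estimator <- match.arg(estimator)
  out <- list()
  for (tid in unique(data$trial)) {
    rows <- data[data$trial == tid, , drop = FALSE]
    d <- match_design(network, unique(rows$treatment))
    for (arm in setdiff(d$treatments, d$reference)) {
      sub <- rows[rows$treatment %in% c(d$reference, arm), , drop = FALSE]
      if (estimator == "cox") {
        cf <- cox_fit(sub, treatment = arm)
        theta <- cf$loghr; se <- cf$se
      } else {
        sub2 <- ipd_data(as.data.frame(sub), network)
        fit <- fit_pairwise_ma(sub2, settings = settings,
                               n_interior = n_interior)
        s <- fit$summaries[1, ]
        sgn <- if (s$comparison == paste0(d$reference, ":", arm)) 1 else -1
        theta <- sgn * s$mean; se <- s$sd
      }
      out[[length(out) + 1L]] <-
        data.frame(design = paste(sort(d$treatments), collapse = "|"),
                   trial = tid,
                   comparison = paste0(d$reference, ":", arm),
                   theta = theta, se = se)
    }
  }
  do.call(rbind, out)
}

#' Network estimates per design for the Q decomposition
#'
#' Maps a fitted model's posterior-mean treatment effects onto each design's
#' comparisons via the consistency equations.
#'
#' @param fit an `rp_fit`.
#' @param data the `rp_ipd` the fit used.
#' @param network an `rp_network`.
#' @return data.frame (design, comparison, theta).
#' @export
network_design_estimates <- function(fit, data,
                                     network = attr(data, "network")) {
  out <- list()
  for (tid in unique(data$trial)) {
    d <- match_design(network, unique(data$treatment[data$trial == tid]))
    key <- paste(sort(d$treatments), collapse = "|")
    if (key %in% vapply(out, `[[`, "", "design")) next
    for (arm in setdiff(d$treatments, d$reference)) {
      cmp <- paste0(d$reference, ":", arm)
      est <- fit$summaries$mean[fit$summaries$comparison == cmp]
      if (!length(est)) {
        rev <- paste0(arm, ":", d$reference)
        est <- -fit$summaries$mean[fit$summaries$comparison == rev]
      }
      out[[length(out) + 1L]] <- data.frame(design = key, comparison = cmp,
                                            theta = est)
    }
  }
  do.call(rbind, out)
}

#' Posterior treatment ranking
#'
#' Per draw, every treatment's effect versus the common reference (the
#' reference itself at 0) is ranked ascending — the smallest log hazard ratio
#' is rank 1, the most effective — and the rank counts are tallied as
#' percentages.
#'
#' @param chains an `rp_chains` (or `rp_fit`).
#' @param network the treatment network (defaults to the fit's).
#' @return matrix of class `rp_ranks`, treatments x ranks, percentages; rows
#'   and columns each sum to 100.
#' @export
rank_treatments <- function(chains, network = NULL) {
  if (inherits(chains, "rp_fit")) chains <- chains$chains
  if (is.null(network)) network <- chains$spec$network
  labs <- basic_labels(network)
  base_pars <- if (chains$spec$effect == "fixed")
    paste0("beta[", labs, "]") else paste0("mu[", labs, "]")
  bd <- all_draws(chains, base_pars)
  eff <- cbind(0, treatment_effects(bd, network))
  colnames(eff)[1] <- network$reference
  n_t <- ncol(eff)
  counts <- matrix(0L, n_t, n_t,
                   dimnames = list(colnames(eff), paste0("rank", 1:n_t)))
  rk <- t(apply(eff, 1, rank, ties.method = "first"))
  for (k in seq_len(n_t))
    counts[, k] <- colSums(rk == k)
  pct <- 100 * counts / nrow(eff)
  structure(pct, class = c("rp_ranks", "matrix"))
}

#' @export
print.rp_ranks <- function(x, ...) {
  cat("Treatment ranking (% of draws; rank 1 = most effective)\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Shrinkage intervals for trial-level departures from proportional hazards
#'
#' For a model with random-by-trial treatment-ln(time) interactions, returns
#' each trial's posterior mean deviation u_j with the interval
#' u_j +/- 1.96 sd_j, the display behind the shrinkage plot.
#'
#' @param chains an `rp_chains` (or `rp_fit`) with random interactions.
#' @return data.frame (trial, mean, sd, lower, upper).
#' @export
shrinkage_intervals <- function(chains) {
  if (inherits(chains, "rp_fit")) chains <- chains$chains
  if (chains$spec$interactions != "random")
    stop("model has no random-by-trial interactions", call. = FALSE)
  pars <- grep("^u\\[", chains$param_names, value = TRUE)
  m <- all_draws(chains, pars)
  mu <- colMeans(m); sd_ <- apply(m, 2, stats::sd)
  data.frame(trial = sub("^u\\[(.*)\\]$", "\\1", pars), mean = mu,
             sd = sd_, lower = mu - 1.96 * sd_, upper = mu + 1.96 * sd_,
             row.names = NULL)
}
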