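test_that("Wald statistic matches the quadratic form and its edge cases", {
  # hand-built chains: two interaction parameters with known moments
  fake_int <- function(m) {
    structure(list(
      draws = list(cbind(m, deviance = 0)),
      param_names = colnames(m), n_chains = 1, n_burnin = 0,
      n_iter = nrow(m), seed = 1,
      spec = list(interactions = "fixed")), class = "rp_chains")
  }
  set.seed(23)
  z <- matrix(rnorm(4000), ncol = 2,
              dimnames = list(NULL, c("beta_int[A:B]", "beta_int[A:C]")))
  # centred draws: statistic small, p near 1 for m = 0
  ch0 <- fake_int(sweep(z, 2, colMeans(z)))
  w0 <- wald_global_nonph(ch0)
  expect_equal(w0$statistic, 0, tolerance = 1e-10)
  expect_equal(w0$p_value, 1)
  expect_equal(w0$df, 2)

  # m = (1,1), V = I: W = 2 (independent brute-force solve)
  ch1 <- fake_int(sweep(z, 2, colMeans(z)) %*%
                    solve(chol(cov(z))) + 1)
  w1 <- wald_global_nonph(ch1)
  expect_equal(w1$statistic, 2, tolerance = 1e-6)
  m <- colMeans(rpnma:::all_draws(ch1, w1$parameters))
  V <- cov(rpnma:::all_draws(ch1, w1$parameters))
  expect_equal(w1$statistic, drop(t(m) %*% solve(V, m)), tolerance = 1e-10)

  # random moments: agreement with solve() to 1e-10
  for (i in 1:5) {
    A <- matrix(rnorm(4), 2); V <- crossprod(A) + diag(2)
    mm <- rnorm(2)
    draws <- mvtnorm_draws(5000, mm, V)
    colnames(draws) <- c("beta_int[A:B]", "beta_int[A:C]")
    ch <- fake_int(draws)
    w <- wald_global_nonph(ch)
    mhat <- colMeans(draws); Vhat <- cov(draws)
    expect_equal(w$statistic, drop(t(mhat) %*% solve(Vhat, mhat)),
                 tolerance = 1e-10)
  }
})

test_that("Q decomposition is exact on hand-computable cases", {
  # one design, one trial: everything zero
  te <- data.frame(design = "d1", trial = "t1", theta = 0.3, se = 0.2)
  ne <- data.frame(design = "d1", theta = 0.1)
  qd <- q_decomposition(te, ne, q_star = 1)
  expect_equal(qd$q_het, 0)
  expect_equal(qd$df_het, 0)
  expect_equal(qd$df_inc, 0)
  expect_equal(qd$q_total, qd$q_inc)

  # two trials at +/- d with equal variance: pooled 0, Qhet = 2 d^2 / s^2
  dd <- 0.4; s <- 0.25
  te2 <- data.frame(design = "d1", trial = c("t1", "t2"),
                    theta = c(dd, -dd), se = s)
  ne2 <- data.frame(design = "d1", theta = 0.15)
  qd2 <- q_decomposition(te2, ne2, q_star = 1)
  expect_equal(qd2$q_het, 2 * dd^2 / s^2)
  expect_equal(qd2$q_inc, 0.15^2 / (s^2 / 2))
  expect_equal(qd2$q_total, qd2$q_inc + qd2$q_het, tolerance = 1e-12)
  expect_equal(qd2$df_het, 1)
})

test_that("Q = Qinc + Qhet exactly for random inputs", {
  set.seed(29)
  for (rep in 1:50) {
    n_designs <- sample(2:5, 1)
    te <- do.call(rbind, lapply(seq_len(n_designs), function(j) {
      k <- sample(1:6, 1)
      data.frame(design = paste0("d", j), trial = paste0("d", j, "_", 1:k),
                 theta = rnorm(k), se = runif(k, 0.05, 1))
    }))
    ne <- data.frame(design = paste0("d", seq_len(n_designs)),
                     theta = rnorm(n_designs))
    qd <- q_decomposition(te, ne, q_star = 1)
    expect_lt(abs(qd$q_total - (qd$q_inc + qd$q_het)), 1e-10)
    expect_equal(qd$df_total, qd$df_inc + qd$df_het)
    expect_gte(qd$q_inc, 0)
    expect_gte(qd$q_het, 0)
  }
  expect_error(q_decomposition(
    data.frame(design = "d", trial = "t", theta = 0, se = 0),
    data.frame(design = "d", theta = 0), q_star = 1),
    "non-positive standard error")
})

test_that("rank table rows and columns sum to 100 and match a sort oracle", {
  net <- network_spec(c("A", "B", "C"),
                      designs = list(c("A", "B"), c("A", "C")))
  fake_beta <- function(m) {
    colnames(m) <- c("beta[A:B]", "beta[A:C]")
    structure(list(draws = list(cbind(m, deviance = 0)),
                   param_names = colnames(m), n_chains = 1, n_burnin = 0,
                   n_iter = nrow(m), seed = 1,
                   spec = list(effect = "fixed", network = net)),
              class = "rp_chains")
  }
  # degenerate: B always the smallest effect
  m <- cbind(rep(-1, 200), rep(0.5, 200))
  rk <- rank_treatments(fake_beta(m))
  expect_equal(unname(rk["B", "rank1"]), 100)
  expect_equal(unname(rowSums(rk)), rep(100, 3))
  expect_equal(unname(colSums(rk)), rep(100, 3))

  # random draws: tally equals an independent per-draw sort
  set.seed(31)
  m2 <- matrix(rnorm(1000), ncol = 2)
  rk2 <- rank_treatments(fake_beta(m2))
  eff <- cbind(A = 0, B = m2[, 1], C = m2[, 2])
  oracle <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), NULL))
  for (i in seq_len(nrow(eff))) {
    o <- order(eff[i, ])
    for (k in 1:3) oracle[o[k], k] <- oracle[o[k], k] + 1
  }
  expect_equal(unname(unclass(rk2)), unname(100 * oracle / nrow(eff)))

  # permutation equivariance under treatment relabelling
  net_p <- network_spec(c("A", "C", "B"),
                        designs = list(c("A", "C"), c("A", "B")))
  m_p <- m2[, 2:1]
  colnames(m_p) <- c("beta[A:C]", "beta[A:B]")
  ch_p <- structure(list(draws = list(cbind(m_p, deviance = 0)),
                         param_names = colnames(m_p), n_chains = 1,
                         n_burnin = 0, n_iter = nrow(m_p), seed = 1,
                         spec = list(effect = "fixed", network = net_p)),
                    class = "rp_chains")
  rk_p <- rank_treatments(ch_p)
  expect_equal(unclass(rk_p)[c("A", "B", "C"), ],
               unclass(rk2)[c("A", "B", "C"), ])
})

test_that("pairwise MA recovers a known effect and matches its single-trial limit", {
  net <- two_arm_network()
  d <- multi_trial_ipd(5, 400, lhr = -0.3, seed = 71)
  fit <- fit_pairwise_ma(d, settings = quick_settings(seed = 3,
                                                      burnin = 600,
                                                      iter = 1200),
                         n_interior = 1)
  est <- fit$summaries[fit$summaries$comparison == "A:B", ]
  expect_lt(abs(est$mean - (-0.3)), 0.1)

  # a single trial is just the single-trial model
  d1 <- ipd_data(as.data.frame(d)[d$trial == "t1", ], net)
  fit1 <- fit_pairwise_ma(d1, settings = quick_settings(seed = 4,
                                                        burnin = 400,
                                                        iter = 800),
                          n_interior = 1)
  expect_equal(nrow(fit1$summaries), 1)
  expect_true(is.finite(fit1$dic$dic))
  # mixed designs are refused
  net3 <- network_spec(c("A", "B", "C"),
                       designs = list(c("A", "B"), c("A", "C")))
  dd <- ipd_data(rbind(weibull_trial(30, trial = "x1", seed = 72),
                       weibull_trial(30, trial = "x2", seed = 73,
                                     arms = c("A", "C"))), net3)
  expect_error(fit_pairwise_ma(dd), "mixed designs")
})

test_that("contrasts untouched by data return their prior", {
  # network declares A-B and A-C designs but the data only cover A-B:
  # the A:C effect must reproduce its prior spread
  net <- network_spec(c("A", "B", "C"),
                      designs = list(c("A", "B"), c("A", "C")))
  d <- ipd_data(weibull_trial(60, lhr = -0.3, seed = 74), net)
  spec <- model_spec(net, n_interior = 0)
  pr <- prior_spec(beta_var = 1)
  ch <- run_mcmc(spec, d, priors = pr,
                 settings = mcmc_settings(2, 1500, 4000, seed = 5))
  bc <- as.vector(rpnma:::all_draws(ch, "beta[A:C]"))
  expect_lt(abs(mean(bc)), 0.15)
  expect_lt(abs(sd(bc) - 1), 0.15)
})

test_that("disconnected networks are refused", {
  net <- network_spec(c("A", "B", "C", "D"),
                      designs = list(c("A", "B"), c("C", "D")))
  d <- ipd_data(rbind(weibull_trial(30, trial = "x1", seed = 75),
                      weibull_trial(30, trial = "x2", seed = 76,
                                    arms = c("C", "D"))), net)
  expect_error(fit_nma(d, model_spec(net, n_interior = 0)), "disconnected")
})

test_that("shrinkage intervals are symmetric and track their posterior", {
  net <- two_arm_network()
  d <- multi_trial_ipd(3, 60, lhr = -0.2, seed = 77)
  spec <- model_spec(net, interactions = "random", n_interior = 0)
  ch <- run_mcmc(spec, d, settings = quick_settings(seed = 6, burnin = 500,
                                                    iter = 800))
  si <- shrinkage_intervals(ch)
  expect_equal(nrow(si), 3)
  expect_equal(si$upper - si$mean, si$mean - si$lower, tolerance = 1e-10)
  expect_equal(si$upper, si$mean + 1.96 * si$sd)
  # wrong model variant
  spec0 <- model_spec(net, n_interior = 0)
  ch0 <- run_mcmc(spec0, d, settings = quick_settings(seed = 6,
                                                      burnin = 50,
                                                      iter = 60))
  expect_error(shrinkage_intervals(ch0), "no random-by-trial")
})

test_that("direct and indirect evidence separate coherently around omega", {
  net <- loop_network()
  set.seed(79)
  df <- rbind(weibull_trial(80, trial = "d1", arms = c("A", "B"),
                            lhr = -0.3),
              weibull_trial(80, trial = "d2", arms = c("A", "C"),
                            lhr = -0.1),
              weibull_trial(80, trial = "d3", arms = c("B", "C"),
                            lhr = 0.2))
  d <- ipd_data(df, net)
  spec <- model_spec(net, inconsistency = list(c("A", "B", "C")),
                     n_interior = 0)
  ev <- separate_direct_indirect(d, spec,
                                 settings = quick_settings(seed = 9,
                                                           burnin = 300,
                                                           iter = 500))
  tab <- ev$table
  expect_setequal(unique(tab$source), c("direct", "indirect", "network"))
  expect_setequal(unique(tab$comparison), c("A:B", "A:C", "B:C"))
  expect_true(all(tab$lower <= tab$estimate & tab$estimate <= tab$upper))
  # per-draw construction: direct minus indirect equals omega (or -omega)
  pick <- function(cmp, src)
    tab$estimate[tab$comparison == cmp & tab$source == src]
  w <- ev$omega$mean
  expect_equal(pick("B:C", "direct") - pick("B:C", "indirect"), w,
               tolerance = 1e-10)
  expect_equal(pick("A:B", "direct") - pick("A:B", "indirect"), w,
               tolerance = 1e-10)
  expect_equal(pick("A:C", "indirect") - pick("A:C", "direct"), w,
               tolerance = 1e-10)
})

test_that("per-trial estimates for Q come from Cox or the spline model", {
  net <- two_arm_network()
  d <- multi_trial_ipd(2, 120, lhr = -0.3, seed = 81)
  te_cox <- trial_effect_estimates(d)
  expect_equal(nrow(te_cox), 2)
  expect_true(all(te_cox$se > 0))
  te_rp <- trial_effect_estimates(d, estimator = "rp",
                                  settings = quick_settings(seed = 4,
                                                            burnin = 300,
                                                            iter = 500))
  expect_equal(te_rp$comparison, te_cox$comparison)
  # the two estimators agree within their (frequentist + posterior) spread
  expect_true(all(abs(te_rp$theta - te_cox$theta) <
                    3 * pmax(te_rp$se, te_cox$se)))
})

test_that("fixed and random effect fits agree when heterogeneity is absent", {
  net <- two_arm_network()
  d <- multi_trial_ipd(4, 150, lhr = -0.3, seed = 61)   # T_true = 0
  s <- mcmc_settings(2, 800, 1500, seed = 3)
  f <- run_mcmc(model_spec(net, effect = "fixed", n_interior = 1), d,
                settings = s)
  r <- run_mcmc(model_spec(net, effect = "random", n_interior = 1), d,
                settings = s)
  bf <- mean(rpnma:::all_draws(f, "beta[A:B]"))
  br <- mean(rpnma:::all_draws(r, "mu[A:B]"))
  expect_lt(abs(bf - br), 0.15)
  # the random-effect interval is at least as wide
  expect_gte(sd(rpnma:::all_draws(r, "mu[A:B]")),
             sd(rpnma:::all_draws(f, "beta[A:B]")))
})

test_that("a two-treatment network has no loop to separate", {
  net <- two_arm_network()
  d <- multi_trial_ipd(2, 40, seed = 78)
  spec <- model_spec(net, n_interior = 0)
  expect_error(separate_direct_indirect(d, spec), "exactly one loop")
})
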