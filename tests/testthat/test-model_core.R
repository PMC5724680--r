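cervical_style_network <- function() {
  network_spec(c("RT", "CTRT", "CT+RT", "CT+S"), reference = "RT",
               designs = list(c("RT", "CTRT"), c("RT", "CT+RT"),
                              c("RT", "CT+S"),
                              list(treatments = c("CT+RT", "CT+S"),
                                   reference = "CT+RT")),
               loops = list(c("RT", "CT+RT", "CT+S")))
}

test_that("treatment contrasts encode the consistency equations", {
  net <- cervical_style_network()
  # two-arm design vs the network reference: indicator of the non-ref arm
  expect_equal(build_contrasts(net, c("RT", "CTRT"), "CTRT"), c(1, 0, 0))
  # loop-closing design: -1 on RT:CT+RT and +1 on RT:CT+S for the CT+S arm
  expect_equal(build_contrasts(net, c("CT+RT", "CT+S"), "CT+S"),
               c(0, -1, 1))
  # any design reference arm is all zeros
  expect_equal(build_contrasts(net, c("CT+RT", "CT+S"), "CT+RT"),
               c(0, 0, 0))
  expect_equal(build_contrasts(net, c("RT", "CT+S"), "RT"), c(0, 0, 0))
  # three-arm design with the network reference
  net3 <- network_spec(c("RT", "CT+RT", "CT+S"), reference = "RT",
                       designs = list(c("RT", "CT+RT", "CT+S")))
  expect_equal(build_contrasts(net3, c("RT", "CT+RT", "CT+S"), "CT+S"),
               c(0, 1))
  expect_error(build_contrasts(net, c("RT", "CTRT"), "CT+S"),
               "not in design")
})

test_that("linear predictor assembles baseline, treatment, interaction and loop terms", {
  net <- two_arm_network()
  set.seed(2)
  d <- ipd_data(weibull_trial(60, seed = 2), net)
  spec <- model_spec(net, interactions = "fixed", n_interior = 1)
  md <- build_model_data(d, spec)
  st <- init_state(spec, md, d)

  # zero interaction, reference arm: eta is the spline alone
  st$beta <- 0; st$beta_int <- 0
  refrows <- which(md$trials$t1$C[, 1] == 0)
  lp <- linear_predictor(st, spec, md, "t1", rows = refrows)
  eta_spline <- drop(md$trials$t1$B[refrows, ] %*% st$gamma$t1)
  expect_equal(lp$eta, eta_spline)

  # beta enters eta, alpha enters both eta (times ln t) and deta
  st$beta <- -0.5; st$beta_int <- 0.2
  trt <- which(md$trials$t1$C[, 1] == 1)
  lp2 <- linear_predictor(st, spec, md, "t1", rows = trt)
  lnt <- md$trials$t1$lnt[trt]
  expect_equal(lp2$eta, drop(md$trials$t1$B[trt, ] %*% st$gamma$t1) -
                 0.5 + 0.2 * lnt)
  expect_equal(lp2$deta,
               drop(md$trials$t1$dB[trt, ] %*% st$gamma$t1) + 0.2)
})

test_that("deta is the ln-time derivative of eta (finite differences)", {
  net <- two_arm_network()
  set.seed(4)
  d <- ipd_data(weibull_trial(40, seed = 4), net)
  spec <- model_spec(net, interactions = "fixed", n_interior = 2)
  md <- build_model_data(d, spec)
  tr <- md$trials$t1
  h <- 1e-5
  set.seed(9)
  for (rep in 1:20) {
    gam <- rnorm(4, sd = 0.5); bet <- rnorm(1); alp <- rnorm(1, sd = 0.3)
    eta_at <- function(lnt) {
      drop(rcs_eval(tr$basis, lnt) %*% gam) +
        drop(tr$C %*% bet) + drop(tr$C %*% alp) * lnt
    }
    st <- init_state(spec, md, d)
    st$gamma$t1 <- gam; st$beta <- bet; st$beta_int <- alp
    lp <- linear_predictor(st, spec, md, "t1")
    fd <- (eta_at(tr$lnt + h) - eta_at(tr$lnt - h)) / (2 * h)
    expect_lt(max(abs(fd - lp$deta) / pmax(abs(lp$deta), 1)), 1e-6)
  }
})

test_that("log likelihood has the stated closed form on single patients", {
  net <- two_arm_network()
  # a state with eta = 0 at the patient's time: one censored patient
  # contributes -exp(0) = -1, one event with deta = 1 contributes -1 too
  df <- data.frame(trial = "t1", treatment = c("A", "B", "A"),
                   time = c(1, 1, 2), event = c(1, 0, 1))
  d <- ipd_data(df, net)
  spec <- model_spec(net, n_interior = 0)
  md <- build_model_data(d, spec, basis = "raw")
  st <- init_state(spec, md, d)
  st$beta <- 0
  st$gamma$t1 <- c(0, 1)   # eta = ln t, deta = 1; at t = 1: eta = 0
  ll_each <- rpnma:::loglik_contributions(st, spec, md)
  expect_equal(ll_each[1], -1)      # event at t=1: log 1 + 0 - 1
  expect_equal(ll_each[2], -1)      # censored at t=1: -exp(0)
  expect_equal(sum(ll_each), log_likelihood(st, spec, md))
})

test_that("with no interior knots the model is exactly Weibull", {
  net <- two_arm_network()
  set.seed(12)
  lam <- 0.3; shp <- 1.4
  tt <- rweibull(100, shape = shp, scale = lam^(-1 / shp))
  ev <- rbinom(100, 1, 0.7)
  if (!any(ev == 1)) ev[1] <- 1
  d <- ipd_data(data.frame(trial = "t1", treatment = rep(c("A", "B"), 50),
                           time = tt, event = ev), net)
  spec <- model_spec(net, n_interior = 0)
  md <- build_model_data(d, spec, basis = "raw")
  st <- init_state(spec, md, d)
  st$gamma$t1 <- c(log(lam), shp)
  st$beta <- 0
  ll <- log_likelihood(st, spec, md)
  # independent closed form: Weibull density on the ln-time scale
  oracle <- sum(ifelse(ev == 1,
                       dweibull(tt, shp, lam^(-1 / shp), log = TRUE) +
                         log(tt),
                       pweibull(tt, shp, lam^(-1 / shp), lower.tail = FALSE,
                                log.p = TRUE)))
  expect_equal(ll, oracle, tolerance = 1e-10)
})

test_that("likelihood domain and invariances hold", {
  net <- two_arm_network()
  d <- multi_trial_ipd(3, 60, lhr = -0.3, seed = 21)
  spec <- model_spec(net, n_interior = 1)
  md <- build_model_data(d, spec)
  st <- init_state(spec, md, d)
  st$beta <- -0.3
  ll0 <- log_likelihood(st, spec, md)
  expect_true(is.finite(ll0))

  # negative slope at an event time: -Inf, not an exception
  st_bad <- st
  st_bad$gamma$t1 <- c(st$gamma$t1[1], -1, 0)
  expect_identical(log_likelihood(st_bad, spec, md), -Inf)

  # invariance to patient and trial ordering
  set.seed(8)
  perm <- sample(nrow(d))
  d_perm <- ipd_data(as.data.frame(d)[perm, ], net)
  md_perm <- build_model_data(d_perm, spec)
  expect_equal(log_likelihood(st, spec, md_perm), ll0, tolerance = 1e-10)

  # zeros-trick equivalence: exp(-lambda_zero) is the patient likelihood
  contr <- rpnma:::loglik_contributions(st, spec, md)
  lambda_zero <- -contr
  expect_equal(exp(-lambda_zero), exp(contr), tolerance = 1e-12)
  expect_equal(sum(log(exp(-lambda_zero))), ll0, tolerance = 1e-8)

  # fixed interactions at zero reproduce the PH model exactly
  spec_i <- model_spec(net, interactions = "fixed", n_interior = 1)
  md_i <- build_model_data(d, spec_i)
  st_i <- init_state(spec_i, md_i, d)
  st_i$gamma <- st$gamma; st_i$beta <- st$beta; st_i$beta_int <- 0
  expect_equal(log_likelihood(st_i, spec_i, md_i), ll0, tolerance = 1e-12)
})

test_that("log prior matches closed forms and support constraints", {
  net <- two_arm_network()
  d <- multi_trial_ipd(2, 40, seed = 31)
  spec <- model_spec(net, n_interior = 1)
  md <- build_model_data(d, spec)
  st <- init_state(spec, md, d)
  st$gamma <- lapply(st$gamma, function(g) g * 0)
  st$beta <- 0
  lp <- log_prior(st, spec)
  m <- length(unlist(st$gamma))
  expect_equal(lp, m * dnorm(0, 0, 100, log = TRUE) +
                 dnorm(0, 0, sqrt(1000), log = TRUE))

  # negative sigma_u is outside the support
  spec_r <- model_spec(net, interactions = "random", n_interior = 1)
  md_r <- build_model_data(d, spec_r)
  st_r <- init_state(spec_r, md_r, d)
  st_r$sigma_u <- -0.1
  expect_identical(log_prior(st_r, spec_r), -Inf)

  # inverse-Wishart at T = I against a direct evaluation of its density
  q <- 2
  lmv <- 0.25 * q * (q - 1) * log(pi) + sum(lgamma(q / 2 + (1 - 1:q) / 2))
  direct <- -0.5 * q * q * log(2) - lmv - 0.5 * (q + q + 1) * 0 -
    0.5 * q   # tr(I %*% I) = q, log|V| = log|T| = 0
  expect_equal(rpnma:::dinvwishart_log(diag(q), diag(q), q), direct)

  # non-positive-definite T gives -Inf for the random-effect prior
  netq <- network_spec(c("A", "B", "C"),
                       designs = list(c("A", "B"), c("A", "C")))
  dq <- ipd_data(rbind(weibull_trial(30, trial = "x1", seed = 41),
                       weibull_trial(30, trial = "x2", seed = 42,
                                     arms = c("A", "C"))), netq)
  spec_q <- model_spec(netq, effect = "random", n_interior = 0)
  md_q <- build_model_data(dq, spec_q)
  st_q <- init_state(spec_q, md_q, dq)
  st_q$T <- matrix(c(1, 2, 2, 1), 2)   # not positive definite
  expect_identical(log_prior(st_q, spec_q), -Inf)
})

test_that("degenerate and malformed networks are rejected", {
  expect_error(network_spec(c("A", "B"), designs = list(c("A", "B")),
                            loops = list(c("A", "B", "B"))),
               "duplicate|three network treatments|no loop|reference")
  # loop needs a closing two-arm design
  expect_error(
    network_spec(c("A", "B", "C"), reference = "A",
                 designs = list(c("A", "B"), c("A", "C")),
                 loops = list(c("A", "B", "C"))),
    "no loop")
  # loops must be edge-disjoint
  expect_error(
    network_spec(c("A", "B", "C"), reference = "A",
                 designs = list(c("A", "B"), c("A", "C"),
                                list(treatments = c("B", "C"),
                                     reference = "B")),
                 loops = list(c("A", "B", "C"), c("A", "C", "B"))),
    "edge-disjoint|closing pair")
  # inconsistency loop must be declared
  net <- loop_network()
  expect_error(model_spec(net, inconsistency = list(c("A", "C", "B"))),
               "not declared")
})
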