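#' Nelson-Aalen cumulative hazard estimate
#'
#' Standard increments d_i/n_i at distinct event times; censoring reduces the
#' risk set after its time. Computed through the survival package's
#' counting-process estimator.
#'
#' @param times positive survival/censoring times.
#' @param events 0/1 event indicators.
#' @return list of class `rp_na` with `time` (distinct event times), `hazard`
#'   (cumulative hazard H), and `var` (its variance estimate).
#' @export
nelson_aalen <- function(times, events) {
  stopifnot(all(times > 0))
  if (!any(events == 1)) {
    warning("no events: Nelson-Aalen estimate is empty", call. = FALSE)
    return(structure(list(time = numeric(0), hazard = numeric(0),
                          var = numeric(0)), class = "rp_na"))
  }
  sf <- survival::survfit(survival::Surv(times, events) ~ 1, ctype = 1)
  keep <- sf$n.event > 0
  structure(list(time = sf$time[keep], hazard = sf$cumhaz[keep],
                 var = (sf$std.chaz[keep])^2), class = "rp_na")
}

#' @export
print.rp_na <- function(x, ...) {
  cat("Nelson-Aalen estimate over", length(x$time), "event times; H(max) =",
      if (length(x$hazard)) signif(utils::tail(x$hazard, 1), 5) else NA,
      "\n")
  invisible(x)
}

#' Cox proportional hazards fit for one trial
#'
#' Partial-likelihood fit with Breslow tie handling for a binary treatment
#' comparison, giving the log hazard ratio and its standard error from the
#' observed information.
#'
#' @param data rows for one trial: columns `time`, `event`, `treatment`.
#' @param treatment the non-reference arm label; default the second level in
#'   sort order.
#' @return list of class `rp_cox` with `loghr`, `se`, `fit` (the underlying
#'   coxph object), `trial`.
#' @export
cox_fit <- function(data, treatment = NULL) {
  arms <- sort(unique(data$treatment))
  if (length(arms) != 2)
    stop("cox_fit expects exactly two arms, got ",
         paste(arms, collapse = ", "), call. = FALSE)
  if (is.null(treatment)) treatment <- arms[2]
  x <- as.integer(data$treatment == treatment)
  for (a in 0:1)
    if (!any(data$event == 1 & x == a))
      stop("no events in one arm; Cox fit is unidentified", call. = FALSE)
  fit <- survival::coxph(survival::Surv(data$time, data$event) ~ x,
                         ties = "breslow")
  if (!is.finite(fit$coefficients) || abs(fit$coefficients) > 15)
    stop("monotone partial likelihood (complete separation of event orders)",
         call. = FALSE)
  structure(list(loghr = unname(fit$coefficients),
                 se = unname(sqrt(fit$var[1, 1])), fit = fit,
                 trial = unique(data$trial) %||% NA_character_),
            class = "rp_cox")
}

#' Schoenfeld residual test of proportional hazards
#'
#' Score-type test of zero association between the scaled Schoenfeld
#' residuals and a time transform; the default ln(t) transform aligns the
#' screen with the model's treatment-ln(time) interaction alternative. A
#' Kaplan-Meier-rank transform is available by flag.
#'
#' @param fit an `rp_cox` from [cox_fit()].
#' @param transform `"log"` (default) or `"km"`.
#' @return list of class `rp_schoenfeld` with `chisq`, `df` (1), `p`.
#' @export
schoenfeld_test <- function(fit, transform = c("log", "km")) {
  transform <- match.arg(transform)
  nev <- sum(fit$fit$nevent)
  if (nev < 3) stop("too few events (< 3) for a Schoenfeld test",
                    call. = FALSE)
  z <- survival::cox.zph(fit$fit, transform = transform, global = FALSE)
  structure(list(chisq = unname(z$table[1, "chisq"]), df = 1L,
                 p = unname(z$table[1, "p"]), transform = transform),
            class = "rp_schoenfeld")
}

#' Pool per-trial Schoenfeld tests
#'
#' Trials are independent, so the chi-squared statistics add, giving an
#' overall nonspecific test with degrees of freedom equal to the number of
#' trials.
#'
#' @param results list of `rp_schoenfeld` objects.
#' @return list of class `rp_schoenfeld_pooled` with per-trial values and
#'   `chisq`, `df`, `p` for the pooled test.
#' @export
pooled_schoenfeld <- function(results) {
  if (length(results) < 1) stop("no per-trial results", call. = FALSE)
  ch <- vapply(results, function(r) r$chisq, 0)
  df <- length(results)
  chisq <- sum(ch)
  structure(list(per_trial = data.frame(trial = seq_along(ch), chisq = ch,
                                        p = vapply(results,
                                                   function(r) r$p, 0)),
                 chisq = chisq, df = df,
                 p = stats::pchisq(chisq, df, lower.tail = FALSE)),
            class = "rp_schoenfeld_pooled")
}

#' @export
print.rp_schoenfeld_pooled <- function(x, ...) {
  cat("Pooled Schoenfeld test: chi-squared =", signif(x$chisq, 4), "on",
      x$df, "df, p =", signif(x$p, 3), "\n")
  invisible(x)
}

#' Compare a fitted spline baseline with the Nelson-Aalen estimate
#'
#' At each Nelson-Aalen step time, computes the posterior median and 95%
#' credible interval of the fitted model's log cumulative hazard for the
#' trial's reference arm, and the fraction of Nelson-Aalen points falling
#' inside the interval. Step times outside the boundary knots are evaluated
#' by the spline's linear tails.
#'
#' @param chains an `rp_chains` from a fit containing the trial.
#' @param trial trial id.
#' @param na an `rp_na` for the same trial (reference arm or whole trial).
#' @return data.frame (time, na_logH, model_median, model_lo, model_hi) with
#'   attribute `coverage` = fraction of points inside the interval.
#' @export
spline_vs_na <- function(chains, trial, na) {
  if (length(na$time) == 0)
    return(structure(data.frame(time = numeric(0), na_logH = numeric(0),
                                model_median = numeric(0),
                                model_lo = numeric(0),
                                model_hi = numeric(0)), coverage = NA_real_))
  tr <- chains$md$trials[[trial]]
  if (is.null(tr)) stop("trial '", trial, "' not in the fit", call. = FALSE)
  gpars <- paste0("gamma[", trial, ",", seq_len(ncol(tr$B)), "]")
  G <- all_draws(chains, gpars)
  B <- if (chains$md$basis_kind == "raw")
    cbind(1, rcs_raw(log(na$time), tr$knots))
  else rcs_eval(tr$basis, log(na$time))
  eta <- B %*% t(G)   # times x draws
  qs <- t(apply(eta, 1, stats::quantile, c(0.5, 0.025, 0.975)))
  keep <- na$hazard > 0
  out <- data.frame(time = na$time, na_logH = ifelse(keep, log(na$hazard),
                                                     NA_real_),
                    model_median = qs[, 1], model_lo = qs[, 2],
                    model_hi = qs[, 3])
  cov <- mean(out$na_logH >= out$model_lo & out$na_logH <= out$model_hi,
              na.rm = TRUE)
  structure(out, coverage = cov)
}
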