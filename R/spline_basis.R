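#' Place restricted-cubic-spline knots for one trial
#'
#' Boundary knots sit at the minimum and maximum uncensored ln(time); interior
#' knots at centiles of the uncensored ln(times): \{50\} for one knot,
#' \{33, 67\} for two, \{25, 50, 75\} for three. Centiles are empirical
#' quantiles with linear interpolation between order statistics. Custom knots
#' (on the ln scale) override the defaults after validation.
#'
#' @param data `rp_ipd` rows for a single trial (or any data frame with
#'   `time` and `event`).
#' @param n_interior number of interior knots, 0..3 (ignored when `custom`
#'   given).
#' @param custom optional numeric vector of interior knots on the ln-time
#'   scale.
#' @param scale `"ln"` (default) or `"time"`: scale on which `custom` is
#'   expressed; stored internally on the ln scale.
#' @return list of class `rp_knots` with `interior`, `boundary_min`,
#'   `boundary_max` (all ln scale).
#' @export
place_knots <- function(data, n_interior = 2L, custom = NULL,
                        scale = c("ln", "time")) {
  scale <- match.arg(scale)
  if (length(unique(data$trial)) > 1)
    stop("place_knots expects data from a single trial", call. = FALSE)
  lt <- log(data$time[data$event == 1])
  if (!is.null(custom) && scale == "time") custom <- log(custom)
  p <- if (is.null(custom)) as.integer(n_interior) else length(custom)
  if (is.null(custom) && (p < 0 || p > 3))
    stop("n_interior must be between 0 and 3", call. = FALSE)
  if (length(unique(lt)) < p + 2)
    stop("too few distinct uncensored times (need >= ", p + 2,
         ") to place ", p, " interior knot(s)", call. = FALSE)
  bmin <- min(lt); bmax <- max(lt)
  if (is.null(custom)) {
    cent <- switch(as.character(p), "0" = numeric(0), "1" = 0.50,
                   "2" = c(0.33, 0.67), "3" = c(0.25, 0.50, 0.75))
    interior <- as.numeric(stats::quantile(lt, cent, type = 7, names = FALSE))
  } else {
    interior <- sort(as.numeric(custom))
    if (anyDuplicated(interior))
      stop("duplicate interior knots", call. = FALSE)
    if (any(interior <= bmin | interior >= bmax))
      stop("custom knots must lie strictly inside the boundary knots (",
           signif(bmin, 6), ", ", signif(bmax, 6), ") on the ln scale",
           call. = FALSE)
  }
  if (anyDuplicated(c(bmin, interior, bmax)))
    stop("duplicate knots", call. = FALSE)
  structure(list(interior = interior, boundary_min = bmin,
                 boundary_max = bmax), class = "rp_knots")
}

#' @export
print.rp_knots <- function(x, ...) {
  cat("RCS knots (ln-time scale): boundaries [", signif(x$boundary_min, 5),
      ",", signif(x$boundary_max, 5), "], interior {",
      paste(signif(x$interior, 5), collapse = ", "), "}\n")
  invisible(x)
}

#' Raw restricted cubic spline basis of ln(time)
#'
#' Column 1 is ln(t) itself; column j+1 is
#' v_j(x) = (x-k_j)_+^3 - lambda_j (x-k_min)_+^3 - (1-lambda_j)(x-k_max)_+^3
#' with lambda_j = (k_max-k_j)/(k_max-k_min). The resulting function space is
#' continuous with continuous first and second derivatives and exactly linear
#' outside the boundary knots.
#'
#' @param ln_times numeric vector on the ln-time scale.
#' @param knots an `rp_knots` object.
#' @return matrix with `1 + length(knots$interior)` columns.
#' @export
rcs_raw <- function(ln_times, knots) {
  x <- as.numeric(ln_times)
  kmin <- knots$boundary_min; kmax <- knots$boundary_max
  out <- matrix(x, nrow = length(x), ncol = 1)
  for (kj in knots$interior) {
    lam <- (kmax - kj) / (kmax - kmin)
    out <- cbind(out, pmax(x - kj, 0)^3 - lam * pmax(x - kmin, 0)^3 -
                        (1 - lam) * pmax(x - kmax, 0)^3)
  }
  colnames(out) <- c("lnt", if (length(knots$interior))
    paste0("v", seq_along(knots$interior)))
  out
}

# derivative of the raw basis w.r.t. ln(time): d/dx lnt = 1;
# dv_j = 3(x-k_j)_+^2 - 3 lambda_j (x-k_min)_+^2 - 3(1-lambda_j)(x-k_max)_+^2
rcs_raw_deriv <- function(ln_times, knots) {
  x <- as.numeric(ln_times)
  kmin <- knots$boundary_min; kmax <- knots$boundary_max
  out <- matrix(1, nrow = length(x), ncol = 1)
  for (kj in knots$interior) {
    lam <- (kmax - kj) / (kmax - kmin)
    out <- cbind(out, 3 * pmax(x - kj, 0)^2 - 3 * lam * pmax(x - kmin, 0)^2 -
                        3 * (1 - lam) * pmax(x - kmax, 0)^2)
  }
  out
}

#' Gram-Schmidt orthogonalisation of a spline basis
#'
#' Orthogonalises the raw basis columns against the intercept and each other
#' over the construction sample (QR factorisation with the intercept first,
#' columns rescaled so the intercept stays 1 and each orthogonal column has a
#' positive inner product with its raw source). Records the invertible
#' (p+2)x(p+2) transform carrying [1, raw] to [1, ortho], so the basis can be
#' evaluated (and differentiated) at new times and so that fitted linear
#' predictors are invariant to the change of basis.
#'
#' @param ln_times construction sample on the ln-time scale (a trial's event
#'   and censoring times).
#' @param knots an `rp_knots` object.
#' @return object of class `rp_basis`: list with `knots`, `transform`,
#'   `raw`, `ortho`, `ortho_deriv` (matrices over the construction sample).
#' @export
orthogonalise <- function(ln_times, knots) {
  raw <- rcs_raw(ln_times, knots)
  X <- cbind(1, raw)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular basis: spline columns are linearly dependent over this ",
         "trial's times", call. = FALSE)
  Q <- qr.Q(qrX)
  R <- qr.R(qrX)
  n <- nrow(X)
  # rescale so column 1 is exactly the intercept and the rest are O(1)
  Tm <- solve(R) * sqrt(n)
  # sign convention: ortho column k has positive inner product with raw k
  ortho_all <- X %*% Tm
  for (k in 2:ncol(Tm)) {
    s <- sum(ortho_all[, k] * raw[, k - 1])
    if (s < 0) Tm[, k] <- -Tm[, k]
  }
  if (Tm[1, 1] < 0) Tm[, 1] <- -Tm[, 1]
  Tm[, 1] <- Tm[, 1] / Tm[1, 1]  # exact intercept
  ortho_all <- X %*% Tm
  draw <- rcs_raw_deriv(ln_times, knots)
  dortho <- cbind(0, draw) %*% Tm
  structure(list(knots = knots, transform = Tm, raw = raw,
                 ortho = ortho_all[, -1, drop = FALSE],
                 ortho_deriv = dortho[, -1, drop = FALSE]),
            class = "rp_basis")
}

#' Evaluate an orthogonalised basis at new ln-times
#'
#' @param basis an `rp_basis`.
#' @param ln_times numeric vector.
#' @return matrix `[u0 ... up]` including the leading intercept column of 1s
#'   as column 1 (so `eta = B %*% gamma`).
#' @export
rcs_eval <- function(basis, ln_times) {
  cbind(1, rcs_raw(ln_times, basis$knots)) %*% basis$transform
}

#' Derivative of the orthogonalised basis with respect to ln(time)
#'
#' Analytic derivative of each raw column mapped through the same transform
#' as the basis itself; column 1 (intercept) has derivative 0.
#'
#' @param ln_times numeric vector.
#' @param knots an `rp_knots` object.
#' @param transform the transform recorded by [orthogonalise()]; identity
#'   behaviour (raw-basis derivatives with a leading zero column) when NULL.
#' @return matrix of derivatives, same shape as [rcs_eval()] output.
#' @export
rcs_deriv <- function(ln_times, knots, transform = NULL) {
  D <- cbind(0, rcs_raw_deriv(ln_times, knots))
  if (is.null(transform)) D else D %*% transform
}
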