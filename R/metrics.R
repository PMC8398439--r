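#' Transfer (dissolution) profile container
#'
#' A cumulative-transfer profile: percent of the initial donor amount that
#' has reached the receptor (including earlier removed samples) at each
#' sampling time.
#'
#' @param time_min Strictly increasing sampling times, minutes.
#' @param cumulative_percent Cumulative transferred percent at each time.
#' @return A data frame of class \code{"transfer_profile"} with columns
#'   \code{time_min} and \code{cumulative_percent}.
#' @export
transfer_profile <- function(time_min, cumulative_percent) {
  if (length(time_min) != length(cumulative_percent))
    stop("time_min and cumulative_percent must have the same length")
  if (any(!is.finite(time_min)) || any(diff(time_min) <= 0))
    stop("time_min must be strictly increasing")
  # small headroom above 100 for noisy bench measurements
  if (any(!is.finite(cumulative_percent)) || any(cumulative_percent < -1e-9) ||
      any(cumulative_percent > 110))
    stop("cumulative_percent must lie in [0, 100] (plus measurement noise)")
  structure(data.frame(time_min = as.numeric(time_min),
                       cumulative_percent = as.numeric(cumulative_percent)),
            class = c("transfer_profile", "data.frame"))
}

.as_profile <- function(x) {
  if (inherits(x, "transwell_sim")) return(x$observed)
  if (inherits(x, "transfer_profile")) return(x)
  if (is.data.frame(x) && all(c("time_min", "cumulative_percent") %in% names(x)))
    return(transfer_profile(x$time_min, x$cumulative_percent))
  stop("expected a transfer_profile, a compatible data frame, or a transwell_sim")
}

#' Read / write transfer-profile CSV files
#'
#' CSV with columns \code{time_min}, \code{cumulative_percent}.
#' @param path File path.
#' @return \code{read_profile}: a \code{\link{transfer_profile}}.
#' @export
read_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "cumulative_percent") %in% names(df)))
    stop("profile CSV must have columns time_min, cumulative_percent")
  transfer_profile(df$time_min, df$cumulative_percent)
}

#' @rdname read_profile
#' @param profile A profile to serialize.
#' @export
write_profile <- function(profile, path) {
  profile <- .as_profile(profile)
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Fit the Weibull function to a transfer profile
#'
#' Nonlinear least squares of
#' \deqn{Y_t = 100\,(1 - e^{-(t/MDT)^b})}
#' on the percent scale (unweighted). MDT is the mean dissolution
#' (transfer) time scale parameter and b the shape parameter; both are
#' constrained positive. Initialization: MDT at the interpolated time the
#' profile first reaches 63.2\%, b = 1.
#'
#' @param profile A \code{\link{transfer_profile}}, compatible data frame,
#'   or \code{"transwell_sim"} (its observed profile is used).
#' @return An object of class \code{"weibull_fit"} with components
#'   \code{mdt_min}, \code{mdt_hours}, \code{shape}, \code{residual_sse},
#'   \code{converged} and the underlying \code{nls} fit.
#' @examples
#' t <- c(10, 20, 30, 45, 60, 90, 120, 180, 240)
#' y <- 100 * (1 - exp(-(t / 35)^0.9))
#' fit_weibull(transfer_profile(t, y))
#' @export
fit_weibull <- function(profile) {
  pr <- .as_profile(profile)
  if (nrow(pr) < 3)
    stop("at least 3 profile points are required")
  if (diff(range(pr$cumulative_percent)) <= 5)
    stop("degenerate (flat) profile: percent spread must exceed 5")
  t <- pr$time_min; y <- pr$cumulative_percent
  mdt0 <- if (max(y) >= 63.2) {
    i <- which(y >= 63.2)[1]
    if (i == 1) t[1] else
      t[i - 1] + (63.2 - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  } else max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 100 * (1 - exp(-(t / mdt)^b)),
                      start = list(mdt = mdt0, b = 1),
                      lower = c(1e-6, 1e-3), upper = c(Inf, Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Weibull fit failed: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  structure(list(mdt_min = unname(cf["mdt"]),
                 mdt_hours = unname(cf["mdt"]) / 60,
                 shape = unname(cf["b"]),
                 residual_sse = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 fit = fit, profile = pr),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit: MDT = %.4g min (%.4g h), b = %.4g, SSE = %.3g\n",
              x$mdt_min, x$mdt_hours, x$shape, x$residual_sse))
  invisible(x)
}

#' @export
coef.weibull_fit <- function(object, ...) {
  c(mdt_min = object$mdt_min, shape = object$shape)
}

#' @export
predict.weibull_fit <- function(object, time_min = object$profile$time_min, ...) {
  100 * (1 - exp(-(time_min / object$mdt_min)^object$shape))
}

#' f1 difference and f2 similarity factors
#'
#' Regulatory profile-comparison metrics over the common sampling
#' timepoints of a reference profile R and a test profile T:
#' \deqn{f_1 = 100\,\sum_t |R_t - T_t| / \sum_t R_t}
#' \deqn{f_2 = 50\,\log_{10}\!\left(100\,\big(1 + \tfrac1n\sum_t (R_t-T_t)^2\big)^{-1/2}\right)}
#' Profiles are declared \code{"different"} only when both f1 > 15 and
#' f2 < 50, otherwise \code{"similar"}.
#'
#' @param reference,test Profiles (any form accepted by
#'   \code{\link{fit_weibull}}). Comparison is restricted to timepoints the
#'   two share; at least 3 are required.
#' @param truncate_after_85 If \code{TRUE}, drop timepoints after the first
#'   at which the reference reaches 85\% (keeping that point), the usual
#'   regulatory convention. Off by default: all common scheduled timepoints
#'   are used.
#' @return An object of class \code{"profile_comparison"}: list with
#'   \code{f1}, \code{f2}, \code{verdict}, \code{n_points}.
#' @examples
#' r <- transfer_profile(c(10, 20, 30), c(10, 20, 30))
#' s <- transfer_profile(c(10, 20, 30), c(12, 22, 32))
#' f1_f2(r, s)
#' @export
f1_f2 <- function(reference, test, truncate_after_85 = FALSE) {
  r <- .as_profile(reference); s <- .as_profile(test)
  common <- intersect(r$time_min, s$time_min)
  if (length(common) < 3)
    stop("profiles share fewer than 3 common timepoints")
  common <- sort(common)
  R <- r$cumulative_percent[match(common, r$time_min)]
  T_ <- s$cumulative_percent[match(common, s$time_min)]
  if (truncate_after_85 && any(R >= 85)) {
    keep <- seq_len(which(R >= 85)[1])
    if (length(keep) >= 3) { R <- R[keep]; T_ <- T_[keep]; common <- common[keep] }
  }
  if (sum(R) == 0) stop("f1 undefined: reference profile sums to zero")
  n <- length(R)
  f1 <- 100 * sum(abs(R - T_)) / sum(R)
  f2 <- 50 * log10(100 * (1 + sum((R - T_)^2) / n)^(-0.5))
  structure(list(f1 = f1, f2 = f2,
                 verdict = if (f1 > 15 && f2 < 50) "different" else "similar",
                 n_points = n, time_min = common),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("f1 = %.3g, f2 = %.3g over %d timepoints: profiles are %s\n",
              x$f1, x$f2, x$n_points, x$verdict))
  invisible(x)
}

#' First time a cumulative profile reaches a given fraction
#'
#' Linear interpolation of the first crossing. For a
#' \code{"transwell_sim"} the dense trajectory is used; for a plain profile
#' the observed points.
#'
#' @param x A \code{"transwell_sim"} or transfer profile.
#' @param fraction Target fraction of the initial amount, in [0, 1].
#' @return Crossing time in minutes.
#' @examples
#' p <- transfer_profile(c(30, 60, 90), c(30, 60, 90))
#' time_to_fraction(p, 0.45)  # 45 min
#' @export
time_to_fraction <- function(x, fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  if (fraction == 0) return(0)
  if (inherits(x, "transwell_sim")) {
    t <- x$time_min; y <- x$cumulative_percent
  } else {
    pr <- .as_profile(x); t <- c(0, pr$time_min); y <- c(0, pr$cumulative_percent)
  }
  target <- 100 * fraction
  above <- which(y >= target)
  if (length(above) == 0)
    stop("profile never attains ", target, "% (max ", round(max(y), 2), "%)")
  i <- above[1]
  if (i == 1) return(t[1])
  t[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
}

#' Ratio of fitted mean dissolution times
#'
#' Mass-effect summary: the MDT of a higher-dose run divided by the MDT of
#' a lower-dose run under otherwise identical conditions.
#'
#' @param high,low \code{"transwell_sim"} objects, transfer profiles, or
#'   \code{"weibull_fit"}s; profiles/simulations are fitted with
#'   \code{\link{fit_weibull}}.
#' @return Dimensionless MDT ratio.
#' @export
mdt_ratio <- function(high, low) {
  m <- function(z) if (inherits(z, "weibull_fit")) z$mdt_min else
    fit_weibull(z)$mdt_min
  m(high) / m(low)
}
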