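#' Construct a digitized Kaplan-Meier curve
#'
#' Represents survival-probability coordinates read off a published
#' Kaplan-Meier plot (e.g. with a graph digitizer), for one endpoint of one
#' trial arm. A `(0, 1)` origin is prepended when absent.
#'
#' @param time Numeric vector of times in months, strictly increasing, >= 0.
#' @param survival Numeric vector of survival probabilities in `[0, 1]`,
#'   non-increasing, same length as `time`.
#' @param n_at_risk_start Number of subjects at risk at time 0.
#' @param endpoint Endpoint label, `"PFS"` or `"OS"`.
#' @param arm Arm label, e.g. `"TC"` or `"PC"`.
#' @return An object of class `digitized_curve`.
#' @examples
#' digitized_curve(c(0, 6, 12), c(1, 0.5, 0.25), n_at_risk_start = 8)
#' @export
digitized_curve <- function(time, survival, n_at_risk_start,
                            endpoint = "PFS", arm = "TC") {
  if (length(time) != length(survival)) {
    stop("time and survival must have equal length", call. = FALSE)
  }
  if (length(time) == 0L) stop("empty curve", call. = FALSE)
  if (any(time < 0)) stop("negative time in digitized curve", call. = FALSE)
  if (any(survival < 0 | survival > 1)) {
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  ord <- order(time)
  time <- time[ord]; survival <- survival[ord]
  if (anyDuplicated(time)) stop("times must be strictly increasing", call. = FALSE)
  if (time[1] > 0) {
    time <- c(0, time); survival <- c(1, survival)
  }
  if (abs(survival[1] - 1) > 1e-9) {
    stop("survival at time 0 must be 1", call. = FALSE)
  }
  bad <- which(diff(survival) > 1e-12)
  if (length(bad)) {
    stop(sprintf(
      "survival increases between t = %g and t = %g (%.4f -> %.4f): curve is not monotone",
      time[bad[1]], time[bad[1] + 1], survival[bad[1]], survival[bad[1] + 1]
    ), call. = FALSE)
  }
  if (!is.numeric(n_at_risk_start) || n_at_risk_start < 1) {
    stop("n_at_risk_start must be a positive count", call. = FALSE)
  }
  structure(
    list(time = time, survival = pmin(survival, 1), endpoint = endpoint,
         arm = arm, n_at_risk_start = as.integer(n_at_risk_start)),
    class = "digitized_curve"
  )
}

#' Read a digitized curve from CSV
#'
#' Expects a header `time_months,survival`.
#'
#' @param path CSV file path.
#' @inheritParams digitized_curve
#' @return A `digitized_curve`.
#' @export
read_digitized_curve <- function(path, n_at_risk_start, endpoint = "PFS", arm = "TC") {
  df <- utils::read.csv(path)
  if (!all(c("time_months", "survival") %in% names(df))) {
    stop("expected columns time_months,survival in ", path, call. = FALSE)
  }
  digitized_curve(df$time_months, df$survival, n_at_risk_start, endpoint, arm)
}

#' Reconstruct pseudo individual-patient data from a digitized curve
#'
#' Converts digitized Kaplan-Meier coordinates into per-subject
#' `(time, event)` records by an interval event-count method: within each
#' digitized interval, the number of events is the at-risk count times the
#' conditional drop, rounded to the nearest integer, and event times are
#' placed at the interval midpoint. No censoring is assumed before the end of
#' follow-up; subjects still at risk past the last digitized point are
#' administratively censored at `censor_time`. The Kaplan-Meier estimator
#' recomputed from the output reproduces the input coordinates to within
#' digitization resolution.
#'
#' @param curve A [digitized_curve()].
#' @param censor_time Administrative censoring time in months; must be at
#'   least the last digitized time.
#' @return A `pseudo_ipd` object: a data frame with columns `time` (months)
#'   and `event` (1 = event, 0 = censored), with `endpoint` and `arm`
#'   attributes. Row count equals `n_at_risk_start`.
#' @examples
#' cv <- digitized_curve(c(0, 6, 12), c(1, 0.5, 0.25), n_at_risk_start = 8)
#' ipd <- reconstruct_ipd(cv, censor_time = 12)
#' table(ipd$event)
#' @export
reconstruct_ipd <- function(curve, censor_time) {
  stopifnot(inherits(curve, "digitized_curve"))
  tm <- curve$time; sv <- curve$survival
  if (censor_time < tm[length(tm)]) {
    stop("censor_time must be >= the last digitized time", call. = FALSE)
  }
  n_risk <- curve$n_at_risk_start
  times <- numeric(0); events <- integer(0)
  if (length(tm) > 1) {
    for (i in 2:length(tm)) {
      s_prev <- sv[i - 1]; s_cur <- sv[i]
      drop <- if (s_prev > 0) 1 - s_cur / s_prev else 0
      k <- round(n_risk * drop)
      k <- min(k, n_risk)
      if (k > 0) {
        mid <- (tm[i - 1] + tm[i]) / 2
        times <- c(times, rep(mid, k)); events <- c(events, rep(1L, k))
        n_risk <- n_risk - k
      }
    }
  }
  if (n_risk > 0) {
    times <- c(times, rep(censor_time, n_risk))
    events <- c(events, rep(0L, n_risk))
  }
  if (any(sv < 1) && !any(events == 1L)) {
    stop("curve drops but no events were reconstructed; n_at_risk_start too small",
         call. = FALSE)
  }
  pseudo_ipd(times, events, endpoint = curve$endpoint, arm = curve$arm)
}

#' Construct a pseudo-IPD object
#'
#' @param time Observed times in months, > 0 for events.
#' @param event Event indicator (1 = event, 0 = censored).
#' @param endpoint,arm Labels carried as attributes.
#' @return A data frame of class `pseudo_ipd`.
#' @export
pseudo_ipd <- function(time, event, endpoint = "PFS", arm = "TC") {
  stopifnot(length(time) == length(event), all(event %in% c(0L, 1L)),
            all(time >= 0))
  df <- data.frame(time = as.numeric(time), event = as.integer(event))
  attr(df, "endpoint") <- endpoint
  attr(df, "arm") <- arm
  class(df) <- c("pseudo_ipd", "data.frame")
  df
}

#' @export
print.pseudo_ipd <- function(x, ...) {
  cat(sprintf("Pseudo-IPD: %s / %s, %d subjects (%d events, %d censored)\n",
              attr(x, "arm"), attr(x, "endpoint"), nrow(x),
              sum(x$event), sum(1 - x$event)))
  invisible(x)
}

#' Write pseudo-IPD to CSV
#'
#' Columns `time_months,event`.
#'
#' @param ipd A `pseudo_ipd`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pseudo_ipd <- function(ipd, path) {
  utils::write.csv(
    data.frame(time_months = ipd$time, event = ipd$event),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read pseudo-IPD from CSV
#'
#' @param path CSV with columns `time_months,event`.
#' @inheritParams pseudo_ipd
#' @return A `pseudo_ipd`.
#' @export
read_pseudo_ipd <- function(path, endpoint = "PFS", arm = "TC") {
  df <- utils::read.csv(path)
  pseudo_ipd(df$time_months, df$event, endpoint = endpoint, arm = arm)
}

#' Kaplan-Meier survival at given times
#'
#' Convenience wrapper around [survival::survfit()] evaluating the product-limit
#' estimate of a pseudo-IPD set at arbitrary times.
#'
#' @param ipd A `pseudo_ipd`.
#' @param times Times (months) at which to evaluate the step function.
#' @return Survival probabilities at `times`.
#' @export
km_survival_at <- function(ipd, times) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  sf <- summary(fit, times = times, extend = TRUE)
  sf$surv
}
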