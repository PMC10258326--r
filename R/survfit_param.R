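# Family registry. Parameterizations follow flexsurv's conventions and are
# part of the package contract:
#   exponential : rate                      S(t) = exp(-rate t)
#   weibull     : shape, scale (AFT)        S(t) = exp(-(t/scale)^shape)
#   gompertz    : shape (may be < 0), rate  S(t) = exp(-rate/shape (e^{shape t}-1))
#   gamma       : shape, rate
#   loglogistic : shape, scale              S(t) = 1/(1+(t/scale)^shape)
#   lognormal   : meanlog, sdlog            S(t) = 1-Phi((ln t-meanlog)/sdlog)
SURV_FAMILIES <- c("weibull", "exponential", "gompertz", "gamma",
                   "loglogistic", "lognormal")

.flexsurv_dist <- c(weibull = "weibull", exponential = "exp",
                    gompertz = "gompertz", gamma = "gamma",
                    loglogistic = "llogis", lognormal = "lnorm")

.dist_fns <- list(
  weibull     = list(p = stats::pweibull, q = stats::qweibull),
  exponential = list(p = stats::pexp, q = stats::qexp),
  gompertz    = list(p = flexsurv::pgompertz, q = flexsurv::qgompertz),
  gamma       = list(p = stats::pgamma, q = stats::qgamma),
  loglogistic = list(p = flexsurv::pllogis, q = flexsurv::qllogis),
  lognormal   = list(p = stats::plnorm, q = stats::qlnorm)
)

#' Fit a parametric survival distribution to right-censored data
#'
#' Maximum-likelihood fit of one of six parametric families to a pseudo-IPD
#' set, maximizing the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)}.
#' Optimization is delegated to [flexsurv::flexsurvreg()]. AIC and BIC use
#' \eqn{2k - 2\ell} and \eqn{k\log n - 2\ell} with `n` the number of subjects.
#'
#' @param data A `pseudo_ipd` (or data frame with `time` and `event`
#'   columns); at least 2 events required, all times > 0.
#' @param family One of `"weibull"`, `"exponential"`, `"gompertz"`,
#'   `"gamma"`, `"loglogistic"`, `"lognormal"`.
#' @return An object of class `psm_fit` with elements `family`, `params`
#'   (named, natural scale), `loglik`, `k`, `n_obs`, `aic`, `bic`,
#'   `converged`.
#' @examples
#' d <- pseudo_ipd(c(rep(5, 10), rep(10, 5)), c(rep(1, 10), rep(0, 5)))
#' fit_distribution(d, "exponential")$params  # rate = events / exposure
#' @export
fit_distribution <- function(data, family) {
  family <- match.arg(family, SURV_FAMILIES)
  if (any(data$time <= 0)) stop("all times must be > 0", call. = FALSE)
  if (sum(data$event) < 2) {
    stop("at least 2 events are required to fit a survival distribution",
         call. = FALSE)
  }
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = data,
                          dist = .flexsurv_dist[[family]]),
    error = function(e) {
      stop(sprintf("fit of %s family did not converge: %s",
                   family, conditionMessage(e)), call. = FALSE)
    }
  )
  params <- fit$res[, "est"]
  names(params) <- rownames(fit$res)
  k <- fit$npars
  n <- nrow(data)
  ll <- fit$loglik
  structure(
    list(family = family, params = params, loglik = ll, k = k, n_obs = n,
         aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
         converged = TRUE, n_events = sum(data$event),
         endpoint = attr(data, "endpoint"), arm = attr(data, "arm")),
    class = "psm_fit"
  )
}

#' @export
print.psm_fit <- function(x, ...) {
  cat(sprintf("Parametric survival fit: %s (%s / %s)\n", x$family,
              x$arm %||% "?", x$endpoint %||% "?"))
  cat("  params:", paste(sprintf("%s = %.5g", names(x$params), x$params),
                         collapse = ", "), "\n")
  cat(sprintf("  loglik = %.3f, AIC = %.2f, BIC = %.2f (n = %d, events = %d)\n",
              x$loglik, x$aic, x$bic, x$n_obs, x$n_events))
  invisible(x)
}

#' Fit all six candidate families
#'
#' Fits every family in the registry, collecting convergence failures
#' instead of stopping, so model selection can proceed on the survivors.
#'
#' @inheritParams fit_distribution
#' @return A named list of `psm_fit` objects (failed fits omitted, with a
#'   warning naming them).
#' @export
fit_all_distributions <- function(data) {
  fits <- list()
  failed <- character(0)
  for (fam in SURV_FAMILIES) {
    f <- tryCatch(fit_distribution(data, fam), error = function(e) NULL)
    if (is.null(f)) failed <- c(failed, fam) else fits[[fam]] <- f
  }
  if (length(failed)) {
    warning("families failed to converge: ", paste(failed, collapse = ", "),
            call. = FALSE)
  }
  if (!length(fits)) stop("no family converged", call. = FALSE)
  fits
}

#' Select the best-fitting distribution
#'
#' Minimum-AIC (or minimum-BIC) selection among converged fits. With
#' `criterion = "both"` the AIC winner is returned and a message is emitted
#' if BIC would pick a different family. Ties are broken by fewer parameters,
#' then by the fixed family order of the registry.
#'
#' @param fits List of `psm_fit` objects.
#' @param criterion `"aic"`, `"bic"`, or `"both"`.
#' @return The selected `psm_fit`.
#' @export
select_best <- function(fits, criterion = c("aic", "bic", "both")) {
  criterion <- match.arg(criterion)
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  pick <- function(crit) {
    vals <- vapply(fits, function(f) f[[crit]], numeric(1))
    ks <- vapply(fits, function(f) f$k, numeric(1))
    fam_rank <- match(vapply(fits, function(f) f$family, character(1)),
                      SURV_FAMILIES)
    ord <- order(vals, ks, fam_rank)
    fits[[ord[1]]]
  }
  if (criterion == "both") {
    best_aic <- pick("aic"); best_bic <- pick("bic")
    if (!identical(best_aic$family, best_bic$family)) {
      message(sprintf("AIC selects %s but BIC selects %s; returning the AIC winner",
                      best_aic$family, best_bic$family))
    }
    best_aic
  } else {
    pick(criterion)
  }
}

#' Evaluate a fitted survival function
#'
#' Closed-form survival probabilities for a `psm_fit` at given times.
#'
#' @param fit A `psm_fit`.
#' @param times Times in months, >= 0.
#' @return Vector of survival probabilities; `S(0) = 1`.
#' @examples
#' f <- structure(list(family = "exponential", params = c(rate = 0.1)),
#'                class = "psm_fit")
#' survival_at(f, c(0, 10))  # 1, exp(-1)
#' @export
survival_at <- function(fit, times) {
  stopifnot(inherits(fit, "psm_fit"))
  if (any(times < 0)) stop("negative time", call. = FALSE)
  pfun <- .dist_fns[[fit$family]]$p
  args <- c(list(q = times), as.list(unname(fit$params)), lower.tail = FALSE)
  names(args)[2:(1 + length(fit$params))] <- names(formals(pfun))[2:(1 + length(fit$params))]
  do.call(pfun, args)
}

#' Median survival time of a fitted distribution
#'
#' Solves `S(m) = 0.5` via the family's quantile function (closed form where
#' one exists). For distributions whose survival plateaus above 0.5 (a
#' negative-shape Gompertz) the median is `Inf`.
#'
#' @param fit A `psm_fit`.
#' @return Median in months.
#' @export
fitted_median <- function(fit) {
  stopifnot(inherits(fit, "psm_fit"))
  qfun <- .dist_fns[[fit$family]]$q
  args <- c(list(p = 0.5), as.list(unname(fit$params)))
  names(args)[2:(1 + length(fit$params))] <- names(formals(qfun))[2:(1 + length(fit$params))]
  do.call(qfun, args)
}

#' Write a model-comparison table
#'
#' One row per fitted family with parameters (as JSON), log-likelihood, AIC
#' and BIC, sorted by AIC.
#'
#' @param fits Named list of `psm_fit` objects.
#' @return A data frame with columns `family`, `params`, `loglik`, `aic`,
#'   `bic`, `k`, `n_obs`.
#' @export
model_comparison_table <- function(fits) {
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(family = f$family,
               params = as.character(jsonlite::toJSON(as.list(f$params),
                                                      auto_unbox = TRUE, digits = 8)),
               loglik = f$loglik, aic = f$aic, bic = f$bic,
               k = f$k, n_obs = f$n_obs, stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  df[order(df$aic), ]
}
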