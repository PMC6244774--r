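# Cox proportional hazards from the partial likelihood up.
#
# The log partial likelihood is accumulated over distinct event times; tied
# events are handled with either the Breslow or the Efron denominator. Both
# reduce to the same expression when no event times are tied. Maximisation
# is safeguarded Newton-Raphson with step-halving.

# Log partial likelihood, gradient and Hessian at beta.
# X: n x p matrix; time, event: length n. frac_fun gives, for a tie of
# multiplicity d, the Efron fractions (0..d-1)/d or Breslow zeros.
.cox_pl <- function(beta, X, time, event, ties) {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  eta <- eta - max(eta) # guard exp overflow; constant shifts cancel below
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  wo <- w[ord]; Xo <- X[ord, , drop = FALSE]; to <- time[ord]
  cw <- cumsum(wo)
  cwx <- apply(Xo * wo, 2, cumsum)
  if (p == 1L) cwx <- matrix(cwx, ncol = 1L)
  # upper-triangle cross-product cumulative sums for the Hessian
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cwxx <- sapply(seq_len(nrow(pairs)), function(k) {
    cumsum(wo * Xo[, pairs[k, 1]] * Xo[, pairs[k, 2]])
  })
  if (nrow(pairs) == 1L) cwxx <- matrix(cwxx, ncol = 1L)

  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  ev_times <- unique(time[event == 1])
  for (t in ev_times) {
    k <- sum(to >= t) # risk set is the first k rows in descending order
    D <- which(time == t & event == 1)
    d <- length(D)
    s <- colSums(X[D, , drop = FALSE])
    wD <- w[D]
    S0 <- cw[k]
    S1 <- cwx[k, ]
    S2 <- matrix(0, p, p)
    S2[cbind(pairs[, 1], pairs[, 2])] <- cwxx[k, ]
    S2 <- S2 + t(S2) - diag(diag(S2), p)
    fr <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    S0D <- sum(wD)
    S1D <- colSums(X[D, , drop = FALSE] * wD)
    S2D <- crossprod(X[D, , drop = FALSE] * sqrt(wD))
    ll <- ll + sum(eta[D])
    for (f in fr) {
      S0f <- S0 - f * S0D
      S1f <- S1 - f * S1D
      S2f <- S2 - f * S2D
      mu <- S1f / S0f
      ll <- ll - log(S0f)
      grad <- grad - mu
      hess <- hess - (S2f / S0f - tcrossprod(mu))
    }
    grad <- grad + s
  }
  list(loglik = ll, grad = grad, hess = hess)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with
#' step-halving. Tied event times are handled by the Breslow (default) or
#' Efron method; the two agree exactly when no event times are tied.
#' Inference is Wald: `se` from the inverse negative Hessian at the
#' maximum, 95% confidence limits `exp(coef +/- 1.96 se)`, two-sided normal
#' p-values. Rows with missing covariate values are dropped listwise and
#' counted in `n_dropped`.
#'
#' @param time Positive follow-up times (weeks).
#' @param event Progression indicator (1 observed, 0 censored).
#' @param covariates Numeric vector, matrix or data.frame of predictors
#'   (one column per covariate; columns are named in the output).
#' @param tie_method `"breslow"` or `"efron"`.
#' @param max_iter,grad_tol Newton-Raphson safeguards: iteration cap and
#'   gradient-norm convergence tolerance.
#' @return An object of class `cox_fit`: `coef`, `se`, `hr`, `ci95`
#'   (2-column matrix), `wald_z`, `p_value`, `loglik`, `loglik_null`, `n`,
#'   `n_events`, `n_dropped`, `tie_method`, `iterations`, `converged`.
#' @examples
#' coh <- glioma_cohort()
#' cox_fit(coh$time_weeks, coh$event, coh$oba_global_z)
#' @export
cox_fit <- function(time, event, covariates,
                    tie_method = c("breslow", "efron"),
                    max_iter = 50L, grad_tol = 1e-8) {
  tie_method <- match.arg(tie_method)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) {
    colnames(X) <- if (ncol(X) == 1L) "x" else paste0("x", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  time <- as.numeric(time); event <- as.integer(event)
  if (length(time) != nrow(X) || length(event) != nrow(X)) {
    stop("time, event and covariates must have the same length")
  }
  if (anyNA(time) || anyNA(event)) stop("missing times or event indicators")
  keep <- stats::complete.cases(X)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]; time <- time[keep]; event <- event[keep]
  n <- nrow(X); p <- ncol(X)
  if (any(time <= 0)) stop("times must be strictly positive")
  if (sum(event) < 1L) stop("need at least one observed event")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate: ", paste(colnames(X)[sds == 0], collapse = ", "))
  }

  beta <- numeric(p)
  pl <- .cox_pl(beta, X, time, event, tie_method)
  loglik_null <- pl$loglik
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (sqrt(sum(pl$grad^2)) < grad_tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(solve(-pl$hess, pl$grad), error = function(e) NULL)
    if (is.null(step)) {
      stop("singular information matrix (collinear covariates?)")
    }
    # step-halving on partial-likelihood decrease (tolerance absorbs
    # rounding noise in the accumulated log likelihood)
    ok <- FALSE
    for (h in 0:20) {
      cand <- beta + step / 2^h
      plc <- .cox_pl(cand, X, time, event, tie_method)
      if (is.finite(plc$loglik) &&
          plc$loglik >= pl$loglik - 1e-9 * (1 + abs(pl$loglik))) {
        ok <- TRUE
        break
      }
    }
    if (!ok) break
    beta <- cand
    pl <- plc
    if (sqrt(sum(pl$grad^2)) < grad_tol) {
      converged <- TRUE
      break
    }
  }
  # a monotone partial likelihood drives the coefficient to +/- infinity
  # while the gradient vanishes, so divergence is detected on the scale of
  # the covariate: a log-HR above 15 per covariate SD is separation
  if (!converged || any(abs(beta) * sds > 15)) {
    stop("Cox fit did not converge (monotone partial likelihood / ",
         "perfect separation?)")
  }
  info <- solve(-pl$hess)
  se <- sqrt(diag(info))
  z <- beta / se
  ci <- cbind(lower = exp(beta - 1.96 * se), upper = exp(beta + 1.96 * se))
  rownames(ci) <- colnames(X)
  structure(
    list(coef = stats::setNames(beta, colnames(X)),
         se = stats::setNames(se, colnames(X)),
         hr = stats::setNames(exp(beta), colnames(X)),
         ci95 = ci,
         wald_z = stats::setNames(z, colnames(X)),
         p_value = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
         loglik = pl$loglik, loglik_null = loglik_null,
         n = n, n_events = sum(event), n_dropped = n_dropped,
         tie_method = tie_method, iterations = iter, converged = converged),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (%s ties): n = %d, events = %d%s\n",
              x$tie_method, x$n, x$n_events,
              if (x$n_dropped) sprintf(" (%d dropped)", x$n_dropped) else ""))
  tab <- data.frame(coef = x$coef, HR = x$hr, lower95 = x$ci95[, "lower"],
                    upper95 = x$ci95[, "upper"], se = x$se, z = x$wald_z,
                    p = x$p_value)
  print(round(tab, 4))
  invisible(x)
}

#' Bivariate Cox confounder model
#'
#' Fits a two-covariate Cox model: the main predictor (global oscillatory
#' activity in the confounder analyses) plus one potential confounder.
#'
#' @inheritParams cox_fit
#' @param main Numeric vector, the predictor of interest.
#' @param confounder Numeric vector, the covariate to adjust for.
#' @param names Length-2 character vector naming the two columns.
#' @return A `cox_fit` with `p = 2`.
#' @export
cox_fit_bivariate <- function(time, event, main, confounder,
                              tie_method = c("breslow", "efron"),
                              names = c("main", "confounder")) {
  X <- cbind(main, confounder)
  colnames(X) <- names
  if (stats::sd(main, na.rm = TRUE) > 0 &&
      isTRUE(all.equal(stats::cor(main, confounder,
                                  use = "complete.obs")^2, 1))) {
    stop("confounder is collinear with the main covariate")
  }
  cox_fit(time, event, X, tie_method = match.arg(tie_method))
}

#' Kaplan-Meier product-limit estimate
#'
#' @inheritParams cox_fit
#' @return An object of class `km_curve`: `times` (unique observed times,
#'   increasing), `survival` (non-increasing, starts below 1 only after an
#'   event), `at_risk`, `n_event`, `n_censor` per time, and `median_time`
#'   (first time at which survival drops to 0.5 or below; `NA` if never
#'   reached).
#' @export
km_estimate <- function(time, event) {
  time <- as.numeric(time); event <- as.integer(event)
  if (length(time) < 1L) stop("need at least one observation")
  ut <- sort(unique(time))
  at_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  d <- vapply(ut, function(t) sum(time == t & event == 1), numeric(1))
  cens <- vapply(ut, function(t) sum(time == t & event == 0), numeric(1))
  surv <- cumprod(1 - d / at_risk)
  med <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1L]] else NA_real_
  structure(
    list(times = ut, survival = surv, at_risk = as.integer(at_risk),
         n_event = as.integer(d), n_censor = as.integer(cens),
         median_time = med),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d time points, median %s\n",
              length(x$times),
              if (is.na(x$median_time)) "not reached" else
                format(x$median_time)))
  invisible(x)
}

#' Export a Kaplan-Meier curve as a table
#'
#' @param curve A `km_curve`.
#' @return `data.frame` with columns `time`, `survival`, `at_risk`,
#'   `n_event`, `n_censor`.
#' @export
km_table <- function(curve) {
  data.frame(time = curve$times, survival = curve$survival,
             at_risk = curve$at_risk, n_event = curve$n_event,
             n_censor = curve$n_censor)
}

#' Median split of a biomarker
#'
#' Dichotomises at the sample median: values at or below the median are
#' labelled `"low"`, values above `"high"` (so with odd n the middle value
#' goes to the low group).
#'
#' @param values Numeric vector, length >= 2, not all equal.
#' @return Character vector of `"low"`/`"high"` labels.
#' @export
median_split <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  if (length(unique(values)) == 1L) {
    stop("all values equal; median split is degenerate")
  }
  m <- stats::median(values)
  ifelse(values <= m, "low", "high")
}

#' Median and spread of observed event times
#'
#' Summarises progression-free survival among patients whose progression
#' was observed: censored follow-up times are excluded.
#'
#' @inheritParams cox_fit
#' @return List with `median_weeks`, `sd_weeks` and `n_events`.
#' @export
median_event_time <- function(time, event) {
  t_ev <- as.numeric(time)[as.integer(event) == 1L]
  if (length(t_ev) == 0L) stop("no observed events")
  list(median_weeks = stats::median(t_ev),
       sd_weeks = stats::sd(t_ev),
       n_events = length(t_ev))
}
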