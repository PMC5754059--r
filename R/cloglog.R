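#' Complementary log-log response probability
#'
#' The discrete-time hazard link used throughout the transition models:
#' `p = 1 - exp(-exp(eta))`.  Strictly increasing in `eta`; `exp(eta)` is
#' the integrated hazard over one cycle, so scenario multipliers on the
#' probability scale approximate hazard-ratio interventions for small
#' probabilities.
#'
#' @param eta finite numeric vector of linear predictors.
#' @return probabilities in (0, 1) for finite input.
#' @export
#' @examples
#' cloglog_prob(0)              # 1 - exp(-1)
#' cloglog_prob(log(log(2)))    # exactly 0.5
cloglog_prob <- function(eta) {
  if (!is.numeric(eta) || any(!is.finite(eta)))
    stop("cloglog_prob: 'eta' must be finite numeric")
  -expm1(-exp(eta))
}

#' Fit a discrete-time complementary log-log hazard model
#'
#' Maximum-likelihood fit of a Bernoulli model with the cloglog link by
#' Fisher scoring with step-halving.  Convergence is declared when the
#' relative change in log-likelihood falls below `ll_tol` or the gradient
#' max-norm falls below `grad_tol`.  All-event or no-event outcomes, and
#' (quasi-)complete separation, raise an estimation error rather than
#' returning a silently degenerate fit.
#'
#' @param formula model formula; the response must be 0/1 or logical.
#' @param data data frame holding the response and covariates.
#' @param weights optional non-negative case weights.
#' @param max_iter maximum Fisher-scoring iterations.
#' @param ll_tol relative log-likelihood convergence tolerance.
#' @param grad_tol gradient max-norm convergence tolerance.
#' @return an object of class `cloglog_fit` with components `coefficients`,
#'   `se`, `vcov`, `logLik`, `logLik_zero` (log-likelihood at the zero
#'   coefficient vector), `converged`, `iterations`, `n_obs`.
#' @seealso [cloglog_prob()], [predict.cloglog_fit()]
#' @export
fit_cloglog <- function(formula, data, weights = NULL, max_iter = 100L,
                        ll_tol = 1e-8, grad_tol = 1e-6) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.numeric(y)
  if (is.factor(y)) y <- as.numeric(y) - 1
  if (!all(y %in% c(0, 1)))
    stop("fit_cloglog: response must be binary (0/1)")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  w <- if (is.null(weights)) rep(1, length(y)) else as.numeric(weights)
  if (length(w) != length(y)) stop("fit_cloglog: weights length mismatch")
  if (sum(w * y) == 0 || sum(w * (1 - y)) == 0)
    stop("fit_cloglog: estimation error - outcome is all-0 or all-1 among ",
         "at-risk records; the cloglog hazard is not identified")

  eps <- 1e-12
  loglik <- function(beta) {
    mu <- clamp(cloglog_prob(clamp(X %*% beta, -30, 30)), eps, 1 - eps)
    sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  p <- ncol(X)
  beta <- numeric(p)
  ll0 <- loglik(beta)  # log-likelihood at the zero vector
  ll <- ll0
  converged <- FALSE
  iter <- 0L
  info <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- clamp(as.numeric(X %*% beta), -30, 30)
    mu <- clamp(cloglog_prob(eta), eps, 1 - eps)
    dmu <- exp(eta - exp(eta))                  # d mu / d eta
    score <- as.numeric(t(X) %*% (w * dmu * (y - mu) / (mu * (1 - mu))))
    Wdiag <- w * dmu^2 / (mu * (1 - mu))        # expected information weights
    info <- crossprod(X * sqrt(Wdiag))
    step <- tryCatch(solve(info, score), error = function(e)
      stop("fit_cloglog: estimation error - singular information matrix ",
           "(collinear covariates or complete separation)"))
    # step-halving to guarantee ascent
    ll_new <- loglik(beta + step)
    h <- 0L
    while (ll_new < ll && h < 30L) {
      step <- step / 2
      ll_new <- loglik(beta + step)
      h <- h + 1L
    }
    beta <- beta + step
    rel <- abs(ll_new - ll) / (abs(ll) + 1e-10)
    ll <- ll_new
    if (rel < ll_tol || max(abs(score)) < grad_tol) {
      converged <- TRUE
      break
    }
  }
  if (max(abs(beta)) > 30)
    stop("fit_cloglog: estimation error - coefficients diverging ",
         "(complete or quasi-complete separation suspected)")
  if (!converged)
    warning("fit_cloglog: not converged after ", max_iter,
            " iterations; estimates flagged")
  vc <- solve(info)
  colnames(vc) <- rownames(vc) <- colnames(X)
  est <- as.numeric(beta)
  names(est) <- colnames(X)
  out <- list(coefficients = est,
              se = sqrt(diag(vc)),
              vcov = vc,
              logLik = ll,
              logLik_zero = ll0,
              converged = converged,
              iterations = iter,
              n_obs = length(y),
              formula = formula,
              terms = attr(mf, "terms"),
              call = match.call())
  class(out) <- "cloglog_fit"
  out
}

#' @export
print.cloglog_fit <- function(x, ...) {
  cat("Discrete-time cloglog hazard model\n")
  cat("  n =", x$n_obs, " logLik =", format(x$logLik, digits = 6),
      if (!x$converged) " [NOT CONVERGED]" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.cloglog_fit <- function(object, ...) object$coefficients

#' @export
vcov.cloglog_fit <- function(object, ...) object$vcov

#' @export
logLik.cloglog_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients),
            nobs = object$n_obs, class = "logLik")
}

#' @export
nobs.cloglog_fit <- function(object, ...) object$n_obs

#' Summarize a cloglog fit
#' @param object a `cloglog_fit`.
#' @param ... unused.
#' @return a `summary.cloglog_fit` with a coefficient table (estimate, SE,
#'   z, p).
#' @export
summary.cloglog_fit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, logLik = object$logLik,
              converged = object$converged, n_obs = object$n_obs)
  class(out) <- "summary.cloglog_fit"
  out
}

#' @export
print.summary.cloglog_fit <- function(x, ...) {
  cat("Discrete-time cloglog hazard model (n =", x$n_obs, ")\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("logLik:", format(x$logLik, digits = 6),
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  invisible(x)
}

#' Predict from a cloglog fit
#' @param object a `cloglog_fit`.
#' @param newdata data frame of covariates; defaults to refusing (no stored
#'   model frame).
#' @param type `"response"` (probability) or `"link"` (linear predictor).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.cloglog_fit <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  eta <- as.numeric(X %*% object$coefficients)
  if (type == "link") eta else cloglog_prob(clamp(eta, -30, 30))
}
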