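#' Maximum-likelihood logistic regression via IRLS
#'
#' Self-contained Fisher-scoring / iteratively reweighted least squares
#' fitter for the binary logistic model.  Convergence is declared when the
#' relative change in log-likelihood falls below `tol`; each update is
#' step-halved until the log-likelihood does not decrease, so the
#' log-likelihood path is monotone non-decreasing.  The covariance matrix is
#' the inverse of the observed (= expected, for the canonical link)
#' information at the optimum.  Complete or quasi-complete separation is
#' detected as a diverging coefficient and reported as an error of class
#' `ssb_separation_error`, distinct from plain non-convergence.
#'
#' @param y Binary response vector (0/1).
#' @param X Design matrix including the intercept column.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param sep_threshold Absolute coefficient magnitude treated as divergence.
#' @param sep_terms Coefficient names whose divergence raises the separation
#'   error (`NULL`, the default, monitors every coefficient).  Divergence in
#'   an unmonitored coefficient — the familiar quasi-separation of a sparse
#'   nuisance indicator cell — instead yields a warning once the likelihood
#'   has plateaued, matching how standard GLM software behaves.
#' @return An object of class `logistic_fit`: `coefficients`, `covariance`,
#'   `n_obs`, `converged`, `iterations`, `log_likelihood`.
#' @examples
#' x <- rep(0:1, each = 50)
#' y <- rep(c(0, 1), 50)
#' fit <- fit_logistic(y, cbind(1, x))
#' coef(fit)
#' @export
fit_logistic <- function(y, X, max_iter = 50, tol = 1e-10,
                         sep_threshold = 15, sep_terms = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("more parameters than observations", call. = FALSE)
  if (qr(X)$rank < p) {
    stop("design matrix is rank deficient (duplicated column?)", call. = FALSE)
  }

  loglik <- function(beta) {
    eta <- drop(X %*% beta)
    # numerically stable log(1 + e^eta) = max(eta, 0) + log1p(e^-|eta|)
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }

  nms <- colnames(X) %||% paste0("b", seq_len(p) - 1)
  monitored <- if (is.null(sep_terms)) {
    seq_len(p)
  } else {
    idx <- match(sep_terms, nms)
    idx[!is.na(idx)]
  }

  beta <- numeric(p)
  ll <- loglik(beta)
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    w <- mu * (1 - mu)
    info <- crossprod(X, X * w)
    score <- crossprod(X, y - mu)
    delta <- tryCatch(solve(info, score),
                      error = function(e) {
                        stop("information matrix singular", call. = FALSE)
                      })
    step <- 1
    repeat {
      cand <- beta + step * delta
      ll_new <- loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 2^-25) {
        ll_new <- ll
        cand <- beta
        break
      }
    }
    beta <- drop(cand)
    if (length(monitored) && max(abs(beta[monitored])) > sep_threshold) {
      stop(structure(
        class = c("ssb_separation_error", "error", "condition"),
        list(message = "complete separation detected (diverging coefficient)",
             call = NULL)))
    }
    if (abs(ll_new - ll) < tol * (abs(ll) + 0.1)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter, " iterations", call. = FALSE)
  }
  runaway <- setdiff(which(abs(beta) > sep_threshold), monitored)
  if (length(runaway)) {
    warning("quasi-separation in covariate(s) ",
            paste(nms[runaway], collapse = ", "),
            "; their coefficients are unreliable (sparse cell)",
            call. = FALSE)
  }
  mu <- expit(drop(X %*% beta))
  info <- crossprod(X, X * (mu * (1 - mu)))
  cov <- solve(info)
  cov <- (cov + t(cov)) / 2
  names(beta) <- nms
  dimnames(cov) <- list(nms, nms)
  structure(
    list(coefficients = beta, covariance = cov, n_obs = n,
         converged = converged, iterations = iter, log_likelihood = ll),
    class = "logistic_fit"
  )
}

#' Fit a logistic model from a formula, dropping incomplete cases
#'
#' Thin wrapper building the design matrix with [stats::model.matrix()] and
#' delegating to [fit_logistic()].  Records missing any model variable are
#' dropped for this model only (complete-case per model).
#'
#' @param formula Model formula with a binary response.
#' @param data Data frame.
#' @param ... Passed to [fit_logistic()].
#' @return A `logistic_fit`.
#' @export
fit_logistic_formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  fit <- fit_logistic(y, X, ...)
  fit$formula <- formula
  fit
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$covariance

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: %d obs, %d parameters, logLik %.3f (%d IRLS iterations)\n",
              x$n_obs, length(x$coefficients), x$log_likelihood, x$iterations))
  se <- sqrt(diag(x$covariance))
  print(data.frame(estimate = x$coefficients, se = se,
                   z = x$coefficients / se,
                   row.names = names(x$coefficients)))
  invisible(x)
}

# Wald 95% CI on the odds-ratio scale for selected coefficients.
wald_or_ci <- function(fit, terms, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  est <- fit$coefficients[terms]
  se <- sqrt(diag(fit$covariance))[terms]
  data.frame(term = terms, or = exp(est), lo = exp(est - z * se),
             hi = exp(est + z * se), p = 2 * pnorm(-abs(est / se)),
             row.names = NULL)
}

# Wald chi-square test that a set of coefficients is jointly zero.
wald_test <- function(fit, terms) {
  idx <- match(terms, names(fit$coefficients))
  if (anyNA(idx)) stop("unknown coefficient(s): ",
                       paste(terms[is.na(idx)], collapse = ", "), call. = FALSE)
  b <- fit$coefficients[idx]
  V <- fit$covariance[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V, b))
  df <- length(idx)
  list(statistic = stat, df = df, p_value = pchisq(stat, df, lower.tail = FALSE))
}
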