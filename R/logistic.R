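# Logistic regression by iteratively reweighted least squares, with the
# predicted probabilities feeding the ROC machinery.

as_feature_matrix <- function(features) {
  x <- as.matrix(features)
  if (!is.numeric(x)) abort_data("features must be numeric")
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("x", seq_len(ncol(x)))
  }
  x
}

#' Fit a logistic regression by IRLS
#'
#' Maximum-likelihood logistic regression of a binary outcome on one or
#' more features, by Newton / iteratively reweighted least squares.
#' Iteration stops when the log-likelihood changes by less than `tol`
#' (default 1e-8) or after `max_iter` (default 100) iterations. Under
#' complete separation the likelihood has no finite maximizer; the fit is
#' flagged `converged = FALSE`, a warning is raised and the last iterate is
#' returned. A small quadratic (ridge) penalty can be supplied to
#' stabilise such fits.
#'
#' @param features Numeric matrix or data frame, one column per feature.
#' @param outcome 0/1 outcome vector.
#' @param penalty Ridge penalty weight on the squared coefficient norm
#'   (intercept included); default 0 (plain maximum likelihood).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum number of IRLS iterations.
#' @return An object of class `leak_logit`: `coefficients` (intercept
#'   first), `log_lik`, `converged`, `iterations`, `separation`, `vcov`
#'   (inverse observed information), `feature_names`.
#' @export
fit_logistic <- function(features, outcome, penalty = 0,
                         tol = 1e-8, max_iter = 100) {
  x <- as_feature_matrix(features)
  y <- as.numeric(outcome)
  check_two_classes(y)
  if (nrow(x) != length(y)) abort_data("features and outcome lengths differ")

  design <- cbind(`(Intercept)` = 1, x)
  p <- ncol(design)
  beta <- rep(0, p)
  loglik <- function(eta) {
    # numerically safe Bernoulli log-likelihood
    sum(y * eta - log1p(exp(eta))) - penalty * sum(beta^2)
  }
  eta <- drop(design %*% beta)
  ll_old <- loglik(eta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(design, y - mu)) - 2 * penalty * beta
    hess <- crossprod(design, design * w) + diag(2 * penalty, p)
    beta <- beta + solve(hess, grad)
    eta <- drop(design %*% beta)
    ll <- loglik(eta)
    if (abs(ll - ll_old) < tol) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  mu <- stats::plogis(eta)
  separation <- all(abs(y - mu) < 1e-6)
  if (separation && penalty == 0) {
    converged <- FALSE
    warning("complete separation: coefficients diverge, last iterate returned")
  } else if (!converged) {
    warning("IRLS did not converge in ", max_iter, " iterations")
  }
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- crossprod(design, design * w) + diag(2 * penalty, p)
  structure(
    list(
      coefficients = stats::setNames(drop(beta), colnames(design)),
      log_lik = ll_old,
      converged = converged,
      iterations = iter,
      separation = separation,
      vcov = solve(info),
      feature_names = colnames(x)
    ),
    class = "leak_logit"
  )
}

#' @export
print.leak_logit <- function(x, ...) {
  cat("Logistic model (IRLS,", x$iterations, "iterations,",
      if (x$converged) "converged" else "NOT converged", ")\n")
  print(round(x$coefficients, 4))
  cat("log-likelihood:", format(x$log_lik), "\n")
  invisible(x)
}

#' Predicted event probabilities from a logistic model
#'
#' Applies the inverse logistic link to the linear predictor; these
#' predicted values are the scores evaluated by ROC analysis.
#'
#' @param model A `leak_logit` fit.
#' @param features Feature matrix/data frame with the same columns the
#'   model was fitted on.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predicted_scores <- function(model, features) {
  stopifnot(inherits(model, "leak_logit"))
  x <- as_feature_matrix(features)
  if (ncol(x) != length(model$feature_names)) {
    abort_data("feature dimension does not match the fitted model")
  }
  eta <- drop(cbind(1, x) %*% model$coefficients)
  stats::plogis(eta)
}
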