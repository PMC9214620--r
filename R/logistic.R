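#' Logistic regression by iteratively reweighted least squares
#'
#' Self-contained maximum-likelihood logistic fitter used by the screen
#' (the screening statistic is computed by the package itself; established
#' GLM routines serve only as independent cross-checks in the tests).
#'
#' Convergence is declared when the largest absolute coefficient change
#' falls below `tol` (default 1e-8) within `max_iter` iterations (default
#' 100). Standard errors come from the inverse observed information
#' `(X' W X)^{-1}` at the final estimate. Separation and other
#' non-convergence (coefficients growing without the step shrinking, or
#' the iteration cap) set `converged = 0`; callers must then suppress
#' OR/CI reporting. Rank-deficient designs are handled by pivoted-QR
#' aliasing: redundant columns get `NA` coefficients and an `estimable`
#' flag of `FALSE`, and the remaining coefficients equal the fit without
#' those columns.
#'
#' @param y Binary 0/1 outcome vector.
#' @param x Design matrix including an intercept column.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Iteration cap.
#' @param divergence_bound Absolute log-odds beyond which the fit is
#'   declared separated (default 30).
#' @return List with `coefficients`, `se` (both `NA` for aliased columns),
#'   `converged` (0/1), `estimable` (logical per column), `iterations`,
#'   `loglik`.
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(1, rbinom(200, 1, 0.3))
#' y <- rbinom(200, 1, plogis(-1 + 1.2 * x[, 2]))
#' fit_logistic(y, x)$coefficients
fit_logistic <- function(y, x, tol = 1e-8, max_iter = 100L,
                         divergence_bound = 30) {
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("input error: outcome must be binary 0/1 with no missing values")
  }
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(nrow(x) == length(y))
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(p))

  qx <- qr(x)
  estimable <- rep(FALSE, p)
  estimable[qx$pivot[seq_len(qx$rank)]] <- TRUE
  xe <- x[, estimable, drop = FALSE]
  pe <- ncol(xe)

  beta <- numeric(pe)
  converged <- FALSE
  diverged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(xe %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    a <- crossprod(xe, xe * w)
    b <- crossprod(xe, w * eta + (y - mu))
    beta_new <- tryCatch(drop(solve(a, b)), error = function(e) NULL)
    if (is.null(beta_new) || anyNA(beta_new)) { diverged <- TRUE; break }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (max(abs(beta)) > divergence_bound) { diverged <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
  }

  eta <- drop(xe %*% beta)
  mu <- stats::plogis(eta)
  se_e <- rep(NA_real_, pe)
  if (converged) {
    w <- pmax(mu * (1 - mu), 1e-10)
    info <- crossprod(xe, xe * w)
    vcov_e <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(vcov_e)) converged <- FALSE else se_e <- sqrt(diag(vcov_e))
  }

  coef <- se <- rep(NA_real_, p)
  names(coef) <- names(se) <- colnames(x)
  coef[estimable] <- beta
  se[estimable] <- se_e
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  list(coefficients = coef, se = se,
       converged = as.integer(converged && !diverged),
       estimable = estimable, iterations = it, loglik = ll)
}
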