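# Beta regression (logit mean link, log-link intercept-only precision) fitted
# by direct maximum likelihood, plus the fixed-effect logistic model of pool
# detection probability versus within-individual frequency.

#' Design matrix and response for the FO-error beta regression
#'
#' One row per (taxon, pellet sample size): response is the mean relative FO
#' error, covariates are the number of pellets analysed `n`, the full-sample
#' FO (`fo_tot`), the within-individual FO (`fo_pel`), and all first- and
#' second-order interactions. Responses on the closed interval are compressed
#' into (0,1) by the Smithson-Verkuilen transform
#' `y' = (y (N - 1) + 0.5) / N` with `N` the number of rows.
#'
#' @param errors an `error_curve` data frame (relative errors).
#' @param fo FO table providing `fo_tot` and `fo_pel` per taxon.
#' @param clip `"error"` (default): any response outside `[0, 1]` is an
#'   error; `"zero"`: small negative responses (Monte-Carlo overshoot of a
#'   near-zero error) are floored at 0 before compression.
#' @return list with `X` (model matrix), `y` (compressed response),
#'   `y_raw`, and the merged `data`.
#' @export
beta_design <- function(errors, fo, clip = c("error", "zero")) {
  clip <- match.arg(clip)
  if (!is.null(attr(errors, "error_kind")) &&
      attr(errors, "error_kind") != "relative")
    stop("beta_design expects relative errors")
  d <- merge(as.data.frame(errors), fo[, c("taxon", "fo_tot", "fo_pel")],
             by = "taxon", sort = FALSE)
  y <- d$mean_error
  if (clip == "zero") y <- pmax(y, 0)
  if (any(y < 0 | y > 1)) stop("responses outside [0, 1]")
  N <- length(y)
  y <- (y * (N - 1) + 0.5) / N
  X <- stats::model.matrix(~ n * fo_tot * fo_pel, data = d)
  list(X = X, y = y, y_raw = d$mean_error, data = d)
}

.betareg_loglik <- function(theta, X, y) {
  beta <- theta[-length(theta)]
  phi <- exp(theta[length(theta)])
  mu <- stats::plogis(drop(X %*% beta))
  a <- mu * phi
  b <- (1 - mu) * phi
  sum(lgamma(phi) - lgamma(a) - lgamma(b) +
        (a - 1) * log(y) + (b - 1) * log1p(-y))
}

.betareg_grad <- function(theta, X, y) {
  beta <- theta[-length(theta)]
  phi <- exp(theta[length(theta)])
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ystar <- log(y) - log1p(-y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  gbeta <- drop(crossprod(X, phi * (ystar - mustar) * mu * (1 - mu)))
  gphi <- phi * sum(digamma(phi) - mu * digamma(mu * phi) -
                      (1 - mu) * digamma((1 - mu) * phi) +
                      mu * log(y) + (1 - mu) * log1p(-y))
  c(gbeta, gphi)
}

#' Fit a beta regression by maximum likelihood
#'
#' Mean submodel `mu = plogis(X beta)` with a Beta(mu*phi, (1-mu)*phi)
#' likelihood and an intercept-only precision `phi` on the log scale.
#' Optimised by quasi-Newton (BFGS) with analytic gradient, initialised from
#' an OLS fit on `logit(y)` and a method-of-moments precision; convergence
#' when the relative log-likelihood change is below 1e-10 (up to 200
#' iterations). Standard errors come from the inverse observed information.
#'
#' @param X model matrix of full column rank (include the intercept).
#' @param y response strictly inside (0, 1).
#' @return list of class `betareg_fit`: `coefficients`, `se`, `phi`,
#'   `loglik`, `linear_predictor`, `fitted`, `pseudo_r2`, `converged`,
#'   `iterations`.
#' @export
fit_betareg <- function(X, y) {
  X <- as.matrix(X)
  if (any(y <= 0 | y >= 1)) stop("y must lie strictly inside (0, 1)")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  ylog <- stats::qlogis(y)
  beta0 <- stats::lm.fit(X, ylog)$coefficients
  mu0 <- stats::plogis(drop(X %*% beta0))
  v <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v, 1e-8) - 1, 1)
  theta0 <- c(beta0, log(phi0))

  opt <- stats::optim(theta0, fn = .betareg_loglik, gr = .betareg_grad,
                      X = X, y = y, method = "BFGS",
                      control = list(fnscale = -1, maxit = 200,
                                     reltol = 1e-10))
  theta <- opt$par
  H <- try(stats::optimHess(theta, .betareg_loglik, .betareg_grad, X = X, y = y),
           silent = TRUE)
  se <- rep(NA_real_, length(theta))
  if (!inherits(H, "try-error")) {
    V <- try(solve(-H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) se <- sqrt(diag(V))
  }
  beta <- theta[-length(theta)]
  names(beta) <- colnames(X)
  eta <- drop(X %*% beta)
  fit <- structure(list(
    coefficients = beta,
    se = stats::setNames(se[-length(se)], colnames(X)),
    phi = exp(theta[length(theta)]),
    phi_se_log = se[length(se)],
    loglik = opt$value,
    linear_predictor = eta,
    fitted = stats::plogis(eta),
    converged = opt$convergence == 0,
    iterations = opt$counts[["function"]]
  ), class = "betareg_fit")
  fit$pseudo_r2 <- pseudo_r2(fit, y)
  fit
}

#' Pseudo-R² of a beta regression
#'
#' Squared Pearson correlation between `logit(y)` and the fitted linear
#' predictor — the standard beta-regression pseudo-R². `NA` when either
#' vector has zero variance.
#'
#' @param fit a `betareg_fit`.
#' @param y the response used in fitting.
#' @return value in `[0, 1]`, or `NA`.
#' @export
pseudo_r2 <- function(fit, y) {
  lp <- fit$linear_predictor
  ly <- stats::qlogis(y)
  if (stats::sd(lp) == 0 || stats::sd(ly) == 0) return(NA_real_)
  stats::cor(ly, lp)^2
}

#' Logistic model of pool detection versus within-individual FO
#'
#' Fixed-effect logistic regression (IRLS via `stats::glm`) of the
#' per-(individual, taxon) pool detection flag on the taxon's
#' within-individual pellet frequency. Only pairs where the taxon was
#' detected in that individual's separate pellets should be supplied.
#'
#' @param detected binary vector (pool detected the taxon for this
#'   individual).
#' @param fopel numeric vector, same length: fraction of the individual's
#'   pellets containing the taxon.
#' @return list of class `logistic_fit`: `coefficients`, `se`, `z`,
#'   `converged`.
#' @export
fit_pool_detection <- function(detected, fopel) {
  detected <- as.numeric(detected)
  stopifnot(length(detected) == length(fopel),
            all(detected %in% c(0, 1)))
  if (all(detected == 1) || all(detected == 0))
    stop("complete separation: response is constant")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(detected ~ fopel, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep_warn || any(abs(stats::coef(fit)) > 25))
    stop("complete or quasi-complete separation in pool-detection fit")
  sm <- summary(fit)$coefficients
  structure(list(coefficients = sm[, "Estimate"], se = sm[, "Std. Error"],
                 z = sm[, "z value"], converged = fit$converged),
            class = "logistic_fit")
}
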