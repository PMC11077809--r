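#' Build the cost-model design matrix
#'
#' Treatment coding with fixed references: age band 0 and AMG 1. Column order
#' is deterministic: intercept, the sex indicator, age-band indicators in
#' increasing band order, then AMG indicators in catalogue order. By default
#' the indicator sets cover the levels present in the data (reduced designs
#' are first-class); an explicit `encoding` freezes the level sets, and a
#' record carrying a level outside it is an error naming the level.
#'
#' @param records Person data frame.
#' @param encoding Optional list with integer vectors `age_bands` and
#'   `amg_codes` (non-reference levels to encode).
#' @return List with the model matrix `X`, the response `y` (`NULL` when
#'   `cost_eur` is absent or all missing) and the `encoding` used.
#' @export
build_design <- function(records, encoding = NULL) {
  if (is.null(encoding)) {
    encoding <- list(
      age_bands = sort(setdiff(unique(records$age_band), 0L)),
      amg_codes = sort(setdiff(unique(records$amg_code), 1L))
    )
  } else {
    bad_b <- setdiff(unique(records$age_band), c(0L, encoding$age_bands))
    if (length(bad_b))
      stop("unseen level(s) at predict time: ",
           paste0("age_band_", bad_b, collapse = ", "))
    bad_g <- setdiff(unique(records$amg_code), c(1L, encoding$amg_codes))
    if (length(bad_g))
      stop("unseen level(s) at predict time: ",
           paste0("amg_", bad_g, collapse = ", "))
  }
  n <- nrow(records)
  nb <- length(encoding$age_bands)
  ng <- length(encoding$amg_codes)
  X <- matrix(0, nrow = n, ncol = 2 + nb + ng)
  lbl <- function(prefix, x) if (length(x)) paste0(prefix, x) else character(0)
  colnames(X) <- c("(Intercept)", "sex",
                   lbl("age_band_", encoding$age_bands),
                   lbl("amg_", encoding$amg_codes))
  X[, 1] <- 1
  X[, 2] <- records$sex
  if (nb) X[cbind(seq_len(n), 2L + match(records$age_band, encoding$age_bands))[
    !is.na(match(records$age_band, encoding$age_bands)), , drop = FALSE]] <- 1
  if (ng) X[cbind(seq_len(n), 2L + nb + match(records$amg_code, encoding$amg_codes))[
    !is.na(match(records$amg_code, encoding$amg_codes)), , drop = FALSE]] <- 1
  y <- if ("cost_eur" %in% names(records) && !all(is.na(records$cost_eur)))
    records$cost_eur else NULL
  list(X = X, y = y, encoding = encoding)
}

# Family/link menu -> stats family object. power_half means eta = mu^0.5.
menu_family <- function(family, link) {
  family <- match.arg(family, c("gaussian", "poisson", "gamma",
                                "inverse_gaussian"))
  link <- match.arg(link, c("identity", "log", "power_half"))
  lk <- if (link == "power_half") stats::power(0.5) else stats::make.link(link)
  switch(family,
    gaussian = stats::gaussian(link = lk),
    # quasipoisson: identical IRLS solution, no integer-response warnings on
    # continuous costs; the Poisson quasi log-likelihood is computed below.
    poisson = stats::quasipoisson(link = lk),
    gamma = stats::Gamma(link = lk),
    inverse_gaussian = stats::inverse.gaussian(link = lk)
  )
}

# Maximum-likelihood dispersion and log-likelihood per family, with mu fixed
# at the fitted values. k counts the regression coefficients plus one
# dispersion parameter where the likelihood has one (all but poisson).
ml_loglik <- function(family, y, mu, p) {
  n <- length(y)
  switch(family,
    gaussian = {
      s2 <- sum((y - mu)^2) / n
      list(loglik = -n / 2 * (log(2 * pi * s2) + 1), dispersion = s2,
           k = p + 1L)
    },
    poisson = {
      ll <- sum(y * log(mu) - mu - lgamma(y + 1))
      list(loglik = ll, dispersion = 1, k = p)
    },
    gamma = {
      slm <- sum(log(mu)); sly <- sum(log(y)); sym <- sum(y / mu)
      nll <- function(lnu) {
        nu <- exp(lnu)
        -(n * nu * lnu - nu * slm + (nu - 1) * sly - nu * sym -
            n * lgamma(nu))
      }
      opt <- optimize(nll, c(-15, 15))
      nu <- exp(opt$minimum)
      list(loglik = -opt$objective, dispersion = 1 / nu, k = p + 1L)
    },
    inverse_gaussian = {
      phi <- mean((y - mu)^2 / (mu^2 * y))
      ll <- -n / 2 * log(2 * pi * phi) - 1.5 * sum(log(y)) - n / 2
      list(loglik = ll, dispersion = phi, k = p + 1L)
    }
  )
}

#' Fit a cost GLM on a prepared design
#'
#' Iteratively reweighted least squares (convergence: relative deviance change
#' below `1e-8`, at most 100 iterations) for the family/link menu used in
#' healthcare cost modelling. The gaussian/identity fit coincides with
#' ordinary least squares. The log-likelihood is evaluated at the
#' maximum-likelihood dispersion (gamma: 1-D profile over the shape; inverse
#' gaussian: closed form), so AIC/BIC are comparable across families; the
#' Pearson dispersion is kept for standard errors.
#'
#' @param design A list from [build_design()] (or any list with `X`, `y`,
#'   `encoding`).
#' @param response Optional response overriding `design$y`.
#' @param family One of `"gaussian"`, `"poisson"`, `"gamma"`,
#'   `"inverse_gaussian"`.
#' @param link One of `"identity"`, `"log"`, `"power_half"`.
#' @return An object of class `cost_glm`.
#' @export
fit_glm <- function(design, response = NULL,
                    family = "gamma", link = "log") {
  X <- design$X
  y <- if (is.null(response)) design$y else response
  if (is.null(y)) stop("no response available")
  if (!all(is.finite(X))) stop("design must be finite")
  if (family %in% c("gamma", "inverse_gaussian") && any(y <= 0))
    stop("response must be strictly positive for the ", family, " family")
  fam <- menu_family(family, link)
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  # the stock family AIC is replaced by the ML version below; stub it out so
  # degenerate dispersions on exact fits cannot warn
  fam_fit <- fam
  fam_fit$aic <- function(...) NA_real_
  fit <- stats::glm.fit(x = X, y = y, family = fam_fit, control = ctl)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient design; aliased column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (!fit$converged)
    warning("IRLS did not converge in 100 iterations (", family, "/", link,
            "); downstream use is refused")
  mu <- fit$fitted.values
  eta <- fam$linkfun(mu)
  p <- ncol(X)
  n <- length(y)
  ml <- ml_loglik(family, y, mu, p)
  w <- fit$weights                      # IRLS weights 1/(V(mu) g'(mu)^2)
  XtWX <- crossprod(X * sqrt(w))
  cov_unscaled <- chol2inv(chol(XtWX))
  dimnames(cov_unscaled) <- list(colnames(X), colnames(X))
  pearson <- sum((y - mu)^2 / fam$variance(mu)) / (n - p)
  # robust (HC0) sandwich: scores x_i * (y-mu) / (V(mu) g'(mu))
  sc <- (y - mu) * fam$mu.eta(eta) / fam$variance(mu)
  meat <- crossprod(X * sc)
  vcov_robust <- cov_unscaled %*% meat %*% cov_unscaled
  structure(list(
    spec = list(family = family, link = link),
    coefficients = fit$coefficients,
    dispersion = ml$dispersion,
    dispersion_pearson = pearson,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    loglik = ml$loglik,
    aic = -2 * ml$loglik + 2 * ml$k,
    bic = -2 * ml$loglik + ml$k * log(n),
    n = n, k = ml$k,
    converged = fit$converged,
    iterations = fit$iter,
    encoding = design$encoding,
    vcov = pearson * cov_unscaled,
    vcov_robust = vcov_robust,
    fitted_mu = mu,
    fitted_eta = as.numeric(eta),
    response = y
  ), class = "cost_glm")
}

#' Fit a cost GLM directly from person records
#'
#' Convenience wrapper: [build_design()] then [fit_glm()].
#'
#' @inheritParams fit_glm
#' @param records Person data frame with `cost_eur`.
#' @param encoding Optional fixed encoding, see [build_design()].
#' @return A `cost_glm` object.
#' @export
fit_cost_glm <- function(records, family = "gamma", link = "log",
                         encoding = NULL) {
  fit_glm(build_design(records, encoding), family = family, link = link)
}

#' @export
print.cost_glm <- function(x, ...) {
  cat(sprintf("cost GLM: %s family, %s link (%s)\n", x$spec$family,
              x$spec$link,
              if (x$converged) sprintf("converged in %d IRLS iterations",
                                       x$iterations) else "NOT converged"))
  cat(sprintf("  n = %d, k = %d, deviance = %.4g (null %.4g)\n",
              x$n, x$k, x$deviance, x$null_deviance))
  cat(sprintf("  logLik = %.2f, AIC = %.2f, BIC = %.2f, dispersion = %.4g\n",
              x$loglik, x$aic, x$bic, x$dispersion))
  invisible(x)
}

#' Predict costs for person records or a design matrix
#'
#' @param object A converged `cost_glm`.
#' @param newdata Person data frame, or a list with an `X` matrix.
#' @param ... Unused.
#' @return Data frame with the linear predictor `eta` and mean cost `mu`.
#'   Identity-link fits may propose non-positive means; these are returned
#'   but flagged with a message.
#' @export
predict.cost_glm <- function(object, newdata, ...) {
  if (!object$converged) stop("refusing to predict from an unconverged model")
  X <- if (is.data.frame(newdata))
    build_design(newdata, object$encoding)$X else newdata$X
  if (ncol(X) != length(object$coefficients)) stop("design not conformable")
  eta <- as.numeric(X %*% object$coefficients)
  fam <- menu_family(object$spec$family, object$spec$link)
  mu <- as.numeric(fam$linkinv(eta))
  if (object$spec$link == "identity" && any(mu <= 0))
    message(sum(mu <= 0), " identity-link prediction(s) are non-positive")
  data.frame(eta = eta, mu = mu)
}

#' Information criteria of a fitted cost GLM
#'
#' `AIC = -2 logLik + 2k`, `BIC = -2 logLik + k log(n)`, with the
#' log-likelihood at the maximum-likelihood dispersion, plus per-observation
#' versions (divide by `n`). Lower is better.
#'
#' @param model A converged `cost_glm`.
#' @return List with `aic`, `bic`, `aic_per_obs`, `bic_per_obs`.
#' @export
information_criteria <- function(model) {
  if (!model$converged) stop("model did not converge")
  list(aic = model$aic, bic = model$bic,
       aic_per_obs = model$aic / model$n, bic_per_obs = model$bic / model$n)
}

#' Deviance pseudo-variance explained
#'
#' `1 - deviance / null deviance`, the GLM analogue of R-squared.
#'
#' @param model A `cost_glm`.
#' @return A value in \[0, 1\]; 0 for a null model.
#' @export
pseudo_r2_deviance <- function(model) {
  if (model$null_deviance <= 0) stop("null deviance must be positive")
  max(0, 1 - model$deviance / model$null_deviance)
}
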