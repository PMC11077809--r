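#' Pregibon link test
#'
#' Refits the model with the squared linear predictor added as an extra
#' covariate; a significant coefficient signals link misspecification. The
#' two-sided p-value of that coefficient is returned (`p > 0.05` is read as
#' "passes"). If the squared predictor is collinear with the design the test
#' degenerates and passes through with a logged note.
#'
#' @param model A converged `cost_glm`.
#' @param records The person data the model was fit on.
#' @return List with `coefficient`, `se`, `p_value`, `degenerate`.
#' @export
pregibon_test <- function(model, records) {
  if (!model$converged) stop("model did not converge")
  design <- build_design(records, model$encoding)
  X2 <- cbind(design$X, eta_sq = model$fitted_eta^2)
  refit <- tryCatch(
    fit_glm(list(X = X2, y = design$y, encoding = model$encoding),
            family = model$spec$family, link = model$spec$link),
    error = function(e) e)
  if (inherits(refit, "error") || !refit$converged) {
    message("Pregibon refit degenerate (",
            if (inherits(refit, "error")) conditionMessage(refit)
            else "no convergence", "); passing through")
    return(list(coefficient = NA_real_, se = NA_real_, p_value = NA_real_,
                degenerate = TRUE))
  }
  b <- unname(refit$coefficients["eta_sq"])
  se <- sqrt(refit$vcov["eta_sq", "eta_sq"])
  p <- if (se == 0) as.numeric(b == 0) else 2 * pnorm(-abs(b / se))
  list(coefficient = b, se = se, p_value = p, degenerate = FALSE)
}

# Response-scale hat operator correction: raw residuals e = (I - M) eps with
# M = diag(dmu/deta) X (X'WX)^{-1} X' diag(1/(V(mu) g'(mu))). Returns the
# estimation-corrected robust covariance of the group mean residuals.
grouped_residual_cov <- function(model, X, groups, resid) {
  fam <- menu_family(model$spec$family, model$spec$link)
  mu <- model$fitted_mu
  eta <- model$fitted_eta
  dmu <- fam$mu.eta(eta)
  u <- dmu / fam$variance(mu)          # 1/(V g') since g' = 1/(dmu/deta)
  G <- nlevels(groups)
  ng <- tabulate(groups, nbins = G)
  At <- matrix(0, nrow(X), G)
  At[cbind(seq_len(nrow(X)), as.integer(groups))] <- 1 / ng[as.integer(groups)]
  XtWX <- crossprod(X * sqrt(dmu^2 / fam$variance(mu)))
  # (I - M)' A' = A' - diag(u) X (X'WX)^{-1} X' diag(dmu) A'
  right <- crossprod(X, dmu * At)
  Bm <- At - (u * X) %*% solve(XtWX, right)
  crossprod(Bm * abs(resid))
}

#' Modified Hosmer-Lemeshow test
#'
#' Sorts records by the linear predictor (ties broken by stable record
#' order), splits them into `n_groups` equal-size groups, and regresses the
#' raw-scale residuals on the group indicators without intercept -- the
#' coefficients are the group mean residuals. The joint test that all group
#' means are zero uses a heteroskedasticity-robust Wald statistic whose
#' covariance accounts for in-sample estimation (the fitted model shrinks
#' grouped residual means), with an eigenvalue pseudo-inverse; the reference
#' distribution is chi-squared with the covariance rank as degrees of
#' freedom.
#'
#' @param model A converged `cost_glm`.
#' @param records The person data the model was fit on.
#' @param n_groups Number of groups (default 10 deciles).
#' @return List with `statistic`, `p_value`, `df`, `n_groups`,
#'   `group_means`.
#' @export
hosmer_lemeshow_test <- function(model, records, n_groups = 10) {
  if (n_groups < 2) stop("n_groups must be at least 2")
  n <- model$n
  if (n < 10 * n_groups)
    stop("need at least 10 observations per group")
  design <- build_design(records, model$encoding)
  r <- model$response - model$fitted_mu
  rk <- rank(model$fitted_eta, ties.method = "first")
  g <- factor(findInterval(rk, seq(1, n + 1, length.out = n_groups + 1)[-1] +
                             0.5) + 1, levels = seq_len(n_groups))
  rbar <- as.numeric(tapply(r, g, mean))
  if (all(abs(r) <= 1e-8 * (abs(model$fitted_mu) + 1)))
    return(list(statistic = 0, p_value = 1, df = 0L, n_groups = n_groups,
                group_means = rbar))
  C <- grouped_residual_cov(model, design$X, g, r)
  ev <- eigen(C, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-8
  z <- crossprod(ev$vectors[, keep, drop = FALSE], rbar)
  stat <- sum(z^2 / ev$values[keep])
  df <- sum(keep)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df, n_groups = n_groups, group_means = rbar)
}

# One Copas split: fit on half A, regress holdout observations on holdout
# predictions, test slope = 1 with a two-component variance: the holdout HC
# component plus the training estimation component a' V(beta) a, using
# b - 1 = sum c_i (y_i - mu_hat_i) with c the OLS slope weights.
copas_one_split <- function(records, family, link, encoding, idx) {
  train <- records[idx, , drop = FALSE]
  hold <- records[-idx, , drop = FALSE]
  m <- fit_glm(build_design(train, encoding), family = family, link = link)
  if (!m$converged) stop("training fit did not converge")
  Xb <- build_design(hold, encoding)$X
  pr <- predict(m, list(X = Xb))
  muh <- pr$mu
  y <- hold$cost_eur
  v <- muh - mean(muh)
  if (sum(v^2) == 0) stop("constant holdout predictions")
  cc <- v / sum(v^2)
  slope <- sum(cc * y)
  a0 <- mean(y) - slope * mean(muh)
  rr <- y - a0 - slope * muh
  v_hold <- sum(cc^2 * rr^2)
  a <- as.numeric(crossprod(Xb, cc * menu_family(family, link)$mu.eta(pr$eta)))
  v_train <- as.numeric(t(a) %*% m$vcov_robust %*% a)
  se <- sqrt(v_hold + v_train)
  # exact-prediction splits: slope and se agree with 1 and 0 only to
  # floating-point resolution
  p <- if (abs(slope - 1) <= 1e-10) 1
       else if (se == 0) 0
       else 2 * pnorm(-abs((slope - 1) / se))
  list(slope = slope, se = se, p = p,
       rmse = sqrt(mean((y - muh)^2)), mae = mean(abs(y - muh)))
}

#' Copas cross-validation test
#'
#' Repeatedly splits the data in random halves, fits the model specification
#' on one half, predicts the other, and regresses observed on predicted costs
#' by OLS; a slope below 1 signals overfitting/shrinkage. Each repetition
#' reports the slope and a two-sided test of slope = 1 whose variance adds
#' the training-stage estimation component to the heteroskedasticity-robust
#' holdout component (holdout-only standard errors over-reject under
#' heavy-tailed costs). Degenerate splits (missing factor levels, constant
#' predictions) are redrawn up to `max_redraws` times with a logged count.
#'
#' @param records Person data frame with at least 100 rows.
#' @param family,link Model specification to validate.
#' @param repetitions Number of split repetitions (default 10).
#' @param seed Integer seed for the splits.
#' @param encoding Optional fixed design encoding.
#' @param max_redraws Redraw budget per repetition.
#' @return List of class `copas_result`: `reps` (data frame with `slope`,
#'   `se`, `p`, `rmse`, `mae`), `mean_slope`, `mean_p` (the summary p-value:
#'   mean of repetition p-values), `rmse_cv`, `mae_cv`, `n_redraws`.
#' @export
copas_test <- function(records, family = "gamma", link = "log",
                       repetitions = 10, seed = 1, encoding = NULL,
                       max_redraws = 10) {
  n <- nrow(records)
  if (n < 100) stop("copas_test needs at least 100 records")
  if (is.null(encoding)) encoding <- build_design(records)$encoding
  set.seed(seed)
  reps <- vector("list", repetitions)
  redraws <- 0L
  for (k in seq_len(repetitions)) {
    for (attempt in seq_len(max_redraws + 1L)) {
      idx <- sample.int(n, n %/% 2)
      out <- tryCatch(copas_one_split(records, family, link, encoding, idx),
                      error = function(e) e)
      if (!inherits(out, "error")) break
      redraws <- redraws + 1L
      if (attempt == max_redraws + 1L)
        stop("repetition ", k, " failed after ", max_redraws, " redraws: ",
             conditionMessage(out))
    }
    reps[[k]] <- as.data.frame(out)
  }
  if (redraws) message(redraws, " degenerate split(s) redrawn")
  reps <- do.call(rbind, reps)
  structure(list(reps = reps,
                 mean_slope = mean(reps$slope),
                 mean_p = mean(reps$p),
                 rmse_cv = mean(reps$rmse),
                 mae_cv = mean(reps$mae),
                 n_redraws = redraws), class = "copas_result")
}

#' Raw-scale fit metrics
#'
#' Auxiliary R-squared (squared correlation from the OLS of observed on
#' predicted costs on the untransformed scale), root mean squared error and
#' mean absolute error.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return List with `r2_aux`, `rmse`, `mae`.
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2)
    stop("observed and predicted must have equal length >= 2")
  if (sd(predicted) == 0) {
    message("constant predictions: auxiliary R-squared set to 0")
    r2 <- 0
  } else {
    r2 <- cor(observed, predicted)^2
  }
  list(r2_aux = r2,
       rmse = sqrt(mean((observed - predicted)^2)),
       mae = mean(abs(observed - predicted)))
}

#' Full specification and validity report
#'
#' Bundles the Pregibon, modified Hosmer-Lemeshow and Copas tests with
#' in-sample and cross-validated raw-scale fit metrics and the deviance
#' pseudo-variance, mirroring the validation battery of the capitation study.
#'
#' @param model A converged `cost_glm`.
#' @param records The person data the model was fit on.
#' @param repetitions Copas repetitions.
#' @param seed Seed for the Copas splits.
#' @return List of class `diagnostics_report`.
#' @export
diagnostics_report <- function(model, records, repetitions = 10, seed = 1) {
  preg <- pregibon_test(model, records)
  hl <- hosmer_lemeshow_test(model, records)
  cop <- copas_test(records, model$spec$family, model$spec$link,
                    repetitions = repetitions, seed = seed,
                    encoding = model$encoding)
  met <- fit_metrics(model$response, model$fitted_mu)
  structure(list(
    pregibon_p = preg$p_value,
    pregibon = preg,
    hl_stat = hl$statistic, hl_p = hl$p_value, hl_groups = hl$n_groups,
    copas_reps = cop$reps, copas_p_summary = cop$mean_p,
    copas_mean_slope = cop$mean_slope,
    r2_aux = met$r2_aux, rmse = met$rmse, mae = met$mae,
    rmse_cv = cop$rmse_cv, mae_cv = cop$mae_cv,
    pseudo_r2 = pseudo_r2_deviance(model)
  ), class = "diagnostics_report")
}
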