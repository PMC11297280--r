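# Fixed-effects probit response model, multivariate outlier screening,
# and correlation comparison.

#' Fit the similarity-by-age probit response model
#'
#' Models the probability of an 'old' response on target and lure trials
#' (foils are excluded: continuous similarity has no baseline encoded
#' phrase there) as
#' `Phi(b0 + b_sim * s + b_age * I(old) + b_sim_age * s * I(old))`,
#' with targets coded `s = 1`. The maximum-likelihood fit uses iteratively
#' reweighted least squares (Fisher scoring) with step halving, so the
#' log-likelihood is non-decreasing across iterations; convergence is a
#' relative log-likelihood change below `tol` (default 1e-8) within
#' `max_iter` iterations. Standard errors come from the observed
#' information at the optimum; estimates are also reported exponentiated
#' (values above 1 increase the odds of responding 'old'), with Wald 95%
#' intervals on the coefficient scale.
#'
#' This is the fixed-effects core of the similarity analysis; random
#' effects for participant, item or trial order are an extension point
#' (fit the same design with a mixed-model backend and compare).
#'
#' @param responses Tibble with `condition`, `similarity`, `age_group`,
#'   `response` (see [simulate_cohort()]); foil rows are dropped.
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @return An object of class `probit_fit`: `coefficients`,
#'   `standard_errors`, `exp_estimates`, `ci95` (matrix with `lower`/
#'   `upper`), `n_obs`, `converged`, `iterations`, `loglik` (per-iteration
#'   trace).
#' @export
fit_probit_similarity_model <- function(responses, max_iter = 100L, tol = 1e-8) {
  stopifnot(all(c("condition", "similarity", "age_group", "response")
                %in% names(responses)))
  d <- responses[responses$condition %in%
                   c("target", "close_lure", "distant_lure"), , drop = FALSE]
  d <- d[!is.na(d$response), , drop = FALSE]
  if (length(unique(d$age_group)) < 2L) {
    abort_smst("both age groups must be present to fit the age terms",
               "smst_design_error")
  }
  if (anyNA(d$similarity) || any(d$similarity < 0 | d$similarity > 1)) {
    abort_smst("similarity must lie in [0, 1] on target/lure trials",
               "smst_domain_error")
  }
  y <- as.numeric(d$response == "old")
  if (all(y == 1) || all(y == 0)) {
    abort_smst("responses are constant: perfect separation, probit unidentifiable",
               "smst_separation_error")
  }
  old <- as.numeric(d$age_group == "old")
  X <- cbind(intercept = 1, sim = d$similarity, age_old = old,
             sim_age_old = d$similarity * old)
  fit <- probit_irls(X, y, max_iter = max_iter, tol = tol)
  ci <- cbind(lower = fit$coefficients - 1.96 * fit$se,
              upper = fit$coefficients + 1.96 * fit$se)
  rownames(ci) <- colnames(X)
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(X)),
    standard_errors = stats::setNames(fit$se, colnames(X)),
    exp_estimates = stats::setNames(exp(fit$coefficients), colnames(X)),
    ci95 = ci, n_obs = nrow(X), converged = fit$converged,
    iterations = fit$iterations, loglik = fit$loglik
  ), class = "probit_fit")
}

probit_loglik <- function(eta, y) {
  # numerically stable via log CDF on the appropriate tail
  sum(ifelse(y == 1, stats::pnorm(eta, log.p = TRUE),
             stats::pnorm(-eta, log.p = TRUE)))
}

probit_irls <- function(X, y, max_iter = 100L, tol = 1e-8) {
  p <- ncol(X)
  beta <- rep(0, p)
  eta <- as.numeric(X %*% beta)
  ll <- probit_loglik(eta, y)
  ll_trace <- ll
  converged <- FALSE
  it <- 0L
  eps <- 1e-10
  while (it < max_iter) {
    it <- it + 1L
    mu <- pmin(pmax(stats::pnorm(eta), eps), 1 - eps)
    phi <- stats::dnorm(eta)
    w <- phi^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / pmax(phi, eps)
    wx <- X * sqrt(w)
    qrfit <- qr(wx)
    if (qrfit$rank < p) {
      abort_smst("design matrix is rank deficient in IRLS", "smst_design_error")
    }
    beta_new <- qr.coef(qrfit, sqrt(w) * z)
    # step halving guarantees a non-decreasing log-likelihood
    step <- 1
    repeat {
      cand <- beta + step * (beta_new - beta)
      eta_cand <- as.numeric(X %*% cand)
      ll_cand <- probit_loglik(eta_cand, y)
      if (ll_cand >= ll - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    beta <- beta + step * (beta_new - beta)
    eta <- as.numeric(X %*% beta)
    ll_new <- probit_loglik(eta, y)
    ll_trace <- c(ll_trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (any(abs(beta) > 1e3)) {
    abort_smst("coefficients diverged: data are (quasi-)separated",
               "smst_separation_error")
  }
  # observed information: -d2l/deta2 = lambda * (lambda + eta) with
  # lambda = phi/Phi for y = 1 and -phi/(1-Phi) for y = 0
  lam <- ifelse(y == 1,
                exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(eta, log.p = TRUE)),
                -exp(stats::dnorm(eta, log = TRUE) - stats::pnorm(-eta, log.p = TRUE)))
  h <- lam * (lam + eta)
  info <- crossprod(X * sqrt(pmax(h, 0)))
  cov <- tryCatch(solve(info), error = function(e) {
    abort_smst("observed information is singular", "smst_design_error")
  })
  list(coefficients = as.numeric(beta), se = sqrt(diag(cov)),
       converged = converged, iterations = it, loglik = ll_trace)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("Probit similarity-by-age model (%d obs, %s in %d iterations)\n",
              x$n_obs, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  tab <- data.frame(estimate = x$coefficients, se = x$standard_errors,
                    exp_estimate = x$exp_estimates,
                    ci_lower = x$ci95[, "lower"], ci_upper = x$ci95[, "upper"])
  print(round(tab, 4))
  invisible(x)
}

#' Multivariate outlier screening by Mahalanobis distance
#'
#' Computes squared Mahalanobis distances of each row from the sample
#' mean/covariance and excludes rows beyond the chi-square quantile cutoff
#' (df = number of covariates unless overridden). With a `group` factor
#' the screen is applied within each group separately, as appropriate for
#' cohorts with different covariate structure.
#'
#' @param covariates Numeric matrix or data frame (rows = cases); row
#'   names (or an `id` column) identify cases.
#' @param quantile Chi-square probability cutoff (default 0.95;
#'   `quantile = 1` excludes nothing).
#' @param df Degrees of freedom for the cutoff; defaults to the number of
#'   covariate columns.
#' @param group Optional factor splitting cases into separately screened
#'   groups.
#' @return An `outlier_report`: `excluded_ids`, `distances` (named squared
#'   distances), `cutoff`, `df`.
#' @export
mahalanobis_outliers <- function(covariates, quantile = 0.95, df = NULL,
                                 group = NULL) {
  if (is.data.frame(covariates)) {
    if ("id" %in% names(covariates)) {
      ids <- as.character(covariates$id)
      covariates <- as.matrix(covariates[setdiff(names(covariates), "id")])
      rownames(covariates) <- ids
    } else {
      covariates <- as.matrix(covariates)
    }
  }
  stopifnot(is.matrix(covariates), is.numeric(covariates))
  if (is.null(rownames(covariates))) {
    rownames(covariates) <- as.character(seq_len(nrow(covariates)))
  }
  if (!is_scalar_number(quantile) || quantile < 0 || quantile > 1) {
    abort_smst("quantile must lie in [0, 1]", "smst_validation_error")
  }
  df <- df %||% ncol(covariates)
  cutoff <- stats::qchisq(quantile, df = df)
  groups <- if (is.null(group)) rep("all", nrow(covariates)) else as.character(group)
  stopifnot(length(groups) == nrow(covariates))
  distances <- numeric(nrow(covariates))
  names(distances) <- rownames(covariates)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- covariates[idx, , drop = FALSE]
    if (nrow(sub) < ncol(sub) + 2L) {
      abort_smst(sprintf("group '%s' has too few rows (%d) for %d covariates",
                         g, nrow(sub), ncol(sub)),
                 "smst_validation_error")
    }
    S <- stats::cov(sub)
    ok <- tryCatch({solve(S); TRUE}, error = function(e) FALSE)
    if (!ok || !all(is.finite(S)) || rcond_safe(S) < 1e-12) {
      abort_smst(
        sprintf("covariance matrix singular in group '%s'; remove redundant covariates", g),
        "smst_singular_covariance_error"
      )
    }
    distances[idx] <- stats::mahalanobis(sub, colMeans(sub), S)
  }
  structure(list(excluded_ids = names(distances)[distances > cutoff],
                 distances = distances, cutoff = cutoff, df = df),
            class = "outlier_report")
}

rcond_safe <- function(S) tryCatch(rcond(S), error = function(e) 0)

#' Pearson correlation with validation
#'
#' @param x,y Equal-length numeric vectors (length at least 3) with
#'   non-zero variance.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort_smst("x and y must have equal length >= 3", "smst_validation_error")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort_smst("inputs must be finite", "smst_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_smst("correlation undefined: zero variance", "smst_undefined_error")
  }
  stats::cor(x, y)
}

#' Fisher z-test comparing two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 Correlations with `|r| < 1`.
#' @param n1,n2 Sample sizes (at least 4).
#' @return List with `z` and `p`.
#' @examples
#' fisher_z_compare(0.46, 40, 0.20, 40)
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(is_scalar_number(r1), is_scalar_number(r2),
            is_count(n1, 4L), is_count(n2, 4L))
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    abort_smst("correlations must satisfy |r| < 1", "smst_domain_error")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}
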