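# Probit model fitting, outlier screening, correlation comparison.

simulate_fit_data <- function(n_per_group, b, seed) {
  # balanced target/lure trials over a similarity grid, both age groups
  sims <- rep(c(1, 0.9, 0.8, 0.55, 0.45), length.out = n_per_group)
  withr::with_seed(seed, {
    tibble::tibble(
      participant_id = rep(1:2, each = n_per_group),
      age_group = rep(c("young", "old"), each = n_per_group),
      condition = rep(ifelse(sims == 1, "target", "close_lure"), 2),
      similarity = rep(sims, 2),
      response = ifelse(
        stats::runif(2 * n_per_group) <
          stats::pnorm(b[1] + b[2] * rep(sims, 2) +
                         b[3] * rep(c(0, 1), each = n_per_group) +
                         b[4] * rep(sims, 2) * rep(c(0, 1), each = n_per_group)),
        "old", "new"
      )
    )
  })
}

test_that("the IRLS probit agrees with glm's probit on the same data", {
  d <- simulate_fit_data(3000, c(-3, 4, 1, -1.2), seed = 71)
  fit <- fit_probit_similarity_model(d)
  ref <- stats::glm(I(response == "old") ~ similarity * I(age_group == "old"),
                    family = stats::binomial("probit"), data = d)
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  # observed vs expected information differ slightly; SEs must still agree
  expect_equal(unname(fit$standard_errors),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 0.05)
  expect_true(fit$converged)
  expect_equal(fit$exp_estimates, exp(fit$coefficients))
  expect_true(all(fit$ci95[, "lower"] < fit$coefficients &
                  fit$coefficients < fit$ci95[, "upper"]))
})

test_that("the IRLS log-likelihood never decreases across iterations", {
  d <- simulate_fit_data(800, c(-2.5, 3.5, 0.8, -1), seed = 73)
  fit <- fit_probit_similarity_model(d)
  expect_true(all(diff(fit$loglik) >= -1e-9))
})

test_that("generator coefficients are recovered within three SEs", {
  b <- c(-4, 5, 1.3, -1.4)
  sch <- paper_schedules()
  params <- response_model_params(b0_foil = b[1], b_sim = b[2], b_age = b[3],
                                  b_sim_age = b[4], sd_participant = 0,
                                  lapse = 0)
  resp <- simulate_cohort(sch, rep(c("young", "old"), each = 20), params,
                          seed = 77)
  fit <- fit_probit_similarity_model(resp)
  z <- abs(fit$coefficients - b) / fit$standard_errors
  expect_true(all(z < 3))
})

test_that("degenerate inputs raise the documented errors", {
  d <- simulate_fit_data(200, c(-2, 3, 1, -1), seed = 75)
  d$response <- "old"
  expect_error(fit_probit_similarity_model(d),
               class = "smst_separation_error")
  d2 <- simulate_fit_data(200, c(-2, 3, 1, -1), seed = 75)
  d2 <- d2[d2$age_group == "young", ]
  expect_error(fit_probit_similarity_model(d2), class = "smst_design_error")
})

test_that("exponentiated estimates read in the documented direction", {
  # a strong positive similarity effect must exponentiate above 1,
  # a negative interaction below 1
  d <- simulate_fit_data(3000, c(-3, 4, 1, -1.2), seed = 79)
  fit <- fit_probit_similarity_model(d)
  expect_gt(fit$exp_estimates[["sim"]], 1)
  expect_lt(fit$exp_estimates[["sim_age_old"]], 1)
})

test_that("an injected far point is the one excluded by the chi-square cutoff", {
  withr::with_seed(81, {
    x <- matrix(stats::rnorm(100), ncol = 2)
    x <- rbind(x, c(10, 10))
    rownames(x) <- paste0("p", 1:51)
    rep <- mahalanobis_outliers(x, quantile = 0.95)
    expect_equal(rep$cutoff, stats::qchisq(0.95, 2))
    expect_true("p51" %in% rep$excluded_ids)
    expect_equal(rep$df, 2L)
    # the reported distances match a direct computation
    d51 <- stats::mahalanobis(x, colMeans(x), stats::cov(x))[51]
    expect_equal(unname(rep$distances["p51"]), unname(d51))

    expect_length(mahalanobis_outliers(x, quantile = 1)$excluded_ids, 0L)

    xx <- matrix(1, nrow = 10, ncol = 2)
    xx[1, ] <- c(2, 2)
    expect_error(mahalanobis_outliers(xx),
                 class = "smst_singular_covariance_error")
  })
})

test_that("outlier distances are invariant under affine transformation", {
  withr::with_seed(83, {
    x <- matrix(stats::rnorm(120), ncol = 3)
    A <- matrix(c(2, 0.5, 0, -1, 3, 0.2, 0, 1, 1.5), 3, 3)
    y <- x %*% A + matrix(rep(c(5, -2, 7), each = 40), ncol = 3)
    rx <- mahalanobis_outliers(x)
    ry <- mahalanobis_outliers(y)
    expect_equal(rx$distances, ry$distances, tolerance = 1e-8)
    expect_identical(rx$excluded_ids, ry$excluded_ids)
  })
})

test_that("group-wise screening uses each group's own covariance", {
  withr::with_seed(85, {
    g1 <- matrix(stats::rnorm(80, 0, 1), ncol = 2)
    g2 <- matrix(stats::rnorm(80, 50, 1), ncol = 2)
    x <- rbind(g1, g2)
    rownames(x) <- paste0("p", 1:80)
    # pooled screening would flag nothing extreme within groups; the shifted
    # group must not be excluded when screened on its own
    rep <- mahalanobis_outliers(x, group = rep(c("a", "b"), each = 40))
    expect_lt(length(rep$excluded_ids), 10)
    expect_true(all(rep$distances < 25))
  })
})

test_that("pearson_r matches the covariance formula and validates input", {
  x <- c(1.2, 2.4, 3.1, 4.8, 5.5, 6.1, 7.9, 8.2, 9.9, 10.3)
  y <- c(2.1, 1.9, 4.2, 4.1, 6.3, 5.9, 8.8, 7.6, 9.1, 11.2)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 10)), class = "smst_undefined_error")
  expect_error(pearson_r(1:2, 1:2), class = "smst_validation_error")
})

test_that("the Fisher z-test matches its closed form", {
  out <- fisher_z_compare(0.3, 40, 0.3, 50)
  expect_equal(out$z, 0)
  expect_equal(out$p, 1)

  out <- fisher_z_compare(0.46, 40, 0.20, 40)
  z_oracle <- (atanh(0.46) - atanh(0.20)) / sqrt(1 / 37 + 1 / 37)
  expect_equal(out$z, z_oracle)
  expect_equal(out$z, 1.267, tolerance = 1e-3)

  swapped <- fisher_z_compare(0.20, 40, 0.46, 40)
  expect_equal(swapped$z, -out$z)
  expect_equal(swapped$p, out$p)

  expect_error(fisher_z_compare(1, 40, 0.2, 40), class = "smst_domain_error")
})
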