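test_that("effect-coded design matrices are orthogonal on balanced full factorials", {
  for (n in 2:5) {
    lv <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    colnames(lv) <- paste0("F", 1:n)
    X <- build_design_matrix(lv, "saturated")
    expect_equal(dim(X), c(2^n, 2^n))
    expect_equal(crossprod(X), 2^n * diag(2^n), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # truncation keeps intercept + mains only
  lv <- as.matrix(expand.grid(A = c(1, -1), B = c(1, -1)))
  expect_equal(dim(build_design_matrix(lv, max_order = 1)), c(4L, 3L))
})

test_that("interaction columns are products of factor levels", {
  lv <- as.matrix(expand.grid(A = c(1, -1), B = c(1, -1), M = c(1, -1)))
  X <- build_design_matrix(lv, "saturated")
  expect_equal(X[, "A:B"], lv[, "A"] * lv[, "B"], ignore_attr = TRUE)
  expect_equal(X[, "A:B:M"], apply(lv, 1, prod), ignore_attr = TRUE)
  expect_true(all(X[, "(Intercept)"] == 1))
})

test_that("constant responses fit as pure intercept", {
  lv <- as.matrix(expand.grid(A = c(1, -1), B = c(1, -1)))
  d <- factorial_design(lv[rep(1:4, 2), ], dG = rep(-3.2, 8))
  fit <- fit_coupling(d)
  expect_equal(unname(coef(fit)["(Intercept)"]), -3.2, tolerance = 1e-12)
  expect_lt(max(abs(coef(fit)[-1])), 1e-12)
})

test_that("noiseless planted coefficients are recovered exactly", {
  truth <- c(C = -8, I4 = 0.4, "I4:F26" = -0.7,
             "I4:F26:Y33:F37:Metal" = -5)
  sim <- gen_factorial_dataset(c("I4", "F26", "Y33", "F37", "Metal"),
                               truth, sigma = 0, replicates = 1)
  fit <- fit_coupling(sim)
  expect_equal(unname(coef(fit)["I4:F26:Y33:F37:Metal"]), -5,
               tolerance = 1e-9)
  expect_equal(unname(coef(fit)["I4:F26"]), -0.7, tolerance = 1e-9)
  expect_equal(unname(coef(fit)["(Intercept)"]), -8, tolerance = 1e-9)
  # all other terms zero
  other <- setdiff(names(coef(fit)),
                   c("(Intercept)", "I4", "I4:F26", "I4:F26:Y33:F37:Metal"))
  expect_lt(max(abs(coef(fit)[other])), 1e-9)
  # saturated single-replicate fit: standard errors honestly unavailable
  expect_false(fit$se_available)
  expect_true(all(is.na(fit$estimates$std_error)))
})

test_that("coefficients equal corner-parity averages on balanced designs", {
  set.seed(3)
  for (n in 2:5) {
    nm <- paste0("F", 1:n)
    sim <- gen_factorial_dataset(nm, setNames(runif(n, -1, 1), nm),
                                 sigma = 0.4, replicates = 2,
                                 seed = 100 + n)
    fit <- fit_coupling(sim)
    est <- coupling_terms(fit)
    for (i in sample(nrow(est), 4)) {
      term <- if (est$term[i] == "(Intercept)") character(0) else
        strsplit(est$term[i], ":")[[1]]
      expect_equal(est$coefficient[i],
                   parity_average_oracle(sim$levels, sim$response, term),
                   tolerance = 1e-10)
    }
  }
})

test_that("order-N regression term matches cycle_coupling on the same rates", {
  set.seed(9)
  for (n in 2:4) {
    nm <- paste0("F", 1:n)
    coefs <- setNames(runif(2, -2, 2), c(nm[1], paste(nm, collapse = ":")))
    sim <- gen_factorial_dataset(nm, coefs, sigma = 0, replicates = 1)
    fit <- fit_coupling(sim)
    est <- coupling_terms(fit)
    top <- est[est$order == n, ]
    ct <- cycle_table(sim$levels, sim$rates)
    expect_equal(top$cycle_energy, cycle_coupling(ct), tolerance = 1e-9)
    expect_equal(top$cycle_energy, 2^n * top$coefficient,
                 tolerance = 1e-12)
  }
})

test_that("coefficients stay attached to their factor subset under reordering", {
  truth <- c("A:C" = -1.4, B = 0.6)
  s1 <- gen_factorial_dataset(c("A", "B", "C"), truth, sigma = 0,
                              replicates = 1)
  s2 <- gen_factorial_dataset(c("C", "B", "A"), truth, sigma = 0,
                              replicates = 1)
  f1 <- coupling_terms(fit_coupling(s1))
  f2 <- coupling_terms(fit_coupling(s2))
  key <- function(e) setNames(e$coefficient, vapply(strsplit(e$term, ":"),
    function(p) paste(sort(p), collapse = ":"), character(1)))
  k1 <- key(f1); k2 <- key(f2)
  expect_equal(k2[names(k1)], k1, tolerance = 1e-9)
})

test_that("noisy coefficient estimates scatter like OLS theory predicts", {
  # sd on the dG scale 0.3, 3 replicates of 2^5 corners: se = 0.3/sqrt(96)
  nm <- c("I4", "F26", "Y33", "F37", "Metal")
  truth <- c(C = -8, "I4:F26:Y33:F37:Metal" = -5)
  se_theory <- 0.3 / sqrt(96)
  worst <- 0
  for (s in 1:100) {
    sim <- gen_factorial_dataset(nm, truth, sigma = 0.3, replicates = 3,
                                 seed = s)
    fit <- fit_coupling(sim)
    err <- coef(fit)
    err["(Intercept)"] <- err["(Intercept)"] + 8
    err["I4:F26:Y33:F37:Metal"] <- err["I4:F26:Y33:F37:Metal"] + 5
    worst <- max(worst, max(abs(err)) / se_theory)
  }
  expect_lt(worst, 4.5)
})

test_that("nominal 95% confidence intervals cover at the nominal rate", {
  nm <- paste0("F", 1:5)
  truth <- setNames(runif(5, -1, 1), nm)
  hits <- 0L; total <- 0L
  for (s in 1:200) {
    sim <- gen_factorial_dataset(nm, truth, sigma = 0.3, replicates = 3,
                                 seed = 5000 + s)
    fit <- fit_coupling(sim)
    ci <- confint(fit)
    tv <- setNames(numeric(nrow(ci)), rownames(ci))
    tv[nm] <- truth
    hits <- hits + sum(ci[, 1] <= tv & tv <= ci[, 2])
    total <- total + nrow(ci)
  }
  coverage <- hits / total
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)
})

test_that("incomplete factorials fit by OLS with a warning", {
  lv <- as.matrix(expand.grid(A = c(1, -1), B = c(1, -1)))
  keep <- rep(1:3, each = 2)   # one corner never observed
  d <- factorial_design(lv[keep, ], dG = c(1, 1.1, 2, 2.1, 3, 3.2))
  expect_warning(fit <- fit_coupling(d, max_order = 1), "not a full")
  expect_length(coef(fit), 3L)
})

test_that("term histogram ranks by magnitude and flags the significance band", {
  sim <- gen_factorial_dataset(paste0("F", 1:3),
                               c("F1:F2:F3" = -2, F1 = 0.1),
                               sigma = 0.05, replicates = 3, seed = 2)
  h <- term_histogram(fit_coupling(sim), threshold = 0.15)
  expect_s3_class(h, "term_histogram")
  expect_identical(h$term[1], "F1:F2:F3")
  body <- h[h$term != "(Intercept)", ]
  expect_true(all(diff(abs(body$coefficient)) <= 1e-12))
  expect_true(h$above_threshold[h$term == "F1:F2:F3"])
  # intercept-only model still reports
  d0 <- factorial_design(matrix(c(1, -1), 2, 1,
                                dimnames = list(NULL, "A")),
                         dG = c(1, 1))
  h0 <- term_histogram(fit_coupling(d0, max_order = 0))
  expect_identical(h0$term, "(Intercept)")
})

test_that("mains-dominant fixture ranks order-1 terms first", {
  sim <- gen_factorial_dataset(paste0("P", 1:5),
                               c(P1 = -1.2, P2 = -0.9, P3 = 0.7,
                                 P4 = -0.5, P5 = 0.4,
                                 "P1:P2" = -0.1),
                               sigma = 0.02, replicates = 2, seed = 31)
  h <- term_histogram(fit_coupling(sim))
  expect_true(all(h$order[1:5] == 1L))
})

test_that("specificity response inverts the discrimination free energy", {
  expect_identical(specificity_response(3, 3), 0)
  expect_equal(specificity_response(exp(6 / 0.592), 1), -6,
               tolerance = 1e-9)
  expect_equal(specificity_response(2.54e4, 1), -6, tolerance = 1e-2)
  expect_equal(specificity_response(5.42, 1), -1, tolerance = 1e-3)
  expect_error(specificity_response(-1, 2), "> 0")
})

test_that("long-format factorial CSV reader builds the requested response", {
  f <- tempfile(fileext = ".csv")
  lv <- expand.grid(A = c(1, -1), B = c(1, -1))
  df <- data.frame(lv, replicate = 1, kcat = c(4, 2, 1, 0.5),
                   KM = c(100, 100, 200, 400))
  write.csv(df, f, row.names = FALSE)
  d1 <- read_factorial_csv(f, response = "kcat")
  expect_equal(d1$response, rate_to_free_energy(df$kcat),
               tolerance = 1e-12)
  d2 <- read_factorial_csv(f, response = "kcat_over_KM")
  expect_equal(d2$response, rate_to_free_energy(df$kcat / df$KM),
               tolerance = 1e-12)
  expect_identical(d2$response_kind, "kcat/KM")
  unlink(f)
})

test_that("holm adjustment only inflates p values", {
  sim <- gen_factorial_dataset(paste0("F", 1:3), c(F1 = -1),
                               sigma = 0.2, replicates = 3, seed = 8)
  raw <- coupling_terms(fit_coupling(sim))
  adj <- coupling_terms(fit_coupling(sim, p_adjust = "holm"))
  i <- raw$term != "(Intercept)"
  expect_true(all(adj$p_value[i] >= raw$p_value[i] - 1e-15))
})
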