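test_that("path_spec parses text, sorts topologically and names cycles", {
  spec <- path_spec(c("A -> B", "B -> C", "# comment", "", "A -> C"))
  expect_identical(spec$exogenous, "A")
  expect_setequal(spec$endogenous, c("B", "C"))
  expect_true(match("A", spec$variables) < match("B", spec$variables))
  expect_error(path_spec(c("A -> B", "B -> C", "C -> A")),
               "cycle.*A -> |cycle.*B -> |cycle.*C -> ")
  expect_error(path_spec(c("A -> A")), "self-loop")
  expect_error(path_spec(c("A -> B", "A -> B")), "duplicate")
})

test_that("implied_covariance reproduces closed forms and simulation", {
  # no edges cannot be expressed (edges define the variables); single edge:
  one <- path_spec(data.frame(from = "X", to = "Y"))
  S1 <- implied_covariance(one, data.frame(from = "X", to = "Y", coef = 0.6),
                           c(Y = 1 - 0.36))
  expect_equal(S1["X", "Y"], 0.6, tolerance = 1e-12)
  expect_equal(unname(diag(S1)), c(1, 1), tolerance = 1e-12)
  # independent exogenous with unit residuals -> identity off the edge
  fork <- path_spec(data.frame(from = c("X", "X"), to = c("M", "Y")))
  cf <- data.frame(from = c("X", "X"), to = c("M", "Y"), coef = c(0.7, 0.4))
  Sf <- implied_covariance(fork, cf, c(M = 1 - 0.49, Y = 1 - 0.16))
  expect_equal(Sf["M", "Y"], 0.7 * 0.4, tolerance = 1e-12)
  # Monte-Carlo oracle on the fork
  d <- simulate_recursive(cf, n = 2e5, seed = 99)
  mc <- cov(as.matrix(d))[colnames(Sf), colnames(Sf)]
  expect_lt(max(abs(mc - Sf)), 0.015)
  expect_error(implied_covariance(fork, cf, c(M = -0.1, Y = 0.5)), ">= 0")
})

test_that("a saturated recursive model fits perfectly", {
  set.seed(8)
  d <- data.frame(X = rnorm(50))
  d$M <- 0.5 * d$X + rnorm(50)
  d$Y <- 0.3 * d$X - 0.4 * d$M + rnorm(50)
  spec <- path_spec(data.frame(from = c("X", "X", "M"), to = c("M", "Y", "Y")))
  fit <- fit_path_model(d, spec)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi_square, 1e-8)
  expect_equal(fit$gfi, 1, tolerance = 1e-8)
  expect_equal(fit$rmsea, 0)
  # coefficients equal the standardized lm solution
  z <- scale(as.matrix(d))
  lmfit <- lm(z[, "Y"] ~ z[, "X"] + z[, "M"] - 1)
  got <- fit$edges$coef[fit$edges$to == "Y"]
  expect_equal(sort(got), sort(unname(coef(lmfit))), tolerance = 1e-8)
})

test_that("path tracing: chain coefficients multiply into the implied corr", {
  cf <- data.frame(from = c("X", "M"), to = c("M", "Y"), coef = c(0.8, 0.5))
  spec <- path_spec(cf[, 1:2])
  S <- implied_covariance(spec, cf, c(M = 1 - 0.64, Y = 1 - 0.25))
  expect_equal(S["X", "Y"], 0.40, tolerance = 1e-12)
  d <- simulate_recursive(cf, n = 2000, seed = 12)
  fit <- fit_path_model(d, spec)
  expect_lt(max(abs(fit$edges$coef - c(0.8, 0.5))), 0.05)
})

test_that("generative coefficients are recovered at large n", {
  cf <- data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
                   coef = c(0.5, -0.45, 0.3))
  d <- simulate_recursive(cf, n = 2000, seed = 31)
  fit <- fit_path_model(d, path_spec(cf[, 1:2]))
  expect_lt(max(abs(fit$edges$coef - cf$coef)), 0.05)
  expect_true(all(fit$edges$p_value < 0.01))
})

test_that("fit_path_model validates its input", {
  spec <- path_spec(data.frame(from = "X", to = "Y"))
  expect_error(fit_path_model(data.frame(X = rnorm(4), Y = rnorm(4)), spec),
               "n >")
  expect_error(fit_path_model(data.frame(X = rnorm(30)), spec), "lacks")
  expect_error(fit_path_model(data.frame(X = rnorm(30), Y = rep(1, 30)), spec),
               "Y")
})

test_that("effect decomposition enumerates all directed paths", {
  cf <- data.frame(from = c("X", "M", "X"), to = c("M", "Y", "Y"),
                   coef = c(0.8, 0.5, -0.2))
  spec <- path_spec(cf[, 1:2])
  eff <- effect_decomposition(spec, cf)
  xy <- eff[eff$source == "X" & eff$target == "Y", ]
  expect_equal(xy$direct, -0.2)
  expect_equal(xy$indirect, 0.8 * 0.5, tolerance = 1e-12)
  expect_equal(xy$total, oracle_total_effect(cf, "X", "Y"), tolerance = 1e-12)
  # chain only: direct 0, indirect = product
  chain <- data.frame(from = c("X", "M"), to = c("M", "Y"), coef = c(0.8, 0.5))
  e2 <- effect_decomposition(path_spec(chain[, 1:2]), chain)
  xy2 <- e2[e2$source == "X" & e2$target == "Y", ]
  expect_equal(c(xy2$direct, xy2$indirect, xy2$total), c(0, 0.4, 0.4),
               tolerance = 1e-12)
  # no path -> all zeros
  yx <- e2[e2$source == "Y" & e2$target == "X", ]
  expect_equal(c(yx$direct, yx$indirect, yx$total), c(0, 0, 0))
  # random specs: total equals exhaustive path enumeration
  set.seed(23)
  for (i in 1:10) {
    vars <- LETTERS[1:5]
    pairs <- t(combn(vars, 2))          # respects an acyclic ordering
    keep <- runif(nrow(pairs)) < 0.5
    if (sum(keep) < 2) next
    cfr <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                      coef = runif(sum(keep), -0.9, 0.9))
    er <- effect_decomposition(path_spec(cfr[, 1:2]), cfr)
    for (j in sample(nrow(er), 5)) {
      expect_equal(er$total[j],
                   oracle_total_effect(cfr, er$source[j], er$target[j]),
                   tolerance = 1e-10)
    }
  }
})

test_that("the default EMF path diagram is acyclic with the expected wiring", {
  spec <- default_emf_path_spec()
  expect_setequal(spec$exogenous, c("TSR", "BSR", "FSR", "SWC", "SBD"))
  expect_true(all(c("EMF", "BNC", "FNC", "LSR") %in% spec$endogenous))
})
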