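test_that("AI-REML matches brute-force restricted-likelihood maximisation", {
  for (seed in 1:5) {
    for (k in 2:3) {
      fx <- make_fixture(seed, n_components = k)
      fit <- fit_univariate(fx$phe, fx$spec, matrices = list(A = fx$A))
      X <- model.matrix(~sex, fx$phe)
      Glist <- glist_from_fixture(fx)
      oracle <- oracle_reml_fit(fx$phe$value, X, Glist)
      expect_equal(unname(fit$components), oracle$theta, tolerance = 1e-3,
                   label = sprintf("components (seed %d, k %d)", seed, k))
      expect_gte(fit$loglik, oracle$ll - 1e-5)
    }
  }
})

test_that("balanced paternal half-sib REML equals the ANOVA estimator", {
  withr::local_seed(7)
  ns <- 80; no <- 12
  off <- sprintf("O%04d", seq_len(ns * no))
  ped <- as_pedigree(tibble::tibble(id = off, dam = NA,
                                    sire = rep(sprintf("S%03d", 1:ns),
                                               each = no)))
  A <- numerator_relatedness(ped)
  s_eff <- rnorm(ns, sd = sqrt(0.3 / 4))
  y <- rep(s_eff, each = no) + rnorm(ns * no, sd = sqrt(1 - 0.3 / 4))
  phe <- tibble::tibble(id = off, trait = "w", value = y)
  fit <- fit_univariate(phe, model_spec("w", ~1,
                                        list(additive = ran_matrix("id", "A"))),
                        matrices = list(A = A))
  ms <- anova(lm(y ~ factor(rep(1:ns, each = no))))
  sire_vc <- (ms$`Mean Sq`[1] - ms$`Mean Sq`[2]) / no
  expect_equal(fit$components[["additive"]], 4 * sire_vc, tolerance = 1e-4)
})

test_that("noiseless breeding values drive the residual to the boundary", {
  # with y drawn exactly as breeding values the residual truth is zero;
  # its REML estimate behaves like max(0, Z), so any one draw may sit just
  # inside the boundary -- check the ensemble over several draws
  ped <- random_pedigree(n_founders = 20, n_gen = 3, per_gen = 120, seed = 3)
  A <- numerator_relatedness(ped)
  n <- nrow(ped)
  spec <- model_spec("w", ~1, list(additive = ran_matrix("id", "A")))
  h2 <- pinned <- logical(0)
  res_ratio <- numeric(0)
  for (s in 1:6) {
    a <- withr::with_seed(s, drop(crossprod(chol(A$values + diag(1e-8, n)),
                                            rnorm(n))))
    phe <- tibble::tibble(id = ped$id, trait = "w", value = a)
    fit <- fit_univariate(phe, spec, matrices = list(A = A))
    h2 <- c(h2, fit$ratios$ratio[fit$ratios$term == "additive"] >= 0.99)
    pinned <- c(pinned, fit$boundary[["residual"]])
    res_ratio <- c(res_ratio, fit$ratios$ratio[fit$ratios$term == "residual"])
  }
  expect_true(any(pinned))
  expect_true(all(h2[pinned]))      # a pinned residual means h2 ~ 1
  expect_lt(mean(res_ratio), 0.05)  # and the ensemble sits at the boundary
})

test_that("restricted likelihood is invariant to fixed-effect recoding", {
  fx <- make_fixture(11, n_components = 2)
  fit1 <- fit_univariate(fx$phe, fx$spec, matrices = list(A = fx$A))
  phe2 <- fx$phe
  phe2$sex <- factor(phe2$sex, levels = c("M", "F")) # flip reference level
  fit2 <- fit_univariate(phe2, fx$spec, matrices = list(A = fx$A))
  expect_lt(abs(fit1$loglik - fit2$loglik), 1e-6)
  expect_equal(fit1$components, fit2$components, tolerance = 1e-4)
})

test_that("confounded structures are rejected", {
  phe <- tibble::tibble(id = sprintf("i%02d", 1:20), trait = "w",
                        value = rnorm(20))
  expect_error(
    fit_univariate(phe, model_spec("w", ~1, list(pe = ran_group("id"))),
                   matrices = list()),
    "not separable")
})

test_that("records with missing covariates or unmatched ids are dropped", {
  fx <- make_fixture(5, n_components = 2)
  phe <- fx$phe
  phe$sex[1] <- NA
  expect_message(
    fit <- fit_univariate(phe, fx$spec, matrices = list(A = fx$A)),
    "dropped")
  expect_equal(fit$n, nrow(phe) - 1)
  expect_equal(fit$n_dropped, 1)
})

test_that("variance ratios and their delta-method SEs are consistent", {
  # arithmetic of the ratios
  fake <- structure(list(
    components = c(a = 1, m = 1, residual = 2),
    vcov = diag(c(0.1, 0.1, 0.2)),
    boundary = c(a = FALSE, m = FALSE, residual = FALSE)
  ), class = "vc_fit")
  vr <- variance_ratios(fake)
  expect_equal(vr$ratio, c(0.25, 0.25, 0.5))
  expect_equal(sum(vr$ratio), 1)

  fake2 <- fake
  fake2$components <- c(a = 2, residual = 2)
  fake2$vcov <- diag(c(0.1, 0.1))
  fake2$boundary <- c(a = FALSE, residual = FALSE)
  expect_equal(variance_ratios(fake2)$ratio, c(0.5, 0.5))

  # delta-method SE of h2 tracks the parametric-bootstrap spread
  ped <- random_pedigree(n_founders = 30, n_gen = 3, per_gen = 80, seed = 6)
  A <- numerator_relatedness(ped)
  spec <- model_spec("w", ~1, list(additive = ran_matrix("id", "A")))
  phe <- simple_phenotypes(ped, A, h2 = 0.4, seed = 7, trait = "w")
  fit <- fit_univariate(phe, spec, matrices = list(A = A))
  se_delta <- fit$ratios$se_ratio[fit$ratios$term == "additive"]
  h2_hat <- fit$ratios$ratio[fit$ratios$term == "additive"]
  vp_hat <- sum(fit$components)
  boots <- vapply(1:60, function(b) {
    phe_b <- simple_phenotypes(ped, A, h2 = h2_hat, vp = vp_hat,
                               seed = 1000 + b, trait = "w")
    fb <- fit_univariate(phe_b, spec, matrices = list(A = A))
    fb$ratios$ratio[fb$ratios$term == "additive"]
  }, numeric(1))
  expect_lt(abs(se_delta - sd(boots)) / sd(boots), 0.35)
})

test_that("likelihood ratio tests follow the chi-squared convention", {
  expect_equal(likelihood_ratio_test(1.9205, 0)$p_value, 0.05,
               tolerance = 1e-3)
  eq <- likelihood_ratio_test(-3.2, -3.2)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # floor at zero when the reduced model appears better
  expect_equal(likelihood_ratio_test(-5, -4)$statistic, 0)
  # mixture halves the tail p
  expect_equal(likelihood_ratio_test(1.9205, 0, mixture = TRUE)$p_value,
               0.025, tolerance = 1e-3)

  # differing fixed structures are rejected
  fx <- make_fixture(2, n_components = 3)
  full <- fit_univariate(fx$phe, fx$spec, matrices = list(A = fx$A))
  red_spec <- model_spec("w", ~1, fx$spec$random["additive"])
  red <- fit_univariate(fx$phe, red_spec, matrices = list(A = fx$A))
  expect_error(likelihood_ratio_test(full, red), "fixed-effect")
  # matched fixed effects work and give a nonnegative statistic
  red_spec2 <- model_spec("w", ~sex, fx$spec$random["additive"])
  red2 <- fit_univariate(fx$phe, red_spec2, matrices = list(A = fx$A))
  lrt <- likelihood_ratio_test(full, red2)
  expect_gte(lrt$statistic, 0)
  expect_lte(lrt$p_value, 1)
})
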