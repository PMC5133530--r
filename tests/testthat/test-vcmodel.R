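make_design <- function(df, ped, formula = Y1 ~ 1, ...)
  vc_design(formula, df, ped, ...)

test_that("equality constraints collapse design columns by summation", {
  ped <- ped_nuclear(3L)
  df <- data.frame(person_id = ped$person_id,
                   SBP_1 = rnorm(5), SBP_2 = rnorm(5), SBP_3 = rnorm(5),
                   age = 30:34)
  groups <- list(SBP = c("SBP_1", "SBP_2", "SBP_3"))
  dsn_con <- vc_design(cbind(SBP_1, SBP_2, SBP_3) ~ age, df, ped,
                       constraints = "age", trait_groups = groups)
  dsn_free <- vc_design(cbind(SBP_1, SBP_2, SBP_3) ~ age, df, ped)
  # constrained: 1 age coefficient, free: 3
  expect_equal(sum(grepl("age", dsn_con$coef_names)), 1L)
  expect_equal(sum(grepl("age", dsn_free$coef_names)), 3L)
  # free-coefficient reduction is sum(group size - 1)
  expect_equal(length(dsn_free$coef_names) - length(dsn_con$coef_names),
               3L - 1L)
  # the constrained column is the sum of the per-trait columns
  jc <- grep("age", dsn_con$coef_names)
  jf <- grep("age", dsn_free$coef_names)
  A_con <- dsn_con$blocks[[1L]]$A
  A_free <- dsn_free$blocks[[1L]]$A
  expect_equal(A_con[, jc], rowSums(A_free[, jf]))
})

test_that("constraint groups respect trait grouping (one beta per group)", {
  ped <- ped_nuclear(3L)
  df <- data.frame(person_id = ped$person_id,
                   SBP_1 = rnorm(5), SBP_2 = rnorm(5),
                   DBP_1 = rnorm(5), DBP_2 = rnorm(5), age = 30:34)
  dsn <- vc_design(cbind(SBP_1, SBP_2, DBP_1, DBP_2) ~ age, df, ped,
                   constraints = c("(Intercept)", "age"),
                   trait_groups = list(SBP = c("SBP_1", "SBP_2"),
                                       DBP = c("DBP_1", "DBP_2")))
  expect_setequal(dsn$coef_names,
                  c("SBP:(Intercept)", "DBP:(Intercept)",
                    "SBP:age", "DBP:age"))
})

test_that("unknown covariates and rank deficiency are rejected", {
  ped <- ped_nuclear(2L)
  df <- data.frame(person_id = ped$person_id, Y1 = rnorm(4), age = 1:4)
  expect_error(vc_design(Y1 ~ weight, df, ped), "weight")
  df$age2 <- df$age * 2
  expect_error(vc_design(Y1 ~ age + age2, df, ped), "rank deficient")
})

test_that("loglikelihood: standard normal at its mean", {
  ped <- as_pedigree(data.frame(pedigree_id = "p", person_id = "a",
                                father_id = NA, mother_id = NA))
  df <- data.frame(person_id = "a", Y1 = 0)
  dsn <- vc_design(Y1 ~ 1, df, ped)
  st <- vc_structures(dsn, ped, "environmental", "theoretical")
  ll <- vc_loglik(dsn, st, beta = 0, Sigma = list(environmental = matrix(1)))
  expect_equal(ll, -0.5 * log(2 * pi), tolerance = 1e-9)
  expect_equal(ll, -0.918939, tolerance = 1e-6)
})

test_that("loglikelihood equals the dense MVN oracle, incl. marginalization", {
  set.seed(14)
  for (rep in 1:8) {
    T_ <- sample(1:3, 1L)
    spec <- sim_spec(n_pedigrees = 2L, sibship = c(2L, 3L),
                     trait_names = paste0("Y", seq_len(T_)),
                     Sigma_a = crossprod(matrix(rnorm(T_ * T_), T_)) / 2,
                     Sigma_h = crossprod(matrix(rnorm(T_ * T_), T_)) / 4,
                     Sigma_e = crossprod(matrix(rnorm(T_ * T_), T_)) + diag(T_),
                     miss_trait = 0.15)
    sim <- sim_study(spec, seed = 100 + rep)
    df <- sim_data_frame(sim)
    dsn <- vc_design(stats::as.formula(paste0(
      if (T_ > 1L) paste0("cbind(", paste0("Y", 1:T_, collapse = ","), ")")
      else "Y1", " ~ age")), df, sim$pedigree)
    comps <- c("additive", "household", "environmental")
    st <- vc_structures(dsn, sim$pedigree, comps, "theoretical")
    beta <- rnorm(length(dsn$coef_names))
    Sigma <- list(additive = spec$Sigma_a, household = spec$Sigma_h,
                  environmental = spec$Sigma_e)
    ll <- vc_loglik(dsn, st, beta, Sigma, by_pedigree = TRUE)
    # oracle: dense covariance per pedigree, observed rows only
    for (i in seq_along(dsn$blocks)) {
      b <- dsn$blocks[[i]]
      K <- list(additive = st$additive[[i]], household = st$household[[i]],
                environmental = st$environmental[[i]])
      Sfull <- oracle_sigma(Sigma, K)[b$obs, b$obs]
      mu <- drop(b$A %*% beta)
      expect_equal(ll[i], oracle_mvn_logdens(b$y, mu, Sfull),
                   tolerance = 1e-8)
    }
  }
})

test_that("independent pedigrees contribute additively to the loglikelihood", {
  sim <- sim_study(sim_spec(n_pedigrees = 3L), seed = 6)
  df <- sim_data_frame(sim)
  dsn <- vc_design(Y1 ~ age, df, sim$pedigree)
  st <- vc_structures(dsn, sim$pedigree, c("additive", "environmental"),
                      "theoretical")
  Sigma <- list(additive = matrix(0.7), environmental = matrix(1.2))
  beta <- c(100, 0.4)
  llp <- vc_loglik(dsn, st, beta, Sigma, by_pedigree = TRUE)
  expect_equal(sum(llp), vc_loglik(dsn, st, beta, Sigma))
  # each pedigree alone reproduces its contribution
  for (pid in unique(sim$pedigree$pedigree_id)[1:2]) {
    sub <- as_pedigree(as.data.frame(
      sim$pedigree[sim$pedigree$pedigree_id == pid, ]))
    dsub <- vc_design(Y1 ~ age, df[df$person_id %in% sub$person_id, ], sub)
    ssub <- vc_structures(dsub, sub, c("additive", "environmental"),
                          "theoretical")
    i <- which(unique(sim$pedigree$pedigree_id) == pid)
    expect_equal(vc_loglik(dsub, ssub, beta, Sigma), llp[i],
                 tolerance = 1e-10)
  }
})

test_that("fit matches closed-form OLS/ML on unrelateds without polygenics", {
  set.seed(22)
  sim <- sim_study(sim_spec(n_pedigrees = 0L, n_unrelated = 120L,
                            Sigma_a = matrix(0), Sigma_e = matrix(2)),
                   seed = 22)
  df <- sim_data_frame(sim)
  fit <- pedvc(Y1 ~ age + sex, df, sim$pedigree,
               components = "environmental")
  ols <- lm(Y1 ~ age + sex, df)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-6)
  sig2_ml <- sum(resid(ols)^2) / nrow(df)
  expect_equal(fit$Sigma$environmental[1L, 1L], sig2_ml, tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("loglikelihood is invariant to input row order", {
  sim <- sim_study(sim_spec(n_pedigrees = 4L), seed = 17)
  df <- sim_data_frame(sim)
  fit1 <- pedvc(Y1 ~ age + sex, df, sim$pedigree)
  fit2 <- pedvc(Y1 ~ age + sex, df[sample.int(nrow(df)), ], sim$pedigree)
  expect_equal(fit1$logLik, fit2$logLik, tolerance = 1e-8)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-6)
})

test_that("additive variance simulated as zero is estimated near zero", {
  set.seed(33)
  frac <- replicate(12, {
    sim <- sim_study(sim_spec(n_pedigrees = 8L, Sigma_a = matrix(0),
                              Sigma_e = matrix(1)),
                     seed = sample.int(1e6, 1L))
    fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
    fit$Sigma$additive[1L, 1L] /
      (fit$Sigma$additive[1L, 1L] + fit$Sigma$environmental[1L, 1L])
  })
  expect_lt(median(frac), 0.05)
})

test_that("missing covariates drop the individual and are logged", {
  sim <- sim_study(sim_spec(n_pedigrees = 3L), seed = 19)
  df <- sim_data_frame(sim)
  df$age[2L] <- NA
  fit <- pedvc(Y1 ~ age, df, sim$pedigree)
  expect_equal(fit$dropped$person_id, df$person_id[2L])
  expect_equal(fit$dropped$reason, "missing_covariate")
  expect_equal(fit$n, nrow(df) - 1L)
})

test_that("unrelateds with additive + environmental are flagged as confounded", {
  sim <- sim_study(sim_spec(n_pedigrees = 0L, n_unrelated = 40L),
                   seed = 12)
  expect_warning(
    fit <- pedvc(Y1 ~ 1, sim_data_frame(sim), sim$pedigree,
                 components = c("additive", "environmental")),
    "confounded")
  expect_false(fit$identifiable)
})

test_that("reported loglikelihood re-evaluates at the estimates", {
  sim <- sim_study(sim_spec(n_pedigrees = 5L), seed = 27)
  fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
  ll <- vc_loglik(fit$design, fit$structures, coef(fit), fit$Sigma)
  expect_equal(fit$logLik, ll, tolerance = 1e-6)
  expect_equal(sum(fit$logLik_by_pedigree), fit$logLik, tolerance = 1e-8)
})

test_that("outlier report ranks a shifted pedigree first; zero residual gives 0", {
  set.seed(41)
  sim <- sim_study(sim_spec(n_pedigrees = 10L), seed = 41)
  df <- sim_data_frame(sim)
  target <- unique(sim$pedigree$pedigree_id)[4L]
  shift_ids <- sim$pedigree$person_id[sim$pedigree$pedigree_id == target]
  df$Y1[df$person_id %in% shift_ids] <-
    df$Y1[df$person_id %in% shift_ids] + 10 * sd(df$Y1)
  fit <- pedvc(Y1 ~ age, df, sim$pedigree)
  rep_out <- pedigree_outlier_report(fit)
  expect_equal(rep_out$pedigrees$pedigree_id[1L], target)
  expect_true(all(rep_out$pedigrees$statistic >= 0))
  expect_true(!is.unsorted(rep_out$pedigrees$p))

  # per-pedigree statistic is r' Sigma^-1 r with the right chi-square df
  i <- 1L
  b <- fit$blocks[[i]]
  expect_equal(rep_out$pedigrees$m[rep_out$pedigrees$pedigree_id ==
                 fit$pedigree$pedigree_id[match(b$ids[1], fit$pedigree$person_id)]][1],
               length(b$y))

  # a block with zero residual scores exactly 0
  fake <- fit
  fake$blocks <- list(list(ids = "solo", n = 1L,
                           obs_map = data.frame(ind = 1L, trait = 1L),
                           y = 1, resid = 0, Sinv_r = 0,
                           R = matrix(1, 1, 1)))
  fake$pedigree <- as_pedigree(data.frame(pedigree_id = "solo",
                                          person_id = "solo",
                                          father_id = NA, mother_id = NA))
  expect_equal(pedigree_outlier_report(fake)$pedigrees$statistic, 0)
})

test_that("summary reports coefficient and variance-component uncertainty", {
  sim <- sim_study(sim_spec(n_pedigrees = 6L), seed = 55)
  fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
  s <- summary(fit)
  expect_true(all(is.finite(s$coefficients[, "Std. Error"])))
  vp <- s$information$par
  expect_equal(unname(vp["additive[1,1]"]), fit$Sigma$additive[1, 1])
  expect_true(all(is.finite(s$information$se)))
  # simulate() round-trip: mean-centered draws have roughly the fitted
  # marginal variance (2 * phi_ii * Sigma_a + Sigma_e)
  ys <- simulate(fit, nsim = 30, seed = 1)
  mu <- fitted(fit)
  vtot <- 2 * 0.5 * fit$Sigma$additive[1, 1] + fit$Sigma$environmental[1, 1]
  vemp <- mean(sapply(ys, function(Y) var(Y[, 1] - mu[, 1], na.rm = TRUE)))
  expect_lt(abs(vemp - vtot) / vtot, 0.5)
})
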