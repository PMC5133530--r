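test_that("score test reduces to the Armitage-type trend statistic", {
  set.seed(51)
  sim <- sim_study(sim_spec(n_pedigrees = 0L, n_unrelated = 150L,
                            n_snps = 5L, Sigma_a = matrix(0),
                            Sigma_e = matrix(1)), seed = 51)
  df <- sim_data_frame(sim)
  fit <- pedvc(Y1 ~ 1, df, sim$pedigree, components = "environmental")
  for (j in 1:5) {
    x <- sim$geno$dosage[, j]
    st <- score_test(fit, x)
    y <- df$Y1[match(names(x), df$person_id)]
    expect_equal(st$stat, length(y) * cor(x, y)^2, tolerance = 1e-8)
  }
})

test_that("dosage orthogonal to the residuals gives a zero statistic", {
  set.seed(52)
  sim <- sim_study(sim_spec(n_pedigrees = 0L, n_unrelated = 60L,
                            Sigma_a = matrix(0), Sigma_e = matrix(1)),
                   seed = 52)
  df <- sim_data_frame(sim)
  fit <- pedvc(Y1 ~ 1, df, sim$pedigree, components = "environmental")
  r <- residuals(fit)[, 1L]
  x <- rnorm(length(r))
  x <- x - mean(x) - r * sum(x * r) / sum(r^2)  # orthogonal to 1 and r
  names(x) <- names(r)
  st <- score_test(fit, x)
  expect_equal(st$stat, 0, tolerance = 1e-12)
  expect_equal(st$p, 1, tolerance = 1e-10)
})

test_that("score test is invariant to the 2 - x allele flip", {
  sim <- sim_study(sim_spec(n_pedigrees = 6L, n_snps = 4L), seed = 53)
  fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
  for (j in 1:4) {
    x <- sim$geno$dosage[, j]
    s1 <- score_test(fit, x)
    s2 <- score_test(fit, 2 - x)
    expect_equal(s1$stat, s2$stat, tolerance = 1e-9)
  }
})

test_that("constant dosage yields an undefined-test flag, not an error", {
  sim <- sim_study(sim_spec(n_pedigrees = 3L), seed = 54)
  fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
  x <- rep(1, fit$n); names(x) <- fit$design$ids
  st <- score_test(fit, x)
  expect_equal(st$flag, "undefined")
  expect_true(is.na(st$p))
})

test_that("LRT agrees with an independent from-scratch refit", {
  sim <- sim_study(sim_spec(n_pedigrees = 6L, n_snps = 3L,
                            causal = data.frame(snp = 1L, trait = 1L,
                                                beta = 0.8)),
                   seed = 57)
  df <- sim_data_frame(sim)
  fit <- pedvc(Y1 ~ age, df, sim$pedigree)
  x <- sim$geno$dosage[, 1L]
  lr <- lrt(fit, x)
  expect_gte(lr$stat, 0)
  # naive refit: add the SNP as an ordinary covariate and fit from scratch
  df$snp1 <- x[df$person_id]
  df$snp1[is.na(df$snp1)] <- mean(df$snp1, na.rm = TRUE)
  fit_alt <- pedvc(Y1 ~ age + snp1, df, sim$pedigree)
  expect_equal(lr$stat, 2 * (fit_alt$logLik - fit$logLik), tolerance = 1e-4)
  expect_equal(unname(lr$effects), unname(coef(fit_alt)["Y1:snp1"]),
               tolerance = 1e-3)
})

test_that("score and LRT p-values agree asymptotically on causal SNPs", {
  set.seed(58)
  sim <- sim_study(sim_spec(n_pedigrees = 12L, sibship = c(3L, 4L),
                            n_snps = 2L, mafs = c(0.3, 0.3),
                            causal = data.frame(snp = 1L, trait = 1L,
                                                beta = 0.5)),
                   seed = 58)
  fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
  x <- sim$geno$dosage[, 1L]
  st <- score_test(fit, x)
  lr <- lrt(fit, x)
  if (st$p < 1e-3) {
    expect_lt(abs(log(st$p / lr$p)), log(2))
  } else {
    expect_equal(st$p, lr$p, tolerance = 0.5)
  }
})

test_that("gwas_scan refines exactly top_k SNPs and attaches metadata", {
  sim <- sim_study(sim_spec(n_pedigrees = 8L, n_snps = 100L), seed = 59)
  fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
  scan <- gwas_scan(fit, sim$geno, maf_min = 0.03)
  expect_equal(sum(!is.na(scan$table$lrt_p)), 10L)  # top 10 by default
  # refined set is exactly the 10 smallest score p-values
  refined <- which(!is.na(scan$table$lrt_p))
  ord <- order(scan$table$score_p)[1:10]
  expect_setequal(refined, ord)
  expect_equal(scan$m_tested, sum(!is.na(scan$table$score_p)))
  expect_equal(scan$bonferroni$threshold, 0.05 / scan$m_tested)
  expect_true(is.finite(scan$lambda_gc))
  expect_s3_class(scan$effects, "data.frame")
})

test_that("scan errors when no SNP passes the MAF rule", {
  sim <- sim_study(sim_spec(n_pedigrees = 4L, n_snps = 5L,
                            mafs = rep(0.01, 5L)), seed = 61)
  fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
  expect_error(gwas_scan(fit, sim$geno, maf_min = 0.45), "MAF|empty")
})

test_that("planted causal SNP is detected among null SNPs", {
  set.seed(62)
  hits <- replicate(10, {
    sim <- sim_study(sim_spec(n_pedigrees = 10L, sibship = c(3L, 4L),
                              n_snps = 50L,
                              mafs = c(0.3, runif(49, 0.1, 0.5)),
                              causal = data.frame(snp = 1L, trait = 1L,
                                                  beta = 1.0)),
                     seed = sample.int(1e6, 1L))
    fit <- pedvc(Y1 ~ age, sim_data_frame(sim), sim$pedigree)
    scan <- gwas_scan(fit, sim$geno, top_k = 0L, maf_min = 0.03)
    which.min(scan$table$score_p) == 1L
  })
  expect_gte(mean(hits), 0.7)
})

test_that("genomic inflation factor: identity, scale, calibration", {
  med1 <- qchisq(0.5, 1)
  expect_equal(genomic_inflation(rep(med1, 11L), 1), 1)
  s <- rchisq(999, 2)
  expect_equal(genomic_inflation(2 * s, 2), 2 * genomic_inflation(s, 2))
  set.seed(63)
  s2 <- qchisq(runif(1e5), 2)   # uniform p-values, df = 2
  expect_gt(genomic_inflation(s2, 2), 0.98)
  expect_lt(genomic_inflation(s2, 2), 1.02)
})

test_that("Bonferroni thresholds reproduce the printed analytic values", {
  b1 <- bonferroni_threshold(0.05, 3084046)
  expect_equal(b1$threshold, 1.62e-8, tolerance = 0.005)
  expect_equal(round(b1$neg_log10, 2), 7.79)
  b2 <- bonferroni_threshold(0.05, 52314)
  expect_equal(b2$threshold, 9.56e-7, tolerance = 0.005)
  expect_equal(round(b2$neg_log10, 2), 6.02)
  b3 <- bonferroni_threshold(0.05, 20634 * 4199714)
  expect_equal(b3$threshold, 5.77e-13, tolerance = 0.005)
})

test_that("Benjamini-Hochberg step-up rule", {
  expect_equal(bh_fdr_threshold(c(0.001, 0.01, 0.02, 0.9), 0.05), 0.02)
  expect_true(is.na(bh_fdr_threshold(rep(1, 10), 0.05)))
  expect_equal(bh_fdr_threshold(0.01, 0.05), 0.01)
  # agreement with p.adjust on random input
  set.seed(64)
  p <- runif(200)^2
  cut <- bh_fdr_threshold(p, 0.05)
  padj <- p.adjust(p, "BH")
  if (is.na(cut)) {
    expect_true(all(padj > 0.05))
  } else {
    expect_true(all(p.adjust(p, "BH")[p <= cut] <= 0.05 + 1e-12))
  }
})

test_that("null score p-values are approximately uniform", {
  set.seed(65)
  sim <- sim_study(sim_spec(n_pedigrees = 10L, sibship = c(3L, 4L),
                            n_snps = 400L), seed = 65)
  fit <- pedvc(Y1 ~ age + sex, sim_data_frame(sim), sim$pedigree)
  scan <- gwas_scan(fit, sim$geno, top_k = 0L, maf_min = 0.05)
  p <- scan$table$score_p[!is.na(scan$table$score_p)]
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_gt(scan$lambda_gc, 0.85)
  expect_lt(scan$lambda_gc, 1.15)
})
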