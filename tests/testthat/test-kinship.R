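test_that("theoretical kinship reproduces textbook coefficients", {
  phi <- theoretical_kinship(ped_nuclear(2L))
  expect_equal(phi["f", "f"], 0.5)
  expect_equal(phi["f", "m"], 0)
  expect_equal(phi["f", "k1"], 0.25)   # parent-offspring
  expect_equal(phi["k1", "k2"], 0.25)  # full siblings

  phi_h <- theoretical_kinship(ped_half_sibs())
  expect_equal(phi_h["k1", "k2"], 0.125)

  phi_i <- theoretical_kinship(ped_sib_mating())
  expect_equal(phi_i["c", "c"], 5 / 8)  # self-kinship of inbred child
})

test_that("recursive kinship agrees with gene-dropping Monte Carlo", {
  set.seed(42)
  ped <- ped_sib_mating()
  phi <- theoretical_kinship(ped)
  for (pair in list(c("c", "c"), c("s1", "s2"), c("s1", "c"))) {
    mc <- mc_kinship(ped, pair[1L], pair[2L], nrep = 1e5)
    expect_within_3se(mc$est, phi[pair[1L], pair[2L]], mc$se)
  }
})

test_that("kinship is invariant to individual relabeling/reordering", {
  ped <- ped_double_first_cousins()
  phi <- theoretical_kinship(ped)
  df <- as.data.frame(ped)
  df <- df[sample.int(nrow(df)), ]
  phi2 <- theoretical_kinship(as_pedigree(df))
  expect_equal(phi2[rownames(phi), colnames(phi)], phi,
               ignore_attr = TRUE)
})

test_that("Delta7 matches the exact transmission-enumeration oracle", {
  ped <- ped_nuclear(2L)
  d7 <- delta7_matrix(ped)
  expect_equal(d7["f", "k1"], 0)       # parent-offspring
  expect_equal(d7["k1", "k2"], 0.25)   # full siblings
  expect_equal(d7["k1", "k2"], enum_delta7(ped, "k1", "k2"))
  expect_equal(d7["f", "k1"], enum_delta7(ped, "f", "k1"))

  dfc <- ped_double_first_cousins()
  d7c <- delta7_matrix(dfc)
  expect_equal(d7c["c1", "c2"], 1 / 16)
  expect_equal(d7c["c1", "c2"], enum_delta7(dfc, "c1", "c2"))
  expect_equal(d7c["a1", "c1"], enum_delta7(dfc, "a1", "c1"))
  expect_equal(diag(d7c), rep(1, nrow(dfc)), ignore_attr = TRUE)
})

test_that("Delta7 refuses inbred pedigrees", {
  expect_error(delta7_matrix(ped_sib_mating()), "inbred")
})

test_that("household matrix follows the shared-household rule", {
  ped <- as_pedigree(data.frame(
    pedigree_id = "fam", person_id = c("a", "b", "c", "d"),
    father_id = NA, mother_id = NA,
    household_id = c("h1", "h1", "h2", NA)))
  H <- household_matrix(ped)
  expect_equal(H["a", "b"], 1)   # same household
  expect_equal(H["a", "c"], 0)   # different household
  expect_equal(unname(H[, "d"]), c(0, 0, 0, 1))  # singleton: identity row
  expect_equal(diag(H), rep(1, 4), ignore_attr = TRUE)
})

test_that("structure matrices are symmetric and PSD", {
  ped <- sim_pedigree(sim_spec(n_pedigrees = 3L), seed = 2)
  for (K in list(theoretical_kinship(ped), delta7_matrix(ped),
                 household_matrix(ped))) {
    expect_equal(K, t(K), ignore_attr = TRUE)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
})

test_that("empirical kinship: duplicates, unrelateds, missing handling", {
  set.seed(7)
  S <- 4000L
  p <- runif(S, 0.1, 0.5)
  n <- 40L
  d <- sapply(p, function(pp) rbinom(n, 2L, pp))
  dimnames(d) <- list(sprintf("u%02d", 1:n), paste0("1-", 1:S))
  d[1L, ] <- d[2L, ]                      # planted duplicate pair
  g <- geno_matrix(d, normalize = FALSE)

  K <- grm_kinship(g)
  expect_equal(K, t(K), ignore_attr = TRUE)
  expect_equal(K["u01", "u02"], K["u01", "u01"])  # duplicate = self
  # sample-frequency centering induces a deterministic -diag/(n-1)
  # finite-sample shift on off-diagonals of unrelateds; beyond it the
  # mean is within Monte Carlo error of 0
  off <- K[upper.tri(K)][-1L]             # drop the duplicate pair
  bias <- -mean(diag(K)) / (n - 1)
  expect_lt(abs(mean(off) - bias), 3 * sd(off) / sqrt(length(off)) + 0.003)

  M <- mom_kinship(g)
  expect_equal(M["u01", "u02"], M["u01", "u01"])
  moff <- M[upper.tri(M)][-1L]
  mbias <- -mean(diag(M)) / (n - 1)
  expect_lt(abs(mean(moff) - mbias),
            3 * sd(moff) / sqrt(length(moff)) + 0.003)
  # identical fully-informative rows dominate any non-identical pair
  expect_gte(M["u01", "u02"], max(moff))

  # pairwise-complete missing handling: masked entries do not bias
  d2 <- d; d2[sample(length(d2), length(d2) %/% 10L)] <- NA
  K2 <- grm_kinship(geno_matrix(d2, normalize = FALSE))
  expect_lt(max(abs(K2 - K)), 0.15)

  # monomorphic-only input errors
  mono <- matrix(0L, 4, 3, dimnames = list(letters[1:4], c("1-1", "1-2", "1-3")))
  expect_error(grm_kinship(geno_matrix(mono, normalize = FALSE)),
               "monomorphic")
})

test_that("GRM and MoM converge to theoretical kinship on gene-dropped data", {
  spec <- sim_spec(n_pedigrees = 3L, generations = 3L, sibship = 3L)
  set.seed(31)
  ped <- sim_pedigree(spec)
  phi <- theoretical_kinship(ped)
  rmse <- function(K) sqrt(mean((K[rownames(phi), rownames(phi)] - phi)^2))
  errs <- sapply(c(1000L, 10000L), function(S) {
    g <- gene_drop(ped, runif(S, 0.1, 0.5))
    c(grm = rmse(grm_kinship(g)), mom = rmse(mom_kinship(g)))
  })
  expect_lt(errs["grm", 2L], errs["grm", 1L])   # decreasing RMSE
  expect_lt(errs["mom", 2L], errs["mom", 1L])
  expect_lt(errs["grm", 2L], 0.05)
})

test_that("within-pedigree scope zeroes cross-pedigree entries", {
  sim <- sim_study(sim_spec(n_pedigrees = 3L, n_snps = 500L), seed = 13)
  K <- grm_kinship(sim$geno, "within_pedigree", sim$pedigree)
  pid <- sim$pedigree$pedigree_id[match(rownames(K),
                                        sim$pedigree$person_id)]
  expect_true(all(K[outer(pid, pid, "!=")] == 0))
  expect_false(all(K[outer(pid, pid, "==")] == 0))
})

test_that("PSD projection clips negative eigenvalues only", {
  A <- matrix(c(1, 0.9, 0.9, 0.5), 2, 2)   # indefinite
  P <- psd_project(A)
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  B <- diag(2)
  expect_identical(psd_project(B), B)      # PSD input untouched
})

test_that("kinship TSV writer emits the lower triangle by ID", {
  phi <- theoretical_kinship(ped_nuclear(2L))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_kinship_tsv(phi, tmp)
  tab <- read.delim(tmp)
  expect_equal(nrow(tab), 4 * 5 / 2)
  expect_equal(tab$value[tab$id_i == "k1" & tab$id_j == "f"], 0.25)
})
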