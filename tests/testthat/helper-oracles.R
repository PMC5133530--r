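# Shared fixtures and independent oracles used across the suite.

# --- tiny pedigrees ------------------------------------------------------

ped_nuclear <- function(nkids = 2L) {
  kids <- paste0("k", seq_len(nkids))
  as_pedigree(data.frame(
    pedigree_id = "fam", person_id = c("f", "m", kids),
    father_id = c(NA, NA, rep("f", nkids)),
    mother_id = c(NA, NA, rep("m", nkids)),
    sex = c("male", "female", rep("unknown", nkids)),
    household_id = "h1"))
}

ped_half_sibs <- function() {
  as_pedigree(data.frame(
    pedigree_id = "fam", person_id = c("f", "m1", "m2", "k1", "k2"),
    father_id = c(NA, NA, NA, "f", "f"),
    mother_id = c(NA, NA, NA, "m1", "m2")))
}

# child of a full-sib mating (inbred)
ped_sib_mating <- function() {
  as_pedigree(data.frame(
    pedigree_id = "fam", person_id = c("f", "m", "s1", "s2", "c"),
    father_id = c(NA, NA, "f", "f", "s1"),
    mother_id = c(NA, NA, "m", "m", "s2"),
    sex = c("male", "female", "male", "female", "unknown")))
}

# double first cousins: two brothers marry two sisters
ped_double_first_cousins <- function() {
  as_pedigree(data.frame(
    pedigree_id = "fam",
    person_id = c("fA", "mA", "fB", "mB", "a1", "a2", "b1", "b2",
                  "c1", "c2"),
    father_id = c(NA, NA, NA, NA, "fA", "fA", "fB", "fB", "a1", "a2"),
    mother_id = c(NA, NA, NA, NA, "mA", "mA", "mB", "mB", "b1", "b2"),
    sex = c("male", "female", "male", "female", "male", "male",
            "female", "female", "unknown", "unknown")))
}

# --- gene-dropping Monte Carlo kinship oracle ----------------------------
# Drops nrep unlinked loci with uniquely labelled founder alleles and
# estimates phi(i, j) as the frequency with which a random allele from i
# is identical by descent with a random allele from j.
mc_kinship <- function(ped, id_i, id_j, nrep = 1e5) {
  n <- nrow(ped)
  fi <- match(ped$father_id, ped$person_id)
  mi <- match(ped$mother_id, ped$person_id)
  a1 <- matrix(0L, n, nrep); a2 <- matrix(0L, n, nrep)
  lab <- 0L
  for (r in seq_len(n)) {
    if (ped$founder[r]) {
      a1[r, ] <- lab + 1L; a2[r, ] <- lab + 2L; lab <- lab + 2L
    } else {
      sf <- stats::runif(nrep) < 0.5
      sm <- stats::runif(nrep) < 0.5
      a1[r, ] <- ifelse(sf, a1[fi[r], ], a2[fi[r], ])
      a2[r, ] <- ifelse(sm, a1[mi[r], ], a2[mi[r], ])
    }
  }
  i <- match(id_i, ped$person_id); j <- match(id_j, ped$person_id)
  ibd <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
         (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
  if (i == j) ibd <- 2L + 2L * (a1[i, ] == a2[i, ])
  phi <- ibd / 4
  list(est = mean(phi), se = stats::sd(phi) / sqrt(nrep))
}

# --- exact transmission-enumeration Delta7 oracle ------------------------
# Enumerates every combination of parental transmissions (2 choices per
# parent per non-founder) at one locus with uniquely labelled founder
# alleles and returns the exact probability that i's two alleles are IBD
# to j's two alleles pairwise.
enum_delta7 <- function(ped, id_i, id_j) {
  n <- nrow(ped)
  fi <- match(ped$father_id, ped$person_id)
  mi <- match(ped$mother_id, ped$person_id)
  nf <- which(!ped$founder)
  nchoice <- 4L^length(nf)
  stopifnot(nchoice <= 4^7)
  i <- match(id_i, ped$person_id); j <- match(id_j, ped$person_id)
  hits <- 0L
  for (code in seq_len(nchoice) - 1L) {
    a1 <- integer(n); a2 <- integer(n)
    lab <- 0L
    cc <- code
    for (r in seq_len(n)) {
      if (ped$founder[r]) {
        a1[r] <- lab + 1L; a2[r] <- lab + 2L; lab <- lab + 2L
      } else {
        pick <- cc %% 4L; cc <- cc %/% 4L
        a1[r] <- if (pick %% 2L == 0L) a1[fi[r]] else a2[fi[r]]
        a2[r] <- if (pick %/% 2L == 0L) a1[mi[r]] else a2[mi[r]]
      }
    }
    hit <- (a1[i] == a1[j] && a2[i] == a2[j]) ||
           (a1[i] == a2[j] && a2[i] == a1[j])
    hits <- hits + hit
  }
  hits / nchoice
}

# --- HWE exact-test oracle -----------------------------------------------
# Combinatorial counting with choose(): conditional probability of h
# heterozygotes among N individuals carrying n_minor minor alleles is
# proportional to N! / (n_AA! h! n_aa!) * 2^h; the p-value sums the
# normalized weights not exceeding the observed one (same tie tolerance
# as the implementation).
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  N <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)
  h <- seq(n_minor %% 2, n_minor, by = 2)
  h <- h[(n_minor - h) / 2 + h <= N]
  naa <- (n_minor - h) / 2
  w <- choose(N, h) * choose(N - h, naa) * 2^h
  prob <- w / sum(w)
  pobs <- prob[h == n_Aa]
  min(1, sum(prob[prob <= pobs * (1 + 1e-9)]))
}

# --- dense multivariate-normal log-density oracle ------------------------
# Eigen-decomposition whitening, independent of the Cholesky route used
# by the implementation.
oracle_mvn_logdens <- function(y, mu, S) {
  e <- eigen(S, symmetric = TRUE)
  z <- crossprod(e$vectors, y - mu) / sqrt(e$values)
  -0.5 * sum(log(e$values)) - 0.5 * sum(z^2) -
    0.5 * length(y) * log(2 * pi)
}

# assemble the dense covariance of vec(Y) (trait-major) for one pedigree
# from component matrices -- used only by oracle checks
oracle_sigma <- function(Sigma, K) {
  S <- 0
  for (cc in names(Sigma)) S <- S + kronecker(Sigma[[cc]], K[[cc]])
  S
}

expect_within_3se <- function(est, target, se) {
  testthat::expect_lt(abs(est - target), 3 * se + 1e-12)
}
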