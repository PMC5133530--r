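# Pedigree / genotype / trait simulator.
#
# Emulates the study conditions of a family GWAS: a set of extended
# pedigrees (non-inbred, nuclear-family households), independent
# gene-dropped SNPs, and multivariate traits drawn exactly from the
# variance-component covariance 2 Sigma_a x Phi + Sigma_d x Delta7 +
# Sigma_h x H + Sigma_e x I, with optional fixed-effect causal SNPs in the
# mean (matching how SNPs are tested) and missing-at-random masks.  One
# global random stream per seed, consumed pedigree -> genotypes -> traits.

#' Simulation specification
#'
#' Defaults describe a family study of 20 extended pedigrees over three
#' generations (sibships of 2-4, so pedigree sizes around 15-40 with
#' married-in founder spouses), 100 independent SNPs with allele
#' frequencies uniform on [0.05, 0.5], a single trait with additive
#' heritability 0.5 (\code{Sigma_a = Sigma_e = 1}) and age and sex
#' covariate effects of realistic blood-pressure scale, and no
#' missingness.  Every field can be overridden.
#'
#' @param n_pedigrees number of pedigrees.
#' @param generations generations per pedigree (>= 2).
#' @param sibship range (length-2) or single value for children per couple.
#' @param n_unrelated additional unrelated singleton individuals.
#' @param n_snps number of independent SNPs to gene-drop.
#' @param maf_range range for uniform allele frequencies, or use
#'   \code{mafs} for explicit per-SNP values.
#' @param mafs optional explicit per-SNP founder allele frequencies.
#' @param trait_names trait names; length sets T.
#' @param Sigma_a,Sigma_d,Sigma_h,Sigma_e T x T component matrices
#'   (\code{NULL} = component absent; \code{Sigma_e} required, PD).
#' @param beta mean coefficients: matrix with rownames among
#'   \code{c("(Intercept)", "age", "sex")} and one column per trait.
#' @param causal optional data frame with columns \code{snp} (SNP index or
#'   ID), \code{trait} (name or index), \code{beta}: fixed SNP effects
#'   added to the trait mean.
#' @param miss_trait,miss_cov,miss_geno missing-at-random rates.
#' @export
sim_spec <- function(n_pedigrees = 20L, generations = 3L, sibship = c(2L, 4L),
                     n_unrelated = 0L,
                     n_snps = 100L, maf_range = c(0.05, 0.5), mafs = NULL,
                     trait_names = "Y1",
                     Sigma_a = NULL, Sigma_d = NULL, Sigma_h = NULL,
                     Sigma_e = NULL,
                     beta = NULL, causal = NULL,
                     miss_trait = 0, miss_cov = 0, miss_geno = 0) {
  T_ <- length(trait_names)
  as_comp <- function(S) if (is.null(S)) NULL else {
    S <- as.matrix(S); stopifnot(nrow(S) == T_, ncol(S) == T_); S
  }
  if (is.null(Sigma_e)) Sigma_e <- diag(T_)
  if (is.null(Sigma_a) && is.null(Sigma_d) && is.null(Sigma_h))
    Sigma_a <- diag(T_)
  if (is.null(beta)) {
    beta <- matrix(c(100, 0.4, -2), 3L, T_,
                   dimnames = list(c("(Intercept)", "age", "sex"),
                                   trait_names))
  }
  stopifnot(generations >= 2L, all(rownames(beta) %in%
                                     c("(Intercept)", "age", "sex")))
  if (length(sibship) == 1L) sibship <- c(sibship, sibship)
  structure(list(n_pedigrees = n_pedigrees, generations = generations,
                 sibship = sibship, n_unrelated = n_unrelated,
                 n_snps = n_snps, maf_range = maf_range, mafs = mafs,
                 trait_names = trait_names, T = T_,
                 Sigma_a = as_comp(Sigma_a), Sigma_d = as_comp(Sigma_d),
                 Sigma_h = as_comp(Sigma_h), Sigma_e = as_comp(Sigma_e),
                 beta = beta, causal = causal,
                 miss_trait = miss_trait, miss_cov = miss_cov,
                 miss_geno = miss_geno),
            class = "sim_spec")
}

#' Simulate pedigrees
#'
#' Each pedigree starts from a founder couple; every child in a
#' non-terminal generation marries a new (unrelated) founder and the
#' couple has a sibship of children, so no pedigree is inbred.  Each
#' couple and its children form one household; terminal-generation
#' children stay in their parents' household.  Unrelated singletons (if
#' requested) are founders in their own one-person pedigrees/households.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return a \code{pedigree}.
#' @export
sim_pedigree <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  add <- function(ped, id, f, m, sex, hh)
    rows[[length(rows) + 1L]] <<- data.frame(
      pedigree_id = ped, person_id = id, father_id = f, mother_id = m,
      sex = sex, household_id = hh, stringsAsFactors = FALSE)
  for (pd in seq_len(spec$n_pedigrees)) {
    pname <- sprintf("ped%02d", pd)
    cnt <- 0L
    nid <- function() { cnt <<- cnt + 1L; sprintf("%s_i%03d", pname, cnt) }
    hhn <- 0L
    newhh <- function() { hhn <<- hhn + 1L; sprintf("%s_h%02d", pname, hhn) }
    f0 <- nid(); m0 <- nid(); hh0 <- newhh()
    add(pname, f0, NA, NA, "male", hh0)
    add(pname, m0, NA, NA, "female", hh0)
    couples <- list(list(f = f0, m = m0, hh = hh0))
    for (g in 2:spec$generations) {
      nxt <- list()
      for (cp in couples) {
        k <- spec$sibship[1L] +
          sample.int(spec$sibship[2L] - spec$sibship[1L] + 1L, 1L) - 1L
        for (ch in seq_len(k)) {
          sex <- sample(c("male", "female"), 1L)
          cid <- nid()
          add(pname, cid, cp$f, cp$m, sex, cp$hh)
          if (g < spec$generations) {
            sid <- nid()
            hh <- newhh()
            add(pname, sid, NA, NA,
                if (sex == "male") "female" else "male", hh)
            # child moves to the new nuclear household
            rows[[length(rows) - 1L]]$household_id <- hh
            nxt[[length(nxt) + 1L]] <-
              if (sex == "male") list(f = cid, m = sid, hh = hh)
              else list(f = sid, m = cid, hh = hh)
          }
        }
      }
      couples <- nxt
    }
  }
  for (u in seq_len(spec$n_unrelated)) {
    id <- sprintf("unrel_%04d", u)
    rows[[length(rows) + 1L]] <- data.frame(
      pedigree_id = id, person_id = id, father_id = NA_character_,
      mother_id = NA_character_, sex = sample(c("male", "female"), 1L),
      household_id = id, stringsAsFactors = FALSE)
  }
  as_pedigree(do.call(rbind, rows))
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder alleles are i.i.d. Bernoulli(maf); each child inherits one
#' uniformly chosen allele per parent per locus, independently across
#' loci.  Dosages count the simulated minor allele (no re-orientation).
#'
#' @param ped a \code{pedigree}.
#' @param mafs per-SNP founder allele frequencies in (0, 1/2].
#' @param seed optional seed.
#' @param chrom chromosome label used in SNP IDs ("chr-bp" convention).
#' @return a \code{\link{geno_matrix}} (plus attribute \code{"haplotypes"}
#'   carrying the two allele matrices, used by IBD checks).
#' @export
gene_drop <- function(ped, mafs, seed = NULL, chrom = "1") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ped, "pedigree"), all(mafs > 0), all(mafs <= 0.5))
  n <- nrow(ped); S <- length(mafs)
  a1 <- matrix(0L, n, S); a2 <- matrix(0L, n, S)
  fi <- match(ped$father_id, ped$person_id)
  mi <- match(ped$mother_id, ped$person_id)
  for (i in seq_len(n)) {
    if (ped$founder[i]) {
      a1[i, ] <- stats::rbinom(S, 1L, mafs)
      a2[i, ] <- stats::rbinom(S, 1L, mafs)
    } else {
      sf <- stats::runif(S) < 0.5
      sm <- stats::runif(S) < 0.5
      a1[i, ] <- ifelse(sf, a1[fi[i], ], a2[fi[i], ])
      a2[i, ] <- ifelse(sm, a1[mi[i], ], a2[mi[i], ])
    }
  }
  d <- a1 + a2
  dimnames(d) <- list(ped$person_id,
                      paste0(chrom, "-", seq_len(S)))
  g <- geno_matrix(d, normalize = FALSE)
  attr(g, "haplotypes") <- list(a1 = a1, a2 = a2)
  g
}

#' Simulate multivariate traits from the variance-component model
#'
#' Generates age (Normal(50, 12)) and sex (0/1, from the pedigree)
#' covariates, forms the mean \code{A beta} plus any causal-SNP fixed
#' effects, and adds a polygenic/dominance/household/environmental draw
#' with covariance assembled exactly as the model defines, pedigree block
#' by pedigree block (trait-major ordering).  Missing-at-random masks are
#' applied last.
#'
#' @param ped a \code{pedigree}.
#' @param geno a \code{geno_matrix} (needed only when \code{spec$causal}
#'   is set).
#' @param spec a \code{\link{sim_spec}}.
#' @param seed optional seed.
#' @return a \code{\link{trait_table}} with covariates \code{age},
#'   \code{sex}.
#' @export
sim_traits <- function(ped, geno = NULL, spec = sim_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped); T_ <- spec$T
  age <- stats::rnorm(n, 50, 12)
  sex <- as.integer(ped$sex == "male")
  X <- cbind(`(Intercept)` = 1, age = age, sex = sex)
  mu <- X[, rownames(spec$beta), drop = FALSE] %*% spec$beta  # n x T

  if (!is.null(spec$causal)) {
    if (is.null(geno)) stop("causal SNP effects need genotypes")
    for (r in seq_len(nrow(spec$causal))) {
      s <- spec$causal$snp[r]
      sid <- if (is.numeric(s)) colnames(geno$dosage)[s] else as.character(s)
      tr <- spec$causal$trait[r]
      ti <- if (is.numeric(tr)) tr else match(as.character(tr),
                                              spec$trait_names)
      x <- geno$dosage[ped$person_id, sid]
      x[is.na(x)] <- 2 * mean(x, na.rm = TRUE) / 2
      mu[, ti] <- mu[, ti] + spec$causal$beta[r] * x
    }
  }

  comps <- list()
  if (!is.null(spec$Sigma_a)) comps$additive <- 2 * theoretical_kinship(ped)
  if (!is.null(spec$Sigma_d)) comps$dominance <- delta7_matrix(ped)
  if (!is.null(spec$Sigma_h)) comps$household <- household_matrix(ped)
  Sg <- list(additive = spec$Sigma_a, dominance = spec$Sigma_d,
             household = spec$Sigma_h, environmental = spec$Sigma_e)

  Y <- matrix(NA_real_, n, T_, dimnames = list(ped$person_id,
                                               spec$trait_names))
  for (pid in unique(ped$pedigree_id)) {
    idx <- which(ped$pedigree_id == pid)
    n_p <- length(idx)
    S <- kronecker(Sg$environmental, diag(n_p))
    for (cc in names(comps))
      S <- S + kronecker(Sg[[cc]], comps[[cc]][idx, idx, drop = FALSE])
    ev <- eigen(S, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(ev$values))
      stop("simulation covariance not PSD in pedigree ", pid)
    A <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
    g <- drop(A %*% stats::rnorm(n_p * T_))
    Y[idx, ] <- mu[idx, ] + matrix(g, n_p, T_)   # trait-major unstack
  }

  if (spec$miss_trait > 0)
    Y[matrix(stats::runif(n * T_) < spec$miss_trait, n, T_)] <- NA
  covars <- cbind(age = age, sex = sex)
  rownames(covars) <- ped$person_id
  if (spec$miss_cov > 0)
    covars[matrix(stats::runif(n * 2L) < spec$miss_cov, n, 2L)] <- NA
  trait_table(Y, covars)
}

#' Simulate a complete study
#'
#' Runs \code{\link{sim_pedigree}}, \code{\link{gene_drop}} and
#' \code{\link{sim_traits}} in that documented order on a single random
#' stream seeded once, and applies genotype missingness.
#'
#' @param spec a \code{\link{sim_spec}}.
#' @param seed integer seed; fully determines the study.
#' @return list with \code{pedigree}, \code{geno}, \code{traits},
#'   \code{mafs}, \code{spec}.
#' @export
sim_study <- function(spec = sim_spec(), seed = 1L) {
  set.seed(seed)
  ped <- sim_pedigree(spec)
  mafs <- if (!is.null(spec$mafs)) spec$mafs else
    stats::runif(spec$n_snps, spec$maf_range[1L], spec$maf_range[2L])
  geno <- gene_drop(ped, mafs)
  if (spec$miss_geno > 0) {
    d <- geno$dosage
    d[matrix(stats::runif(length(d)) < spec$miss_geno, nrow(d))] <- NA
    geno <- geno_matrix(d, geno$map, normalize = FALSE)
  }
  traits <- sim_traits(ped, geno, spec)
  list(pedigree = ped, geno = geno, traits = traits, mafs = mafs,
       spec = spec)
}

#' Data frame view of a simulated study for model fitting
#'
#' Binds IDs, traits and covariates into the data frame layout
#' \code{\link{pedvc}} expects.
#'
#' @param sim output of \code{\link{sim_study}} (or any list with a
#'   \code{traits} trait_table).
#' @export
sim_data_frame <- function(sim) {
  tt <- if (inherits(sim, "trait_table")) sim else sim$traits
  df <- data.frame(person_id = tt$ids, tt$traits, check.names = FALSE)
  if (!is.null(tt$covariates))
    df <- cbind(df, as.data.frame(tt$covariates))
  df
}
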