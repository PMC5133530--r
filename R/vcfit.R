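# Fitting the multivariate variance-component model by maximum likelihood.
#
# Per pedigree, vec(Y) ~ N(A beta, Sigma) with
#   Sigma = 2 Sigma_a x Phi + Sigma_d x Delta7 + Sigma_h x H + Sigma_e x I
# (x = Kronecker product, trait-major ordering, missing trait entries
# marginalized out by row/column deletion).  beta is profiled out by
# generalized least squares at each variance iterate; the T x T component
# matrices are parametrized through Cholesky factors so the search stays
# in the PSD cone.  The ln(2 pi) constant is included in the reported
# loglikelihood.

VC_COMPONENTS <- c("additive", "dominance", "household", "environmental")

# structure matrices per component over the analyzed individuals,
# as per-pedigree block lists aligned with design$blocks
vc_structures <- function(design, pedigree, components, kinship,
                          genotypes = NULL) {
  stopifnot(all(components %in% VC_COMPONENTS))
  if (!"environmental" %in% components)
    stop("the environmental component is always active")
  ids <- design$ids
  glob <- list()
  if ("additive" %in% components) {
    K <- if (is.matrix(kinship)) {
      if (!all(ids %in% rownames(kinship)))
        stop("kinship matrix does not cover all analyzed individuals")
      kinship[ids, ids]
    } else switch(match.arg(kinship, c("theoretical", "grm", "grm_within", "mom")),
      theoretical = theoretical_kinship(pedigree)[ids, ids],
      grm = psd_project(grm_kinship(genotypes, "global"))[ids, ids],
      grm_within = psd_project(
        grm_kinship(genotypes, "within_pedigree", pedigree))[ids, ids],
      mom = psd_project(mom_kinship(genotypes, "global"))[ids, ids])
    glob$additive <- 2 * K
  }
  if ("dominance" %in% components)
    glob$dominance <- delta7_matrix(pedigree)[ids, ids]
  if ("household" %in% components)
    glob$household <- household_matrix(pedigree)[ids, ids]
  glob$environmental <- diag(length(ids))
  dimnames(glob$environmental) <- list(ids, ids)

  lapply(glob, function(K) lapply(design$blocks, function(b)
    K[b$ids, b$ids, drop = FALSE]))
}

# Sigma for one pedigree block at given component matrices, observed rows only
sigma_block <- function(block, Kb_block, Sigma) {
  n_p <- block$n
  S <- 0
  for (comp in names(Sigma))
    S <- S + kronecker(Sigma[[comp]], Kb_block[[comp]])
  S[block$obs, block$obs, drop = FALSE]
}

#' Evaluate the model loglikelihood at given parameters
#'
#' Sums, over pedigrees, the multivariate-normal log-density of the
#' observed trait entries under mean \code{A beta} and covariance
#' assembled from the component matrices; includes the
#' \eqn{-(m/2)\ln 2\pi} constant.
#'
#' @param design a \code{\link{vc_design}}.
#' @param structures per-pedigree structure matrices from the fit (or
#'   built internally by \code{\link{pedvc}}).
#' @param beta coefficient vector in design order.
#' @param Sigma named list of T x T component matrices (subset of
#'   additive/dominance/household/environmental).
#' @param by_pedigree return the per-pedigree contributions.
#' @return total loglikelihood (or vector of per-pedigree contributions).
#' @export
vc_loglik <- function(design, structures, beta, Sigma, by_pedigree = FALSE) {
  Kb <- restructure_blocks(structures, design)
  ll <- vapply(seq_along(design$blocks), function(i) {
    b <- design$blocks[[i]]
    S <- sigma_block(b, Kb[[i]], Sigma)
    R <- tryCatch(chol(S), error = function(e)
      stop("covariance not positive definite in pedigree block ", i))
    r <- b$y - drop(b$A %*% beta)
    z <- backsolve(R, r, transpose = TRUE)
    -sum(log(diag(R))) - 0.5 * sum(z^2) - 0.5 * length(r) * log(2 * pi)
  }, 0)
  if (by_pedigree) ll else sum(ll)
}

# structures is comp -> list over blocks; regroup as block -> comp
restructure_blocks <- function(structures, design) {
  lapply(seq_along(design$blocks), function(i)
    lapply(structures, `[[`, i))
}

# --- Cholesky parametrization of the component matrices ------------------
nvech <- function(T_) T_ * (T_ + 1L) / 2L

chol_to_mat <- function(theta, T_) {
  L <- matrix(0, T_, T_)
  L[lower.tri(L, diag = TRUE)] <- theta
  tcrossprod(L)
}

mat_to_chol <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  S <- e$vectors %*% (pmax(e$values, 1e-8 * max(e$values, 1e-8)) *
                        t(e$vectors))
  L <- t(chol(S))
  L[lower.tri(L, diag = TRUE)]
}

theta_split <- function(theta, components, T_) {
  q <- nvech(T_)
  out <- list()
  for (i in seq_along(components))
    out[[components[i]]] <- chol_to_mat(theta[(i - 1L) * q + seq_len(q)], T_)
  out
}

# profile negative loglikelihood: beta by GLS given variance parameters
vc_profile <- function(theta, design, Kb, components, want = "nll") {
  T_ <- design$T
  Sigma <- theta_split(theta, components, T_)
  k <- length(design$coef_names)
  M <- matrix(0, k, k); v <- numeric(k)
  pieces <- vector("list", length(design$blocks))
  for (i in seq_along(design$blocks)) {
    b <- design$blocks[[i]]
    S <- sigma_block(b, Kb[[i]], Sigma)
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) return(if (want == "nll") 1e10 else NULL)
    WA <- backsolve(R, b$A, transpose = TRUE)   # R^-T A
    wy <- backsolve(R, b$y, transpose = TRUE)
    M <- M + crossprod(WA)
    v <- v + crossprod(WA, wy)
    pieces[[i]] <- list(R = R, WA = WA, wy = wy)
  }
  Mi <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(Mi)) return(if (want == "nll") 1e10 else NULL)
  beta <- drop(Mi %*% v)
  ll <- 0; llp <- numeric(length(pieces))
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    z <- p$wy - p$WA %*% beta
    llp[i] <- -sum(log(diag(p$R))) - 0.5 * sum(z^2) -
      0.5 * length(p$wy) * log(2 * pi)
  }
  ll <- sum(llp)
  if (want == "nll") return(-ll)
  list(nll = -ll, beta = beta, Sigma = Sigma, Minv = Mi, llp = llp,
       pieces = pieces)
}

default_control <- function(control) {
  ctl <- list(maxit = 1000L, reltol = 1e-12, rel_ll_tol = 1e-8,
              par_tol = 1e-6, max_restarts = 5L)
  ctl[names(control)] <- control
  ctl
}

#' Fit a multivariate variance-component model on pedigrees
#'
#' Maximum-likelihood fit of the null (no-SNP) trait model
#' \deqn{vec(Y) \sim N(A\beta,\;
#'   2\Sigma_a\otimes\Phi + \Sigma_d\otimes\Delta_7 +
#'   \Sigma_h\otimes H + \Sigma_e\otimes I)}
#' per pedigree.  Mean coefficients are profiled out by generalized least
#' squares at each variance iterate; the component matrices are searched
#' over their Cholesky factors (quasi-Newton with line search, so the
#' profile likelihood never decreases along accepted steps), with
#' convergence declared when a restart improves the loglikelihood by less
#' than a relative 1e-8 and moves no parameter by more than 1e-6.
#' Individuals with a missing covariate are dropped (and logged in
#' \code{$dropped}); missing trait entries are marginalized out exactly.
#'
#' @inheritParams vc_design
#' @param components variance components to fit; \code{"environmental"} is
#'   always active.  Any subset of \code{c("additive", "dominance",
#'   "household", "environmental")}.
#' @param kinship \code{"theoretical"} (pedigree-derived), \code{"grm"},
#'   \code{"grm_within"}, \code{"mom"} (SNP-based, need \code{genotypes};
#'   projected to the PSD cone), or an explicit kinship-scale matrix with
#'   ID dimnames.
#' @param genotypes a \code{\link{geno_matrix}}, required for SNP-based
#'   kinship.
#' @param control list: \code{maxit}, \code{rel_ll_tol} (1e-8),
#'   \code{par_tol} (1e-6), \code{max_restarts}.
#' @return an object of class \code{"pedvc"}; see
#'   \code{\link{summary.pedvc}}, \code{\link{score_test}},
#'   \code{\link{gwas_scan}}.
#' @examples
#' set.seed(1)
#' sim <- sim_study(sim_spec(n_pedigrees = 6, n_snps = 20), seed = 1)
#' df <- data.frame(person_id = sim$traits$ids, sim$traits$traits,
#'                  sim$traits$covariates, check.names = FALSE)
#' fit <- pedvc(Y1 ~ age, df, sim$pedigree)
#' fit
#' @export
pedvc <- function(formula, data, pedigree,
                  components = c("additive", "environmental"),
                  kinship = "theoretical", genotypes = NULL,
                  constraints = NULL, trait_groups = NULL,
                  control = list()) {
  cl <- match.call()
  components <- union(components, "environmental")
  components <- VC_COMPONENTS[VC_COMPONENTS %in% components]
  ctl <- default_control(control)

  design <- vc_design(formula, data, pedigree, constraints, trait_groups)
  structures <- vc_structures(design, pedigree, components, kinship,
                              genotypes)
  Kb <- restructure_blocks(structures, design)
  T_ <- design$T

  identifiable <- TRUE
  if ("additive" %in% components) {
    dev <- max(vapply(structures$additive, function(K)
      max(abs(K - diag(nrow(K)))), 0))
    if (dev < 1e-8) {
      identifiable <- FALSE
      warning("additive structure equals the identity in every pedigree ",
              "(unrelated individuals): additive and environmental ",
              "components are confounded")
    }
  }

  # initialization: Sigma_e from per-trait OLS residual covariance,
  # Sigma_a = Sigma_e / 2, others a small multiple of the identity
  Sigma0 <- init_components(design, components)
  theta <- unlist(lapply(components, function(cc) mat_to_chol(Sigma0[[cc]])),
                  use.names = FALSE)

  nll <- function(th) vc_profile(th, design, Kb, components, "nll")
  opt <- optimize_nll(theta, nll, ctl)
  iters <- opt$iters
  converged <- opt$converged

  sol <- vc_profile(opt$par, design, Kb, components, "full")
  if (is.null(sol)) stop("variance-component fit failed: covariance not PD ",
                         "at the reported optimum")
  beta <- sol$beta; names(beta) <- design$coef_names
  Sigma <- sol$Sigma

  scale_e <- mean(diag(Sigma$environmental))
  boundary <- names(Sigma)[vapply(Sigma, function(S)
    max(abs(S)) < 1e-6 * max(scale_e, 1e-12), TRUE)]

  # per-pedigree caches for score tests and diagnostics
  blocks <- vector("list", length(design$blocks))
  for (i in seq_along(design$blocks)) {
    b <- design$blocks[[i]]
    p <- sol$pieces[[i]]
    r <- b$y - drop(b$A %*% beta)
    Sinv_r <- backsolve(p$R, backsolve(p$R, r, transpose = TRUE))
    Sinv_A <- backsolve(p$R, p$WA)
    blocks[[i]] <- list(ids = b$ids, n = b$n, obs = b$obs,
                        obs_map = b$obs_map, y = b$y, A = b$A,
                        R = p$R, resid = r, Sinv_r = Sinv_r,
                        Sinv_A = Sinv_A)
  }

  structure(list(call = cl, formula = design$formula,
                 traits = design$traits, T = T_,
                 coefficients = beta, Sigma = Sigma,
                 components = components,
                 logLik = -sol$nll, logLik_by_pedigree = sol$llp,
                 design = design, structures = structures,
                 blocks = blocks, Minv = sol$Minv,
                 theta = opt$par,
                 converged = converged, iterations = iters,
                 boundary = boundary, identifiable = identifiable,
                 kinship = if (is.matrix(kinship)) "matrix" else kinship,
                 pedigree = pedigree,
                 dropped = design$dropped,
                 n = length(design$ids),
                 n_obs = sum(vapply(design$blocks,
                                    function(b) length(b$y), 0L))),
            class = "pedvc")
}

# BFGS with restarts (convergence = relative-L and parameter stability
# between restarts), then an L-BFGS-B polish at machine-level factr for
# high-precision estimates
optimize_nll <- function(theta, nll, ctl) {
  opt <- stats::optim(theta, nll, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  iters <- opt$counts[["function"]]
  converged <- FALSE
  for (r in seq_len(ctl$max_restarts)) {
    opt2 <- stats::optim(opt$par, nll, method = "BFGS",
                         control = list(maxit = ctl$maxit,
                                        reltol = ctl$reltol))
    iters <- iters + opt2$counts[["function"]]
    rel <- abs(opt$value - opt2$value) / max(1, abs(opt$value))
    dpar <- max(abs(opt$par - opt2$par))
    if (opt2$value <= opt$value) opt <- opt2
    if (rel < ctl$rel_ll_tol && dpar < ctl$par_tol) {
      converged <- TRUE; break
    }
  }
  polish <- tryCatch(
    stats::optim(opt$par, nll, method = "L-BFGS-B",
                 control = list(maxit = ctl$maxit, factr = 10,
                                ndeps = rep(1e-6, length(opt$par)))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= opt$value) {
    iters <- iters + polish$counts[["function"]]
    opt <- polish
  }
  list(par = opt$par, value = opt$value, iters = iters,
       converged = converged)
}

init_components <- function(design, components) {
  T_ <- design$T
  # per-trait OLS on the per-trait rows of the stacked design
  res <- matrix(NA_real_, length(design$ids), T_)
  rownames(res) <- design$ids
  for (b in design$blocks) {
    A <- b$A; y <- b$y; m <- b$obs_map
    for (t in seq_len(T_)) {
      sel <- m$trait == t
      if (!any(sel)) next
      At <- A[sel, , drop = FALSE]
      use <- colSums(At != 0) > 0
      cf <- tryCatch(stats::lm.fit(At[, use, drop = FALSE], y[sel])$residuals,
                     error = function(e) y[sel] - mean(y[sel]))
      res[b$ids[m$ind[sel]], t] <- cf
    }
  }
  Se <- stats::cov(res, use = "pairwise.complete.obs")
  Se[is.na(Se)] <- 0
  diag(Se)[diag(Se) <= 0 | is.na(diag(Se))] <- 1
  e <- eigen(Se, symmetric = TRUE)
  Se <- e$vectors %*% (pmax(e$values, 0.05 * mean(diag(Se))) * t(e$vectors))
  out <- list()
  for (cc in components)
    out[[cc]] <- switch(cc,
      environmental = Se,
      additive = Se / 2,
      0.05 * mean(diag(Se)) * diag(T_))
  out
}
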