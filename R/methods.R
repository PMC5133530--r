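# S3 methods for fitted variance-component models.

#' @export
print.pedvc <- function(x, digits = 4L, ...) {
  cat("Multivariate variance-component model (ML)\n")
  cat("  traits:", paste(x$traits, collapse = ", "),
      " individuals:", x$n,
      " pedigrees:", length(x$blocks), "\n")
  cat("  components:", paste(x$components, collapse = ", "),
      " kinship:", x$kinship, "\n")
  cat("  loglikelihood:", format(x$logLik, digits = 10), "\n")
  if (!x$converged) cat("  WARNING: convergence criterion not met\n")
  if (length(x$boundary))
    cat("  boundary component(s):", paste(x$boundary, collapse = ", "), "\n")
  if (!x$identifiable)
    cat("  WARNING: additive/environmental components not identifiable\n")
  cat("\nMean coefficients:\n")
  print(round(x$coefficients, digits))
  for (cc in x$components) {
    cat("\nSigma_", substr(cc, 1, 1), " (", cc, "):\n", sep = "")
    print(round(x$Sigma[[cc]], digits))
  }
  invisible(x)
}

#' @export
coef.pedvc <- function(object, ...) object$coefficients

#' @export
logLik.pedvc <- function(object, ...) {
  p <- length(object$coefficients) +
    length(object$components) * nvech(object$T)
  structure(object$logLik, df = p, nobs = object$n_obs, class = "logLik")
}

#' @export
vcov.pedvc <- function(object, ...) {
  V <- object$Minv
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  V
}

#' @export
fitted.pedvc <- function(object, ...) {
  out <- matrix(NA_real_, object$n, object$T,
                dimnames = list(object$design$ids, object$traits))
  for (b in object$blocks) {
    mu <- drop(b$A %*% object$coefficients)
    out[cbind(match(b$ids[b$obs_map$ind], rownames(out)), b$obs_map$trait)] <- mu
  }
  out
}

#' @export
residuals.pedvc <- function(object, ...) {
  out <- matrix(NA_real_, object$n, object$T,
                dimnames = list(object$design$ids, object$traits))
  for (b in object$blocks)
    out[cbind(match(b$ids[b$obs_map$ind], rownames(out)), b$obs_map$trait)] <-
      b$resid
  out
}

#' Simulate trait data from a fitted model
#'
#' Draws new observed-trait vectors from the fitted multivariate normal,
#' pedigree block by pedigree block, at the observed positions (missing
#' entries stay missing).
#'
#' @param object a \code{pedvc} fit.
#' @param nsim number of replicates.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list of \code{n x T} trait matrices.
#' @export
simulate.pedvc <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    Y <- matrix(NA_real_, object$n, object$T,
                dimnames = list(object$design$ids, object$traits))
    for (b in object$blocks) {
      mu <- drop(b$A %*% object$coefficients)
      y <- mu + drop(crossprod(b$R, stats::rnorm(length(mu))))
      Y[cbind(match(b$ids[b$obs_map$ind], rownames(Y)), b$obs_map$trait)] <- y
    }
    out[[s]] <- Y
  }
  out
}

# observed information over (beta, vech of each active component) by
# central finite differences of the full loglikelihood
vc_information <- function(fit, h_rel = 1e-4) {
  design <- fit$design; T_ <- fit$T
  comps <- fit$components
  vech_idx <- which(lower.tri(diag(T_), diag = TRUE), arr.ind = TRUE)
  par <- c(fit$coefficients,
           unlist(lapply(comps, function(cc) fit$Sigma[[cc]][vech_idx])))
  vech_names <- apply(vech_idx, 1L, function(r)
    paste0("[", r[1L], ",", r[2L], "]"))
  names(par) <- c(names(fit$coefficients),
                  unlist(lapply(comps, function(cc) paste0(cc, vech_names))))
  k <- length(fit$coefficients)
  q <- nrow(vech_idx)

  par_to_args <- function(p) {
    beta <- p[seq_len(k)]
    Sigma <- list()
    for (i in seq_along(comps)) {
      v <- p[k + (i - 1L) * q + seq_len(q)]
      S <- matrix(0, T_, T_)
      S[vech_idx] <- v
      S[vech_idx[, c(2L, 1L), drop = FALSE]] <- v
      Sigma[[comps[i]]] <- S
    }
    list(beta = beta, Sigma = Sigma)
  }
  f <- function(p) {
    a <- par_to_args(p)
    tryCatch(vc_loglik(design, fit$structures, a$beta, a$Sigma),
             error = function(e) NA_real_)
  }
  np <- length(par)
  h <- pmax(h_rel, h_rel * abs(par))
  H <- matrix(NA_real_, np, np, dimnames = list(names(par), names(par)))
  f0 <- f(par)
  for (i in seq_len(np)) {
    ei <- numeric(np); ei[i] <- h[i]
    H[i, i] <- (f(par + ei) - 2 * f0 + f(par - ei)) / h[i]^2
    for (j in seq_len(i - 1L)) {
      ej <- numeric(np); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(par + ei + ej) - f(par + ei - ej) -
         f(par - ei + ej) + f(par - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  info <- -H
  V <- tryCatch(solve(info), error = function(e)
    matrix(NA_real_, np, np, dimnames = dimnames(info)))
  se <- suppressWarnings(sqrt(diag(V)))
  list(par = par, se = se, vcov = V, info = info)
}

#' Summarize a fitted variance-component model
#'
#' Reports mean coefficients with GLS standard errors and z-tests, the
#' estimated component matrices with observed-information standard errors
#' (finite-difference Hessian of the full loglikelihood), and fit
#' diagnostics.
#'
#' @param object a \code{pedvc} fit.
#' @param information compute observed-information SEs for the variance
#'   components (can be slow for many parameters); default TRUE.
#' @param ... unused.
#' @export
summary.pedvc <- function(object, information = TRUE, ...) {
  se_beta <- sqrt(diag(object$Minv))
  z <- object$coefficients / se_beta
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se_beta,
                 `z value` = z,
                 `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  info <- if (information) vc_information(object) else NULL
  structure(list(fit = object, coefficients = coefs, information = info),
            class = "summary.pedvc")
}

#' @export
print.summary.pedvc <- function(x, digits = 4L, ...) {
  print(x$fit, digits = digits)
  cat("\nMean coefficients (GLS standard errors):\n")
  stats::printCoefmat(x$coefficients, digits = digits)
  if (!is.null(x$information)) {
    k <- length(x$fit$coefficients)
    vpar <- x$information$par[-seq_len(k)]
    vse <- x$information$se[-seq_len(k)]
    cat("\nVariance components (observed-information SEs):\n")
    print(round(cbind(Estimate = vpar, `Std. Error` = vse), digits))
  }
  invisible(x)
}

#' Asymptotic confidence intervals for model parameters
#'
#' Wald intervals from the observed information (finite-difference
#' Hessian of the full loglikelihood) for the mean coefficients and the
#' entries of the variance-component matrices.  Variance diagonals get
#' log-scale intervals (\code{est * exp(+/- z * se / est)}), the standard
#' construction for right-skewed variance estimators; covariances and
#' mean coefficients get symmetric intervals.
#'
#' @param object a \code{pedvc} fit.
#' @param parm ignored (all parameters are returned).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with columns \code{estimate}, \code{lower}, \code{upper}.
#' @export
confint.pedvc <- function(object, parm = NULL, level = 0.95, ...) {
  info <- vc_information(object)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- info$par; se <- info$se
  lo <- est - z * se; hi <- est + z * se
  is_var_diag <- grepl("\\[([0-9]+),\\1\\]$", names(est)) & est > 0
  lo[is_var_diag] <- est[is_var_diag] *
    exp(-z * se[is_var_diag] / est[is_var_diag])
  hi[is_var_diag] <- est[is_var_diag] *
    exp(z * se[is_var_diag] / est[is_var_diag])
  cbind(estimate = est, lower = lo, upper = hi)
}

#' Outlier report for pedigrees and individuals
#'
#' Per pedigree, the Mahalanobis statistic \eqn{r^t \hat\Sigma^{-1} r} of
#' the observed residual vector with its observation count m and upper-tail
#' chi-square(m) probability; per observation, the standardized conditional
#' residual given all other observations in the pedigree (from the
#' precision matrix).  Both tables are sorted most-improbable first.
#'
#' @param fit a converged \code{pedvc} fit.
#' @return list with data frames \code{pedigrees} (pedigree_id, statistic,
#'   m, p) and \code{individuals} (person_id, trait, std_resid, p).
#' @export
pedigree_outlier_report <- function(fit) {
  stopifnot(inherits(fit, "pedvc"))
  ped_ids <- vapply(fit$blocks, function(b)
    fit$pedigree$pedigree_id[match(b$ids[1L], fit$pedigree$person_id)], "")
  stat <- vapply(fit$blocks, function(b) drop(crossprod(b$resid, b$Sinv_r)), 0)
  m <- vapply(fit$blocks, function(b) length(b$y), 0L)
  peds <- data.frame(pedigree_id = ped_ids, statistic = stat, m = m,
                     p = stats::pchisq(stat, m, lower.tail = FALSE))
  peds <- peds[order(peds$p), ]; rownames(peds) <- NULL

  ind <- do.call(rbind, lapply(fit$blocks, function(b) {
    Q <- chol2inv(b$R)                 # precision matrix
    z <- drop(Q %*% b$resid) / sqrt(diag(Q))
    data.frame(person_id = b$ids[b$obs_map$ind],
               trait = fit$traits[b$obs_map$trait],
               std_resid = z, stringsAsFactors = FALSE)
  }))
  ind$p <- 2 * stats::pnorm(-abs(ind$std_resid))
  ind <- ind[order(ind$p), ]; rownames(ind) <- NULL
  list(pedigrees = peds, individuals = ind)
}
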