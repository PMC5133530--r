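#' Structure matrices for the variance-component model
#'
#' Each covariance component of the trait model acts through an
#' \code{n x n} symmetric structure matrix over individuals: the additive
#' polygenic component through twice the kinship matrix (theoretical or
#' SNP-estimated), the dominance component through the condensed identity
#' coefficient matrix Delta7, the shared-environment component through the
#' household indicator matrix, and the residual through the identity.
#' Structure matrices here are plain symmetric matrices with individual IDs
#' as dimnames and a \code{"kind"} attribute.
#'
#' @name structure-matrices
NULL

new_structure_matrix <- function(values, ids, kind) {
  dimnames(values) <- list(ids, ids)
  attr(values, "kind") <- kind
  values
}

#' Theoretical kinship matrix from pedigree structure
#'
#' Recursive computation in topological order.  Founders are taken
#' non-inbred and mutually unrelated: phi(i,i) = 1/2 and phi between
#' distinct founders is 0.  For a child k of parents (f, m):
#' phi(k,k) = (1 + phi(f,m)) / 2 and phi(k,j) = (phi(f,j) + phi(m,j)) / 2
#' for any j processed before k.  Values are exact rationals up to
#' floating-point representation.
#'
#' @param ped a \code{\link{as_pedigree}} object.
#' @return symmetric matrix of kinship coefficients, diagonal >= 1/2.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   pedigree_id = 1, person_id = c("f", "m", "c1", "c2"),
#'   father_id = c(NA, NA, "f", "f"), mother_id = c(NA, NA, "m", "m")))
#' phi <- theoretical_kinship(ped)
#' phi["c1", "c2"]  # full siblings: 1/4
#' @export
theoretical_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  phi <- matrix(0, n, n)
  id <- ped$person_id
  fi <- match(ped$father_id, id)
  mi <- match(ped$mother_id, id)
  # rows are parents-before-children within pedigree blocks; cross-pedigree
  # kinship is 0 so a single pass over all rows is valid.
  for (k in seq_len(n)) {
    if (ped$founder[k]) {
      phi[k, k] <- 0.5
    } else {
      f <- fi[k]; m <- mi[k]
      phi[k, k] <- 0.5 * (1 + phi[f, m])
      prev <- seq_len(k - 1L)
      v <- 0.5 * (phi[f, prev] + phi[m, prev])
      phi[k, prev] <- v
      phi[prev, k] <- v
    }
  }
  new_structure_matrix(phi, id, "theoretical_kinship")
}

#' Condensed identity coefficient matrix Delta7 (dominance)
#'
#' For non-inbred individuals i (parents a, b) and j (parents c, d),
#' Delta7(i, j) = phi(a,c) phi(b,d) + phi(a,d) phi(b,c); the diagonal is 1
#' and any pair involving a founder is 0 off-diagonal (founders are
#' mutually unrelated).  The pedigree must contain no inbred individual:
#' each non-founder's parents must have kinship 0.  General identity
#' coefficients for inbred pedigrees are out of scope and raise an error.
#'
#' @param ped a \code{pedigree}.
#' @return symmetric matrix with unit diagonal, entries in [0, 1].
#' @export
delta7_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  phi <- theoretical_kinship(ped)
  id <- ped$person_id
  fi <- match(ped$father_id, id)
  mi <- match(ped$mother_id, id)
  nf <- which(!ped$founder)
  inbred <- nf[phi[cbind(fi[nf], mi[nf])] > 0]
  if (length(inbred))
    stop("inbred individual(s) present (parents related): ",
         paste(id[inbred], collapse = ", "),
         "; Delta7 supports only non-inbred pedigrees")
  n <- nrow(ped)
  d7 <- diag(n)
  if (length(nf) >= 2L) {
    for (u in seq_along(nf)) {
      i <- nf[u]
      for (v in seq_len(u - 1L)) {
        j <- nf[v]
        val <- phi[fi[i], fi[j]] * phi[mi[i], mi[j]] +
               phi[fi[i], mi[j]] * phi[mi[i], fi[j]]
        d7[i, j] <- val; d7[j, i] <- val
      }
    }
  }
  new_structure_matrix(d7, id, "delta7")
}

#' Household indicator matrix
#'
#' Entry (i, j) is 1 if i and j share a household ID and 0 otherwise;
#' the diagonal is 1.  Individuals without a household ID form singleton
#' households.
#'
#' @param ped a \code{pedigree}.
#' @export
household_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  hh <- ped$household_id
  hh[is.na(hh)] <- paste0(".singleton.", seq_len(nrow(ped)))[is.na(hh)]
  H <- outer(hh, hh, "==") * 1
  diag(H) <- 1
  new_structure_matrix(H, ped$person_id, "household")
}

# allele frequencies and missingness helpers ------------------------------
snp_freq <- function(dosage) colMeans(dosage, na.rm = TRUE) / 2

#' SNP-based kinship: genetic relationship matrix (GRM)
#'
#' Per-SNP standardized estimator on the kinship scale:
#' \deqn{\hat\Phi_{ij} = \frac{1}{S'} \sum_s
#'   \frac{(x_{is} - 2\hat p_s)(x_{js} - 2\hat p_s)}{4 \hat p_s (1-\hat p_s)}}
#' over the \eqn{S'} SNPs non-missing in both individuals; \eqn{\hat p_s}
#' is the sample allele frequency over all individuals.  Monomorphic SNPs
#' are skipped.  The diagonal uses the same formula (expectation 1/2 under
#' Hardy-Weinberg); no winsorizing is applied.
#'
#' @param geno a \code{\link{geno_matrix}}.
#' @param scope \code{"global"} or \code{"within_pedigree"} (zeroes entries
#'   between pedigrees; requires \code{ped}).
#' @param ped a \code{pedigree}, required for \code{within_pedigree}.
#' @return symmetric kinship-scale matrix.
#' @export
grm_kinship <- function(geno, scope = c("global", "within_pedigree"),
                        ped = NULL) {
  scope <- match.arg(scope)
  X <- geno$dosage
  p <- snp_freq(X)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; kinship undefined")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  Z <- sweep(X, 2L, 2 * p, "-") / rep(sqrt(4 * p * (1 - p)), each = nrow(X))
  obs <- !is.na(Z)
  Z[!obs] <- 0
  num <- tcrossprod(Z)
  Sp <- tcrossprod(obs * 1)           # pairwise-complete SNP counts
  if (any(Sp == 0)) stop("individual pair with no SNPs in common")
  K <- num / Sp
  K <- mask_scope(K, scope, ped, rownames(X))
  new_structure_matrix(K, rownames(X), "grm")
}

#' SNP-based kinship: method of moments
#'
#' Allele-matching estimator.  With \eqn{e_{ij} = \frac14 \sum_s
#' [x_{is} x_{js} + (2 - x_{is})(2 - x_{js})]} over pairwise-complete SNPs
#' and \eqn{c_{ij} = \sum_s (\hat p_s^2 + \hat q_s^2)} over the same SNPs,
#' \deqn{\hat\varphi_{ij} = \frac{e_{ij} - c_{ij}}{S' - c_{ij}}.}
#'
#' @inheritParams grm_kinship
#' @export
mom_kinship <- function(geno, scope = c("global", "within_pedigree"),
                        ped = NULL) {
  scope <- match.arg(scope)
  X <- geno$dosage
  p <- snp_freq(X)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; kinship undefined")
  X <- X[, poly, drop = FALSE]; p <- p[poly]
  obs <- !is.na(X)
  X0 <- X; X0[!obs] <- 0L
  storage.mode(X0) <- "double"
  B <- obs * 1
  XX <- tcrossprod(X0)                 # sum x_i x_j over shared SNPs
  RS <- X0 %*% t(B)                    # sum_{s in both} x_is
  Sp <- tcrossprod(B)
  if (any(Sp == 0)) stop("individual pair with no SNPs in common")
  E <- 0.5 * XX - 0.5 * RS - 0.5 * t(RS) + Sp
  cs <- p^2 + (1 - p)^2
  C <- B %*% (cs * t(B))               # sum of p^2+q^2 over shared SNPs
  den <- Sp - C
  if (any(den <= 0)) stop("method-of-moments denominator <= 0")
  K <- (E - C) / den
  K <- mask_scope(K, scope, ped, rownames(X))
  new_structure_matrix(K, rownames(X), "mom")
}

mask_scope <- function(K, scope, ped, ids) {
  if (scope == "within_pedigree") {
    if (is.null(ped)) stop("scope 'within_pedigree' requires a pedigree")
    pid <- ped$pedigree_id[match(ids, ped$person_id)]
    if (anyNA(pid)) stop("individual(s) absent from pedigree")
    K[outer(pid, pid, "!=")] <- 0
  }
  K
}

#' Project a symmetric matrix onto the positive semidefinite cone
#'
#' Eigenvalue clipping at zero.  Empirical kinship estimates (notably
#' method-of-moments) can be indefinite; the model fitter projects them
#' before they enter the covariance.
#'
#' @param K symmetric matrix.
#' @param tol eigenvalues below \code{tol} are clipped to 0.
#' @export
psd_project <- function(K, tol = 0) {
  e <- eigen(K, symmetric = TRUE)
  if (all(e$values >= tol)) return(K)
  v <- pmax(e$values, tol)
  out <- e$vectors %*% (v * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(K)
  attr(out, "kind") <- attr(K, "kind")
  out
}

#' Write a structure matrix as a 3-column TSV (lower triangle)
#'
#' Columns \code{id_i}, \code{id_j}, \code{value}.
#'
#' @param K structure matrix with ID dimnames.
#' @param path output path.
#' @export
write_kinship_tsv <- function(K, path) {
  idx <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(id_i = rownames(K)[idx[, 1L]],
                   id_j = colnames(K)[idx[, 2L]],
                   value = K[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
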