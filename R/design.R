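# Design assembly for the multivariate variance-component model.
#
# vec(Y) is trait-major: within a pedigree of n_p individuals the row for
# (trait t, individual i) is (t-1) * n_p + i, so the covariance assembles
# as kron(Sigma_component, K_component) with K the n_p x n_p structure
# matrix.  Equality constraints collapse the per-trait copies of a
# covariate column into a single summed column (one shared coefficient).

trait_names_from_formula <- function(formula) {
  lhs <- formula[[2L]]
  if (is.call(lhs) && identical(lhs[[1L]], as.name("cbind")))
    vapply(as.list(lhs)[-1L], deparse, "")
  else deparse(lhs)
}

#' Build the stacked design for a variance-component model
#'
#' Parses \code{formula} (LHS: one trait or \code{cbind()} of several; RHS:
#' covariates and interactions), drops individuals with missing covariates
#' or no observed trait, and returns per-pedigree design blocks over the
#' trait-major vectorization of Y with missing trait entries removed
#' (multivariate-normal marginalization).  A covariate named in
#' \code{constraints} receives one coefficient per trait group (its column
#' is the sum of the per-trait columns); otherwise one per trait.
#'
#' @param formula e.g. \code{cbind(SBP, DBP) ~ sex + age + sex:age}.
#' @param data data frame with a \code{person_id} column, trait columns and
#'   covariate columns.
#' @param pedigree a \code{pedigree} covering all analyzed individuals.
#' @param constraints character vector of design column names (as produced
#'   by \code{model.matrix}, e.g. \code{"age"}, \code{"sexmale"},
#'   \code{"(Intercept)"}) whose effect is shared across the traits of each
#'   trait group.
#' @param trait_groups named list mapping group labels to trait columns
#'   (default: each trait its own group).
#' @return an internal \code{vc_design} list: per-pedigree blocks (observed
#'   response \code{y}, design \code{A}, observation map), coefficient
#'   names, analyzed IDs and a log of dropped individuals.
#' @export
vc_design <- function(formula, data, pedigree, constraints = NULL,
                      trait_groups = NULL) {
  stopifnot(inherits(pedigree, "pedigree"))
  if (!"person_id" %in% names(data))
    stop("data needs a person_id column")
  ids <- as.character(data$person_id)
  if (anyDuplicated(ids)) stop("duplicate person_id in data")
  unknown <- setdiff(ids, pedigree$person_id)
  if (length(unknown))
    stop("individual(s) absent from pedigree: ", paste(unknown, collapse = ", "))

  traits <- trait_names_from_formula(formula)
  miss <- setdiff(traits, names(data))
  if (length(miss)) stop("trait column(s) absent: ", paste(miss, collapse = ", "))
  Y <- as.matrix(data[, traits, drop = FALSE])
  storage.mode(Y) <- "double"
  T_ <- length(traits)

  rhs <- stats::delete.response(stats::terms(formula, data = data))
  mf <- stats::model.frame(rhs, data, na.action = stats::na.pass)
  X <- stats::model.matrix(rhs, mf)
  if (nrow(X) != nrow(data)) stop("internal: design row mismatch")

  if (is.null(trait_groups)) {
    trait_groups <- as.list(traits); names(trait_groups) <- traits
  }
  stopifnot(all(unlist(trait_groups) %in% traits),
            !anyDuplicated(unlist(trait_groups)))
  if (!is.null(constraints)) {
    bad <- setdiff(constraints, colnames(X))
    if (length(bad))
      stop("unknown covariate(s) in constraints: ", paste(bad, collapse = ", "))
  }

  # drop: missing covariate (whole individual) or no observed trait
  cov_miss <- rowSums(is.na(X)) > 0
  all_na <- rowSums(!is.na(Y)) == 0
  dropped <- rbind(
    data.frame(person_id = ids[cov_miss],
               reason = rep("missing_covariate", sum(cov_miss))),
    data.frame(person_id = ids[all_na & !cov_miss],
               reason = rep("no_observed_trait", sum(all_na & !cov_miss))))
  keep <- !cov_miss & !all_na
  if (!any(keep)) stop("no analyzable individuals left")
  ids <- ids[keep]; Y <- Y[keep, , drop = FALSE]; X <- X[keep, , drop = FALSE]
  rownames(Y) <- ids

  # coefficient map: one coefficient per (constrained column x group) or
  # (free column x trait)
  cmap <- list()
  for (cc in colnames(X)) {
    if (!is.null(constraints) && cc %in% constraints) {
      for (g in names(trait_groups))
        cmap[[length(cmap) + 1L]] <- list(
          name = paste0(g, ":", cc), column = cc,
          traits = trait_groups[[g]])
    } else {
      for (tr in traits)
        cmap[[length(cmap) + 1L]] <- list(
          name = paste0(tr, ":", cc), column = cc, traits = tr)
    }
  }
  coef_names <- vapply(cmap, `[[`, "", "name")

  # per-pedigree blocks in pedigree order
  ped_use <- pedigree[pedigree$person_id %in% ids, , drop = FALSE]
  blocks <- lapply(split(seq_len(nrow(ped_use)), ped_use$pedigree_id)
                   [unique(ped_use$pedigree_id)], function(ridx) {
    pids <- ped_use$person_id[ridx]
    di <- match(pids, ids)
    Yp <- Y[di, , drop = FALSE]
    Xp <- X[di, , drop = FALSE]
    n_p <- length(pids)
    obs <- as.vector(!is.na(Yp))            # trait-major: col t stacks
    A_full <- matrix(0, n_p * T_, length(cmap))
    for (j in seq_along(cmap)) {
      ti <- match(cmap[[j]]$traits, traits)
      for (t in ti)
        A_full[(t - 1L) * n_p + seq_len(n_p), j] <- Xp[, cmap[[j]]$column]
    }
    obs_map <- data.frame(ind = rep(seq_len(n_p), times = T_),
                          trait = rep(seq_len(T_), each = n_p))[obs, ]
    list(ids = pids, n = n_p, Y = Yp, obs = obs,
         y = as.vector(Yp)[obs], A = A_full[obs, , drop = FALSE],
         obs_map = obs_map)
  })

  A_all <- do.call(rbind, lapply(blocks, `[[`, "A"))
  if (qr(A_all)$rank < ncol(A_all))
    stop("design is rank deficient after constraint collapsing; ",
         "remove redundant covariates or constraints")

  structure(list(traits = traits, T = T_, ids = ids, blocks = blocks,
                 coef_names = coef_names, coef_map = cmap,
                 trait_groups = trait_groups, constraints = constraints,
                 dropped = dropped, formula = formula),
            class = "vc_design")
}
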