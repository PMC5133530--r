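#' Trait and covariate tables
#'
#' Holds an \code{n x T} trait matrix and an \code{n x C} covariate matrix
#' (both with \code{NA} for missing), individual IDs, and an optional
#' grouping of trait columns into longitudinal series (e.g.
#' \code{SBP = c("SBP_1", ..., "SBP_4")}) used by equality constraints.
#'
#' @param traits numeric matrix or data frame (rownames or \code{ids} give
#'   individual IDs); at least one column.
#' @param covariates optional numeric matrix/data frame aligned with
#'   \code{traits}.
#' @param ids individual IDs; defaults to rownames of \code{traits}.
#' @param trait_groups optional named list mapping a group label to the
#'   trait columns measured at different time points.
#' @return an object of class \code{"trait_table"}.
#' @export
trait_table <- function(traits, covariates = NULL, ids = NULL,
                        trait_groups = NULL) {
  traits <- as.matrix(traits)
  storage.mode(traits) <- "double"
  if (is.null(ids)) ids <- rownames(traits)
  if (is.null(ids)) stop("individual IDs required (rownames or ids=)")
  ids <- as.character(ids)
  stopifnot(length(ids) == nrow(traits), ncol(traits) >= 1L)
  rownames(traits) <- ids
  if (is.null(colnames(traits)))
    colnames(traits) <- paste0("trait", seq_len(ncol(traits)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    stopifnot(nrow(covariates) == nrow(traits))
    rownames(covariates) <- ids
  }
  if (is.null(trait_groups)) {
    trait_groups <- as.list(colnames(traits))
    names(trait_groups) <- colnames(traits)
  }
  stopifnot(all(unlist(trait_groups) %in% colnames(traits)))
  structure(list(traits = traits, covariates = covariates, ids = ids,
                 trait_groups = trait_groups), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("Trait table: %d individuals x %d trait(s) [%s], %d covariate(s)\n",
              nrow(x$traits), ncol(x$traits),
              paste(colnames(x$traits), collapse = ", "),
              if (is.null(x$covariates)) 0L else ncol(x$covariates)))
  invisible(x)
}

#' Read a phenotype CSV into a trait table
#'
#' First column individual ID; trait columns named in \code{traits};
#' remaining named columns become covariates.  Empty fields and \code{NA}
#' are missing.
#'
#' @param path CSV path.
#' @param traits character vector of trait column names.
#' @param covariates character vector of covariate column names
#'   (default: all other columns).
#' @param trait_groups optional longitudinal grouping, see
#'   \code{\link{trait_table}}.
#' @export
read_traits <- function(path, traits, covariates = NULL, trait_groups = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = c("", "NA"))
  ids <- as.character(df[[1L]])
  miss <- setdiff(traits, names(df))
  if (length(miss)) stop("trait column(s) absent: ", paste(miss, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(df)[-1L], traits)
  Y <- as.matrix(df[, traits, drop = FALSE])
  X <- if (length(covariates)) as.matrix(df[, covariates, drop = FALSE]) else NULL
  trait_table(Y, X, ids = ids, trait_groups = trait_groups)
}

#' Write a trait table as a phenotype CSV
#'
#' @param tt a \code{trait_table}.
#' @param path output path.
#' @export
write_traits <- function(tt, path) {
  df <- data.frame(person_id = tt$ids, tt$traits, check.names = FALSE)
  if (!is.null(tt$covariates))
    df <- cbind(df, as.data.frame(tt$covariates, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
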