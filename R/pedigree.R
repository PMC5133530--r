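#' Pedigree tables
#'
#' A pedigree is stored as a data frame of class \code{"pedigree"} with one
#' row per individual and columns \code{pedigree_id}, \code{person_id},
#' \code{father_id}, \code{mother_id} (\code{NA} for founders), \code{sex}
#' (\code{"male"}, \code{"female"} or \code{"unknown"}), \code{household_id}
#' (\code{NA} allowed; such individuals form singleton households) and the
#' derived logical \code{founder}.  Rows are ordered parents-before-children
#' within each pedigree.  All joins downstream are by \code{person_id},
#' never by row position.
#'
#' @param x a data frame with at least \code{pedigree_id}, \code{person_id},
#'   \code{father_id}, \code{mother_id}; \code{sex} and \code{household_id}
#'   are optional.
#' @return a validated, topologically sorted \code{pedigree} data frame.
#' @examples
#' ped <- as_pedigree(data.frame(
#'   pedigree_id = "fam1",
#'   person_id   = c("p1", "p2", "k1"),
#'   father_id   = c(NA, NA, "p1"),
#'   mother_id   = c(NA, NA, "p2"),
#'   sex         = c("male", "female", "female")))
#' ped$founder
#' @export
as_pedigree <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("pedigree_id", "person_id", "father_id", "mother_id")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("pedigree table lacks column(s): ", paste(miss, collapse = ", "))
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (cc in c(need, "sex", "household_id"))
    if (cc %in% names(x)) x[[cc]] <- as.character(x[[cc]])
  blank_to_na <- function(v) { v[!is.na(v) & (v == "" | v == "NA" | v == "0")] <- NA; v }
  x$father_id <- blank_to_na(x$father_id)
  x$mother_id <- blank_to_na(x$mother_id)
  if (is.null(x$sex)) x$sex <- "unknown"
  x$sex <- tolower(x$sex)
  x$sex[x$sex %in% c("1", "m")] <- "male"
  x$sex[x$sex %in% c("2", "f")] <- "female"
  x$sex[!(x$sex %in% c("male", "female"))] <- "unknown"
  if (is.null(x$household_id)) x$household_id <- NA_character_
  x$household_id <- blank_to_na(x$household_id)
  if (anyDuplicated(x$person_id))
    stop("duplicate person_id: ",
         paste(unique(x$person_id[duplicated(x$person_id)]), collapse = ", "))

  # one parent present implies both must be
  one_parent <- xor(is.na(x$father_id), is.na(x$mother_id))
  if (any(one_parent))
    stop("individual(s) with exactly one parent recorded: ",
         paste(x$person_id[one_parent], collapse = ", "))
  x$founder <- is.na(x$father_id) & is.na(x$mother_id)

  # parents must exist, in the same pedigree
  for (side in c("father_id", "mother_id")) {
    pid <- x[[side]]
    known <- is.na(pid) | pid %in% x$person_id
    if (!all(known))
      stop("missing parent record for: ",
           paste(x$person_id[!known], collapse = ", "),
           " (dangling ", sub("_id", "", side), " ID ",
           paste(pid[!known], collapse = ", "), ")")
    idx <- match(pid, x$person_id)
    same <- is.na(pid) | x$pedigree_id[idx] == x$pedigree_id
    if (!all(same))
      stop("parent in a different pedigree for: ",
           paste(x$person_id[!same], collapse = ", "))
  }

  x <- x[, c("pedigree_id", "person_id", "father_id", "mother_id",
             "sex", "household_id", "founder")]
  x <- x[order(match(x$pedigree_id, unique(x$pedigree_id))), , drop = FALSE]
  x <- ped_toposort(x)
  rownames(x) <- NULL
  class(x) <- c("pedigree", "data.frame")
  x
}

# Kahn topological sort (parents before children) per pedigree; detects cycles.
ped_toposort <- function(x) {
  out <- lapply(split(seq_len(nrow(x)), x$pedigree_id)[unique(x$pedigree_id)],
                function(idx) {
    sub <- x[idx, , drop = FALSE]
    n <- nrow(sub)
    placed <- logical(n)
    order_out <- integer(0)
    repeat {
      ready <- !placed &
        (is.na(sub$father_id) | sub$father_id %in% sub$person_id[placed]) &
        (is.na(sub$mother_id) | sub$mother_id %in% sub$person_id[placed])
      if (!any(ready)) break
      order_out <- c(order_out, which(ready))
      placed[ready] <- TRUE
    }
    if (!all(placed))
      stop("pedigree cycle detected involving individual(s): ",
           paste(sub$person_id[!placed], collapse = ", "))
    sub[order_out, , drop = FALSE]
  })
  do.call(rbind, out)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree table: %d individuals in %d pedigree(s), %d founders\n",
              nrow(x), length(unique(x$pedigree_id)), sum(x$founder)))
  print.data.frame(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("...", nrow(x) - 8L, "more rows\n")
  invisible(x)
}

#' Read a pedigree file
#'
#' Two dialects are supported.  \code{"mendel_csv"} is a CSV with header
#' columns \code{pedigree_id, person_id, father_id, mother_id, sex,
#' household_id} (missing parents/households as empty fields or \code{NA}).
#' \code{"plink_fam"} is the whitespace-delimited PLINK FAM layout
#' (FID IID PAT MAT SEX PHENO; \code{0} denotes a missing parent); FAM files
#' carry no household column.
#'
#' @param path file path.
#' @param dialect \code{"mendel_csv"} or \code{"plink_fam"}.
#' @return a \code{\link{as_pedigree}} object.
#' @export
read_pedigree <- function(path, dialect = c("mendel_csv", "plink_fam")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  if (dialect == "mendel_csv") {
    df <- utils::read.csv(path, colClasses = "character", na.strings = c("", "NA"))
  } else {
    df <- utils::read.table(path, colClasses = "character")
    if (ncol(df) < 4L) stop("FAM file needs at least 4 columns: ", path)
    names(df)[1:4] <- c("pedigree_id", "person_id", "father_id", "mother_id")
    df$sex <- if (ncol(df) >= 5L) df[[5L]] else "unknown"
    df <- df[, c("pedigree_id", "person_id", "father_id", "mother_id", "sex")]
  }
  as_pedigree(df)
}

#' Write a pedigree file
#'
#' @inheritParams read_pedigree
#' @param ped a \code{pedigree}.
#' @export
write_pedigree <- function(ped, path, dialect = c("mendel_csv", "plink_fam")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ped, "pedigree"))
  if (dialect == "mendel_csv") {
    out <- as.data.frame(ped)[, c("pedigree_id", "person_id", "father_id",
                                  "mother_id", "sex", "household_id")]
    utils::write.csv(out, path, row.names = FALSE, na = "")
  } else {
    sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex]
    out <- data.frame(ped$pedigree_id, ped$person_id,
                      ifelse(is.na(ped$father_id), "0", ped$father_id),
                      ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                      sex_code, "-9")
    utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
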