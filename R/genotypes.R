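#' Genotype matrices
#'
#' Dosages are stored as an \code{n x S} integer matrix counting minor
#' alleles (0/1/2, \code{NA} = missing), with individual IDs as row names
#' and SNP IDs as column names, together with a SNP map (data frame with
#' \code{snp_id}, \code{chrom}, \code{bp}, \code{allele_minor},
#' \code{allele_major}, \code{flipped}).  SNP IDs follow the
#' "chr-basepair" convention (e.g. \code{"3-47956424"}) unless the input
#' supplies its own.  Orientation is normalized at load time: if the coded
#' allele turns out to be the major allele by sample frequency, dosages are
#' recoded as \code{2 - x} and \code{flipped} records it (ties keep the
#' coded allele).
#'
#' @param dosage integer matrix, individuals x SNPs, entries 0/1/2/NA.
#' @param map optional SNP map; reconstructed from column names if absent.
#' @param normalize flip columns whose coded-allele frequency exceeds 1/2.
#' @return an object of class \code{"geno_matrix"}: a list with elements
#'   \code{dosage} and \code{map}.
#' @export
geno_matrix <- function(dosage, map = NULL, normalize = TRUE) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage matrix needs individual IDs as rownames")
  if (is.null(colnames(dosage))) stop("dosage matrix needs SNP IDs as colnames")
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage (not 0/1/2/NA) at individual '%s', SNP '%s'",
                 rownames(dosage)[w[1L]], colnames(dosage)[w[2L]]))
  }
  storage.mode(dosage) <- "integer"
  if (is.null(map)) {
    parts <- strsplit(colnames(dosage), "-", fixed = TRUE)
    chrom <- vapply(parts, function(p) p[1L], "")
    bp <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    map <- data.frame(snp_id = colnames(dosage), chrom = chrom, bp = bp,
                      allele_minor = "m", allele_major = "M",
                      flipped = FALSE, stringsAsFactors = FALSE)
  }
  stopifnot(identical(map$snp_id, colnames(dosage)))
  if (normalize) {
    p <- colMeans(dosage, na.rm = TRUE) / 2
    flip <- !is.na(p) & p > 0.5
    if (any(flip)) {
      dosage[, flip] <- 2L - dosage[, flip]
      tmp <- map$allele_minor[flip]
      map$allele_minor[flip] <- map$allele_major[flip]
      map$allele_major[flip] <- tmp
      map$flipped[flip] <- !map$flipped[flip]
    }
  }
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  d <- x$dosage
  cat(sprintf("Genotype matrix: %d individuals x %d SNPs, %.2f%% missing\n",
              nrow(d), ncol(d), 100 * mean(is.na(d))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by individuals and/or SNPs
#'
#' @param geno a \code{geno_matrix}.
#' @param individuals,snps character IDs (or logical/integer indices) to keep.
#' @export
geno_subset <- function(geno, individuals = NULL, snps = NULL) {
  d <- geno$dosage; m <- geno$map
  if (!is.null(individuals)) d <- d[individuals, , drop = FALSE]
  if (!is.null(snps)) {
    d <- d[, snps, drop = FALSE]
    m <- m[match(colnames(d), m$snp_id), , drop = FALSE]
    rownames(m) <- NULL
  }
  structure(list(dosage = d, map = m), class = "geno_matrix")
}

#' Read genotypes
#'
#' \code{"csv_dosage"} expects a header row of SNP IDs, one row per
#' individual with the individual ID in the first column, dosages in
#' \{0,1,2\} or empty/\code{NA} for missing.  \code{"plink_bed"} expects
#' \code{path} to name the \code{.bed} file (or its prefix) with the
#' \code{.bim}/\code{.fam} siblings alongside; the standard SNP-major
#' binary layout with magic bytes \code{0x6c 0x1b 0x01} is required.
#'
#' @param path file path (for PLINK, the \code{.bed} path or prefix).
#' @param dialect \code{"csv_dosage"} or \code{"plink_bed"}.
#' @param ped optional \code{pedigree}; when given, individual IDs must all
#'   resolve against it.
#' @param normalize normalize dosages to minor-allele counts (default TRUE).
#' @return a \code{\link{geno_matrix}}.
#' @export
read_genotypes <- function(path, dialect = c("csv_dosage", "plink_bed"),
                           ped = NULL, normalize = TRUE) {
  dialect <- match.arg(dialect)
  g <- if (dialect == "csv_dosage") read_csv_dosage(path, normalize)
       else read_plink_bed(path, normalize)
  if (!is.null(ped)) {
    unknown <- setdiff(rownames(g$dosage), ped$person_id)
    if (length(unknown))
      stop("genotyped individual(s) absent from pedigree: ",
           paste(unknown, collapse = ", "))
  }
  g
}

read_csv_dosage <- function(path, normalize) {
  if (!file.exists(path)) stop("genotype file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  ids <- df[[1L]]
  d <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(d), nrow(d), ncol(d),
                                 dimnames = list(ids, colnames(d))))
  bad <- !is.na(d) & (is.na(num) | !(num %in% c(0, 1, 2)))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-{0,1,2} dosage '%s' at row %d (individual '%s'), column '%s'",
                 d[w[1L], w[2L]], w[1L], ids[w[1L]], colnames(d)[w[2L]]))
  }
  geno_matrix(num, normalize = normalize)
}

#' Write genotypes as CSV dosage
#'
#' @param geno a \code{geno_matrix}.
#' @param path output path.
#' @export
write_csv_dosage <- function(geno, path) {
  df <- data.frame(person_id = rownames(geno$dosage),
                   geno$dosage, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---- PLINK BED/BIM/FAM --------------------------------------------------
# SNP-major .bed: 3 magic bytes then ceiling(n/4) bytes per SNP, 2 bits per
# individual, little-endian within byte: 00 hom A1, 01 missing, 10 het,
# 11 hom A2.  A1 is treated as the coded (counted) allele.

plink_paths <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  list(bed = paste0(prefix, ".bed"), bim = paste0(prefix, ".bim"),
       fam = paste0(prefix, ".fam"))
}

read_plink_bed <- function(path, normalize) {
  pp <- plink_paths(path)
  for (f in unlist(pp)) if (!file.exists(f)) stop("PLINK file not found: ", f)
  fam <- utils::read.table(pp$fam, colClasses = "character")
  bim <- utils::read.table(pp$bim, colClasses = "character")
  names(bim) <- c("chrom", "snp_id", "cm", "bp", "a1", "a2")[seq_len(ncol(bim))]
  n <- nrow(fam); S <- nrow(bim)
  bpS <- ceiling(n / 4)
  con <- file(pp$bed, "rb"); on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK .bed file: ", pp$bed)
  raw <- readBin(con, "raw", bpS * S)
  if (length(raw) < bpS * S) stop("truncated .bed file: ", pp$bed)
  m <- matrix(as.integer(raw), nrow = bpS, ncol = S)
  # expand each byte into 4 two-bit codes
  codes <- array(0L, dim = c(4L, bpS, S))
  v <- m
  for (k in 1:4) { codes[k, , ] <- v %% 4L; v <- v %/% 4L }
  codes <- matrix(codes, nrow = 4L * bpS, ncol = S)[seq_len(n), , drop = FALSE]
  # code -> dosage of A1: 00->2, 10->1, 11->0, 01->NA
  lut <- c(`0` = 2L, `1` = NA_integer_, `2` = 1L, `3` = 0L)
  d <- matrix(lut[codes + 1L], n, S,
              dimnames = list(fam[[2L]], bim$snp_id))
  map <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom,
                    bp = as.integer(bim$bp),
                    allele_minor = bim$a1, allele_major = bim$a2,
                    flipped = FALSE, stringsAsFactors = FALSE)
  geno_matrix(d, map, normalize = normalize)
}

#' Write genotypes as a PLINK BED/BIM/FAM triple
#'
#' @param geno a \code{geno_matrix}.
#' @param prefix output path prefix (\code{.bed/.bim/.fam} appended).
#' @param ped optional \code{pedigree} supplying family IDs, parents and sex
#'   for the FAM file; otherwise singleton records are written.
#' @export
write_plink_bed <- function(geno, prefix, ped = NULL) {
  d <- geno$dosage; n <- nrow(d); S <- ncol(d)
  pp <- plink_paths(paste0(prefix, ".bed"))
  if (is.null(ped)) {
    fam <- data.frame(rownames(d), rownames(d), "0", "0", "0", "-9")
  } else {
    idx <- match(rownames(d), ped$person_id)
    if (anyNA(idx)) stop("individuals missing from pedigree")
    sex_code <- c(male = "1", female = "2", unknown = "0")[ped$sex[idx]]
    fam <- data.frame(ped$pedigree_id[idx], rownames(d),
                      ifelse(is.na(ped$father_id[idx]), "0", ped$father_id[idx]),
                      ifelse(is.na(ped$mother_id[idx]), "0", ped$mother_id[idx]),
                      sex_code, "-9")
  }
  utils::write.table(fam, pp$fam, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  bim <- data.frame(geno$map$chrom, geno$map$snp_id, 0L, geno$map$bp,
                    geno$map$allele_minor, geno$map$allele_major)
  utils::write.table(bim, pp$bim, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  # dosage of coded allele (A1 = minor) -> 2-bit codes
  code <- matrix(1L, n, S)                # 01 missing
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  bpS <- ceiling(n / 4)
  pad <- matrix(0L, bpS * 4L, S)
  pad[seq_len(n), ] <- code
  dim(pad) <- c(4L, bpS, S)
  bytes <- pad[1L, , ] + 4L * pad[2L, , ] + 16L * pad[3L, , ] + 64L * pad[4L, , ]
  con <- file(pp$bed, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(bytes), con)
  invisible(prefix)
}
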