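#' SSR genotype container
#'
#' Stores multi-allelic SSR (microsatellite) band profiles for a panel of
#' accessions. Each call is an unordered pair of integer allele codes
#' (fragment lengths); homozygotes carry the same code twice. Internally the
#' calls are two accession x marker integer matrices `a1` and `a2` with
#' `a1 <= a2` and both `NA` for a missing call.
#'
#' @param ids character vector of unique accession ids.
#' @param markers data.frame with columns `marker` (unique ids) and `chrom`.
#' @param a1,a2 integer matrices, accessions x markers, allele codes with
#'   `a1 <= a2` elementwise; `NA` in both marks a missing call.
#' @return An object of class `ssr_genotypes`.
#' @export
ssr_genotypes <- function(ids, markers, a1, a2) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate accession ids")
  if (anyDuplicated(markers$marker)) stop("duplicate marker ids")
  if (!identical(dim(a1), dim(a2))) stop("a1/a2 dimension mismatch")
  if (nrow(a1) != length(ids) || ncol(a1) != nrow(markers))
    stop("call matrices must be accessions x markers")
  if (any(xor(is.na(a1), is.na(a2))))
    stop("a1 and a2 must be missing together")
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) { # normalise unordered pairs
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ids, markers$marker)
  structure(list(ids = ids,
                 markers = data.frame(marker = as.character(markers$marker),
                                      chrom = as.character(markers$chrom),
                                      stringsAsFactors = FALSE),
                 a1 = a1, a2 = a2),
            class = "ssr_genotypes")
}

#' @exportS3Method base::print
print.ssr_genotypes <- function(x, ...) {
  cat(sprintf("SSR genotypes: %d accessions x %d markers (%.1f%% missing)\n",
              length(x$ids), nrow(x$markers),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @export
dim.ssr_genotypes <- function(x) c(length(x$ids), nrow(x$markers))

#' SNP genotype container
#'
#' Biallelic diploid SNP calls stored as an accession x site matrix of
#' alternate-allele dosages (0 = ref/ref, 1 = ref/alt, 2 = alt/alt, `NA` =
#' missing). Dosage is a lossless encoding of an unordered biallelic diploid
#' genotype, and identity-by-state sharing between two calls is
#' `2 - |d1 - d2|` allele copies.
#'
#' @param ids character vector of unique accession ids.
#' @param sites data.frame with columns `chrom`, `pos` (1-based, strictly
#'   increasing within chromosome), `ref`, `alt`.
#' @param geno integer matrix accessions x sites with values in {0,1,2,NA}.
#' @return An object of class `snp_genotypes`.
#' @export
snp_genotypes <- function(ids, sites, geno) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate accession ids")
  if (nrow(geno) != length(ids) || ncol(geno) != nrow(sites))
    stop("geno must be accessions x sites")
  if (!all(geno %in% c(0L, 1L, 2L, NA)))
    stop("dosages must be 0, 1, 2 or NA")
  ord_ok <- tapply(sites$pos, sites$chrom, function(p) all(diff(p) > 0))
  if (!all(unlist(ord_ok)))
    stop("positions must be strictly increasing within chromosome")
  key <- paste(sites$chrom, sites$pos, sep = ":")
  dimnames(geno) <- list(ids, key)
  structure(list(ids = ids,
                 sites = data.frame(chrom = as.character(sites$chrom),
                                    pos = as.integer(sites$pos),
                                    ref = as.character(sites$ref),
                                    alt = as.character(sites$alt),
                                    stringsAsFactors = FALSE),
                 geno = geno),
            class = "snp_genotypes")
}

#' @exportS3Method base::print
print.snp_genotypes <- function(x, ...) {
  cat(sprintf("SNP genotypes: %d accessions x %d sites (%.1f%% missing)\n",
              length(x$ids), nrow(x$sites), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @export
dim.snp_genotypes <- function(x) c(length(x$ids), nrow(x$sites))

#' Subset SNP genotypes by site index
#' @param x `snp_genotypes`.
#' @param sites integer or logical index over sites.
#' @return `snp_genotypes` with the selected sites, order preserved.
#' @export
subset_sites <- function(x, sites) {
  stopifnot(inherits(x, "snp_genotypes"))
  snp_genotypes(x$ids, x$sites[sites, , drop = FALSE],
                x$geno[, sites, drop = FALSE])
}
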