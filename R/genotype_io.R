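#' Read an SSR genotype table
#'
#' The tab-separated dialect has one row per marker. The first two columns
#' are the marker id and its chromosome; remaining column names are the
#' accession ids. A cell is either a single integer allele code (`"152"`,
#' homozygote), two codes separated by a slash (`"150/154"`, heterozygote),
#' or `"."` for a missing call.
#'
#' @param path path to a TSV file in the dialect above.
#' @return An [ssr_genotypes] object.
#' @export
read_ssr_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  if (ncol(tab) < 2) stop("SSR table needs marker and chromosome columns")
  ids <- colnames(tab)[-(1:2)]
  if (anyDuplicated(ids))
    stop("duplicate accession ids in header: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dup <- duplicated(tab[[1]])
  if (any(dup))
    stop("duplicate marker id at line ", which(dup)[1] + 1L,
         ": ", tab[[1]][which(dup)[1]])
  n_mk <- nrow(tab); n_ac <- length(ids)
  a1 <- a2 <- matrix(NA_integer_, n_ac, n_mk)
  for (j in seq_len(n_mk)) {
    cells <- as.character(tab[j, -(1:2)])
    miss <- cells == "."
    parts <- strsplit(cells[!miss], "/", fixed = TRUE)
    bad <- vapply(parts, function(p)
      length(p) > 2 || anyNA(suppressWarnings(as.integer(p))), logical(1))
    if (any(bad)) {
      col <- which(!miss)[which(bad)[1]]
      stop("malformed cell at line ", j + 1L, ", accession ", ids[col],
           ": '", cells[!miss][which(bad)[1]], "'")
    }
    v1 <- vapply(parts, function(p) as.integer(p[1]), integer(1))
    v2 <- vapply(parts, function(p) as.integer(p[length(p)]), integer(1))
    a1[!miss, j] <- pmin(v1, v2)
    a2[!miss, j] <- pmax(v1, v2)
  }
  ssr_genotypes(ids,
                data.frame(marker = tab[[1]], chrom = tab[[2]],
                           stringsAsFactors = FALSE),
                a1, a2)
}

#' Write an SSR genotype table
#'
#' Inverse of [read_ssr_table()]; `read_ssr_table(write_ssr_table(x))`
#' reproduces `x` exactly.
#'
#' @param genotypes an [ssr_genotypes] object.
#' @param path output path.
#' @export
write_ssr_table <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "ssr_genotypes"))
  g <- genotypes
  cells <- ifelse(is.na(g$a1), ".",
                  ifelse(g$a1 == g$a2, as.character(g$a1),
                         paste0(g$a1, "/", g$a2)))
  out <- cbind(marker = g$markers$marker, chrom = g$markers$chrom,
               t(matrix(cells, nrow = length(g$ids),
                        dimnames = list(g$ids, NULL))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Consumes the GT field of a VCF v4.2 file (via \pkg{vcfR}). Only biallelic
#' records are accepted; phased separators are accepted and unphased
#' internally; `./.` (or `.`) becomes a missing call.
#'
#' @param path path to an (uncompressed or gzipped) VCF file.
#' @return An [snp_genotypes] object.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(v@gt) == 0 || !"FORMAT" %in% colnames(v@gt))
    stop("VCF has no FORMAT/genotype columns")
  if (!all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"])))
    stop("GT field absent from FORMAT")
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) | fix[, "ALT"] == "."
  if (any(multi))
    stop("non-biallelic record(s): ",
         paste(paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])[
           seq_len(min(5, sum(multi)))], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  gt[] <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  is_miss <- is.na(gt) | gt %in% c("./.", ".")
  rest <- !is_miss
  bad <- rest & !(gt %in% names(known))
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-diploid or unrecognised GT '", gt[bad][1], "' at ",
         fix[i[1], "CHROM"], ":", fix[i[1], "POS"])
  }
  dos[rest] <- known[gt[rest]]
  snp_genotypes(ids,
                data.frame(chrom = fix[, "CHROM"],
                           pos = as.integer(fix[, "POS"]),
                           ref = fix[, "REF"], alt = fix[, "ALT"],
                           stringsAsFactors = FALSE),
                t(dos))
}

#' Write SNP genotypes as an uncompressed VCF v4.2 file
#'
#' Emits a minimal GT-only VCF; `read_vcf(write_vcf(x))` preserves ids,
#' sites and calls.
#'
#' @param genotypes an [snp_genotypes] object.
#' @param path output path.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "snp_genotypes"))
  g <- genotypes
  gt_str <- c("0/0", "0/1", "1/1")[g$geno + 1L]
  gt_str[is.na(gt_str)] <- "./."
  gt <- matrix(gt_str, nrow = length(g$ids))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$ids), collapse = "\t")), con)
  body <- paste(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Filter SNP sites on missingness and minor allele frequency
#'
#' Retains exactly the sites whose missing-call fraction is at most
#' `max_missing` and whose minor allele frequency is at least `min_maf`
#' (boundaries inclusive on the retained side). MAF is computed from
#' non-missing allele counts (two per called accession), so a monomorphic
#' site (MAF 0) is dropped by any positive `min_maf`. The accession set and
#' the order of surviving sites are unchanged.
#'
#' @param genotypes an [snp_genotypes] object.
#' @param max_missing maximum tolerated missing-call fraction per site.
#' @param min_maf minimum minor allele frequency per site.
#' @return An [snp_genotypes] object with the retained sites.
#' @export
filter_snps <- function(genotypes, max_missing = 0.30, min_maf = 0.05) {
  stopifnot(inherits(genotypes, "snp_genotypes"),
            max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  g <- genotypes$geno
  n <- nrow(g)
  n_called <- colSums(!is.na(g))
  miss_rate <- 1 - n_called / n
  p_alt <- ifelse(n_called > 0, colSums(g, na.rm = TRUE) / (2 * n_called), NA)
  maf <- pmin(p_alt, 1 - p_alt)
  keep <- miss_rate <= max_missing & !is.na(maf) & maf >= min_maf
  if (!any(keep)) warning("all sites removed by the filter")
  subset_sites(genotypes, keep)
}

#' Drop monomorphic SSR markers
#'
#' Keeps markers at which at least two distinct alleles are observed among
#' non-missing calls.
#'
#' @param genotypes an [ssr_genotypes] object.
#' @return A filtered [ssr_genotypes] object.
#' @export
filter_polymorphic_ssr <- function(genotypes) {
  stopifnot(inherits(genotypes, "ssr_genotypes"))
  n_all <- ssr_allele_counts(genotypes)
  keep <- n_all >= 2
  ssr_genotypes(genotypes$ids, genotypes$markers[keep, , drop = FALSE],
                genotypes$a1[, keep, drop = FALSE],
                genotypes$a2[, keep, drop = FALSE])
}

# distinct non-missing alleles observed per marker
ssr_allele_counts <- function(genotypes) {
  vapply(seq_len(nrow(genotypes$markers)), function(j) {
    length(unique(stats::na.omit(c(genotypes$a1[, j], genotypes$a2[, j]))))
  }, integer(1))
}

#' Summarise a marker panel
#'
#' Counts distinct observed alleles per SSR marker (their total over the
#' panel, and the mean per marker), tabulates SSR markers per chromosome,
#' and bins SNP sites into half-open genomic windows `[k*w, (k+1)*w)` for a
#' density profile.
#'
#' @param ssr an [ssr_genotypes] object, or NULL.
#' @param snp an [snp_genotypes] object, or NULL.
#' @param window_bp window size in bp for SNP density (default 500 kb).
#' @return A list of class `marker_summary` with elements `n_markers`,
#'   `n_polymorphic_alleles`, `mean_alleles_per_marker` (full precision;
#'   rounded to 2 decimals by `print`), `alleles_per_marker`,
#'   `ssr_per_chrom`, and `snp_density` (chrom, window_start, n_snps).
#' @export
marker_summary <- function(ssr = NULL, snp = NULL, window_bp = 500000) {
  out <- list(n_markers = 0L, n_polymorphic_alleles = 0L,
              mean_alleles_per_marker = NA_real_,
              alleles_per_marker = integer(0),
              ssr_per_chrom = NULL, snp_density = NULL,
              window_bp = window_bp)
  if (!is.null(ssr)) {
    stopifnot(inherits(ssr, "ssr_genotypes"))
    cnt <- ssr_allele_counts(ssr)
    out$n_markers <- length(cnt)
    out$n_polymorphic_alleles <- sum(cnt)
    out$mean_alleles_per_marker <- sum(cnt) / length(cnt)
    out$alleles_per_marker <- stats::setNames(cnt, ssr$markers$marker)
    out$ssr_per_chrom <- as.data.frame(table(chrom = ssr$markers$chrom),
                                       responseName = "n_markers")
  }
  if (!is.null(snp)) {
    stopifnot(inherits(snp, "snp_genotypes"))
    win <- ((snp$sites$pos - 1L) %/% window_bp) * window_bp
    dens <- stats::aggregate(list(n_snps = rep(1L, nrow(snp$sites))),
                             by = list(chrom = snp$sites$chrom,
                                       window_start = win), FUN = sum)
    out$snp_density <- dens[order(dens$chrom, dens$window_start), ]
    rownames(out$snp_density) <- NULL
  }
  structure(out, class = "marker_summary")
}

#' @exportS3Method base::print
print.marker_summary <- function(x, ...) {
  if (x$n_markers > 0)
    cat(sprintf("%d SSR markers, %d polymorphic alleles (mean %.2f per marker)\n",
                x$n_markers, x$n_polymorphic_alleles,
                round(x$mean_alleles_per_marker, 2)))
  if (!is.null(x$snp_density))
    cat(sprintf("SNP density: %d windows of %g bp, %d sites total\n",
                nrow(x$snp_density), x$window_bp, sum(x$snp_density$n_snps)))
  invisible(x)
}
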