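#' @name gd-matrices
#' @title Pairwise parental genetic distance
#'
#' @description
#' `gd_ssr_matrix()` computes Nei band-sharing distance from SSR band
#' profiles: over the markers non-missing in both accessions, each distinct
#' allele is a band (1 for a homozygote, 2 for a heterozygote); with `N_a`
#' and `N_b` the band totals of the two accessions and `N_ab` the shared
#' bands (summed per marker, then pooled over the panel),
#' `GD = 1 - 2 N_ab / (N_a + N_b)`.
#'
#' `gd_snp_matrix()` computes one minus identity-by-state: at each site that
#' is called in both accessions the similarity is the number of shared
#' allele copies over two (1, 0.5 or 0); IBS is the mean over those sites
#' and `GD = 1 - IBS`.
#'
#' Both use pairwise-complete deletion; a pair with no jointly called
#' marker/site gets an `NA` entry (with a warning) and support 0. The
#' returned object is a symmetric numeric matrix of class `gd_matrix` with
#' accession dimnames and a `support` attribute counting the markers/sites
#' used per pair.
#'
#' @param genotypes an [ssr_genotypes] or [snp_genotypes] object.
#' @param pairs optional two-column matrix/data.frame of accession id pairs;
#'   computation is restricted to the accessions appearing in it.
#' @return A `gd_matrix`: symmetric matrix with values in `[0,1]`,
#'   zero diagonal, `attr(,"support")` per-pair counts.
NULL

new_gd_matrix <- function(values, support) {
  if (any(support == 0)) {
    und <- which(support == 0 & upper.tri(support), arr.ind = TRUE)
    if (nrow(und) > 0)
      warning("undefined distance (no shared data) for ", nrow(und),
              " pair(s), e.g. ", rownames(support)[und[1, 1]], " vs ",
              colnames(support)[und[1, 2]])
  }
  structure(values, support = support, class = c("gd_matrix", "matrix"))
}

restrict_ids <- function(ids, pairs) {
  if (is.null(pairs)) return(ids)
  want <- unique(c(as.character(pairs[[1]]), as.character(pairs[[2]])))
  missing_ids <- setdiff(want, ids)
  if (length(missing_ids))
    stop("pair ids absent from genotypes: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  ids[ids %in% want]
}

#' @rdname gd-matrices
#' @export
gd_ssr_matrix <- function(genotypes, pairs = NULL) {
  stopifnot(inherits(genotypes, "ssr_genotypes"))
  if (nrow(genotypes$markers) < 1) stop("need at least one marker")
  ids <- restrict_ids(genotypes$ids, pairs)
  a1 <- genotypes$a1[ids, , drop = FALSE]
  a2 <- genotypes$a2[ids, , drop = FALSE]
  n <- length(ids)
  gd <- matrix(0, n, n, dimnames = list(ids, ids))
  support <- matrix(0L, n, n, dimnames = list(ids, ids))
  bands <- 1L + (a1 != a2)             # bands carried per call
  called <- !is.na(a1)
  diag(support) <- rowSums(called)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      xi1 <- a1[i, ]; xi2 <- a2[i, ]
      for (j in seq(i + 1, n)) {
        ok <- called[i, ] & called[j, ]
        m <- sum(ok)
        support[i, j] <- support[j, i] <- m
        if (m == 0) { gd[i, j] <- gd[j, i] <- NA_real_; next }
        yj1 <- a1[j, ok]; yj2 <- a2[j, ok]
        zi1 <- xi1[ok]; zi2 <- xi2[ok]
        shared <- (zi1 == yj1 | zi1 == yj2) +
          ((zi2 != zi1) & (zi2 == yj1 | zi2 == yj2))
        n_a <- sum(bands[i, ok]); n_b <- sum(bands[j, ok])
        gd[i, j] <- gd[j, i] <- 1 - 2 * sum(shared) / (n_a + n_b)
      }
    }
  }
  diag(gd)[diag(support) == 0] <- NA_real_
  new_gd_matrix(gd, support)
}

#' @rdname gd-matrices
#' @export
gd_snp_matrix <- function(genotypes, pairs = NULL) {
  stopifnot(inherits(genotypes, "snp_genotypes"))
  if (nrow(genotypes$sites) < 1) stop("need at least one site")
  ids <- restrict_ids(genotypes$ids, pairs)
  g <- genotypes$geno[ids, , drop = FALSE]
  # shared copies 2-|di-dj| decomposes over dosage-class indicator products:
  # 2*(N00+N11+N22) + (N01+N10+N12+N21)
  A0 <- (!is.na(g) & g == 0L) * 1; A1 <- (!is.na(g) & g == 1L) * 1
  A2 <- (!is.na(g) & g == 2L) * 1
  M <- A0 + A1 + A2
  shared <- 2 * (tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)) +
    tcrossprod(A0, A1) + tcrossprod(A1, A0) +
    tcrossprod(A1, A2) + tcrossprod(A2, A1)
  support <- tcrossprod(M)
  gd <- 1 - shared / (2 * support)
  gd[support == 0] <- NA_real_
  storage.mode(support) <- "integer"
  dimnames(gd) <- dimnames(support) <- list(ids, ids)
  new_gd_matrix(gd, support)
}

#' @exportS3Method base::print
print.gd_matrix <- function(x, ...) {
  v <- x[upper.tri(x)]
  cat(sprintf("Genetic distance matrix: %d accessions; GD %.3f-%.3f (mean %.3f)%s\n",
              nrow(x), min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              mean(v, na.rm = TRUE),
              if (anyNA(v)) sprintf(", %d undefined pairs", sum(is.na(v)))
              else ""))
  invisible(x)
}

#' Write a distance matrix as TSV or PHYLIP
#'
#' @param dm a `gd_matrix`.
#' @param path output path.
#' @param format `"tsv"` (square, header row and column, full precision) or
#'   `"phylip"` (square PHYLIP distance format).
#' @export
write_gd_matrix <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(data.frame(id = rownames(dm), unclass(dm)[,],
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("%5d", nrow(dm)), con)
    writeLines(paste(formatC(rownames(dm), width = -10),
                     apply(format(unclass(dm)[,], digits = 10), 1,
                           paste, collapse = " ")), con)
  }
  invisible(path)
}

#' Per-cross genetic distance table
#'
#' Looks up the male-female GD of every cross of an NC II design in the SSR
#' and SNP distance matrices.
#'
#' @param design an [make_ncii_design()] table.
#' @param ssr_dm,snp_dm `gd_matrix` objects covering all design parents
#'   (either may be `NULL` to skip that marker system).
#' @return A data.frame (`cross`, `male`, `female`, `gd_ssr`, `gd_snp`).
#' @export
cross_gd <- function(design, ssr_dm = NULL, snp_dm = NULL) {
  if (is.null(ssr_dm) && is.null(snp_dm))
    stop("need at least one distance matrix")
  lookup <- function(dm, label) {
    if (is.null(dm)) return(NA_real_)
    absent <- setdiff(unique(c(design$male, design$female)), rownames(dm))
    if (length(absent))
      stop("parent(s) absent from ", label, " distance matrix: ",
           paste(utils::head(absent, 5), collapse = ", "))
    dm[cbind(design$male, design$female)]
  }
  data.frame(cross = design$cross, male = design$male, female = design$female,
             gd_ssr = lookup(ssr_dm, "SSR"), gd_snp = lookup(snp_dm, "SNP"),
             stringsAsFactors = FALSE)
}

#' Per-male-population genetic distance summary
#'
#' For each male parent: min, max and mean GD to its females under each
#' marker system, and the Pearson correlation (with two-sided p) between the
#' SSR- and SNP-based GD of its crosses.
#'
#' @param table a [cross_gd()] data.frame.
#' @return A data.frame, one row per male, with `ssr_min/ssr_max/ssr_mean`,
#'   `snp_min/snp_max/snp_mean`, `r`, `p`, `n`, `mark`.
#' @export
gd_population_summary <- function(table) {
  res <- lapply(split(table, table$male), function(d) {
    rng <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) c(NA_real_, NA_real_, NA_real_)
      else c(min(v), max(v), mean(v))
    }
    s <- rng(d$gd_ssr); n <- rng(d$gd_snp)
    ct <- pearson_cor(d$gd_ssr, d$gd_snp)
    data.frame(male = d$male[1], n_crosses = nrow(d),
               ssr_min = s[1], ssr_max = s[2], ssr_mean = s[3],
               snp_min = n[1], snp_max = n[2], snp_mean = n[3],
               r = ct$r, p = ct$p, n = ct$n, mark = ct$mark,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
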