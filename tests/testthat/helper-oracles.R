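# Independent brute-force oracles and fixture builders. The oracles are
# deliberately naive (explicit double loops over markers/sites) so they share
# no code path with the implementation they check.

# Nei band-sharing GD between two accessions of an ssr_genotypes object,
# counting bands marker by marker over jointly called markers.
naive_gd_ssr_pair <- function(g, i, j) {
  n_a <- 0; n_b <- 0; n_ab <- 0; used <- 0
  for (m in seq_len(nrow(g$markers))) {
    pa <- unique(c(g$a1[i, m], g$a2[i, m]))
    pb <- unique(c(g$a1[j, m], g$a2[j, m]))
    if (anyNA(pa) || anyNA(pb)) next
    used <- used + 1
    n_a <- n_a + length(pa)
    n_b <- n_b + length(pb)
    n_ab <- n_ab + length(intersect(pa, pb))
  }
  if (used == 0) return(NA_real_)
  1 - 2 * n_ab / (n_a + n_b)
}

# 1 - IBS between two accessions, allele-multiset intersection per site.
naive_gd_snp_pair <- function(g, i, j) {
  sims <- c()
  for (s in seq_len(nrow(g$sites))) {
    da <- g$geno[i, s]; db <- g$geno[j, s]
    if (is.na(da) || is.na(db)) next
    aa <- c(rep(0, 2 - da), rep(1, da))
    bb <- c(rep(0, 2 - db), rep(1, db))
    shared <- 0
    for (al in aa) {
      hit <- match(al, bb)
      if (!is.na(hit)) { shared <- shared + 1; bb <- bb[-hit] }
    }
    sims <- c(sims, shared / 2)
  }
  if (!length(sims)) return(NA_real_)
  1 - mean(sims)
}

naive_gd_matrix <- function(g, pair_fun) {
  ids <- g$ids
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids))
    for (j in seq_along(ids))
      if (i != j) out[i, j] <- pair_fun(g, i, j)
  out
}

# random SSR panel: each accession x marker gets 1-2 alleles from a small
# marker-scoped pool; optional missingness
random_ssr <- function(n_acc = 6, n_mk = 20, miss = 0.1, pool = 5) {
  ids <- sprintf("A%02d", seq_len(n_acc))
  a1 <- a2 <- matrix(NA_integer_, n_acc, n_mk)
  for (m in seq_len(n_mk)) {
    codes <- sort(sample(seq(100, 140, 2), pool))
    for (i in seq_len(n_acc)) {
      if (stats::runif(1) < miss) next
      al <- sample(codes, sample(1:2, 1), replace = TRUE)
      a1[i, m] <- min(al); a2[i, m] <- max(al)
    }
  }
  ssr_genotypes(ids, data.frame(marker = sprintf("S%02d", seq_len(n_mk)),
                                chrom = "chr01"), a1, a2)
}

random_snp <- function(n_acc = 6, n_sites = 20, miss = 0.1,
                       inbred = FALSE) {
  ids <- sprintf("A%02d", seq_len(n_acc))
  vals <- if (inbred) c(0L, 2L) else c(0L, 1L, 2L)
  geno <- matrix(sample(vals, n_acc * n_sites, replace = TRUE),
                 n_acc, n_sites)
  geno[matrix(stats::runif(length(geno)) < miss, n_acc)] <- NA_integer_
  snp_genotypes(ids,
                data.frame(chrom = "chr01", pos = seq_len(n_sites) * 100L,
                           ref = "A", alt = "G"), geno)
}

# SSR panel with an exact number of distinct alleles per marker: accession i
# is homozygous for allele ((i-1) mod k)+1 at a k-allele marker
ssr_with_allele_counts <- function(counts, n_acc = max(counts)) {
  n_mk <- length(counts)
  a1 <- matrix(NA_integer_, n_acc, n_mk)
  for (m in seq_len(n_mk))
    a1[, m] <- 100L + 2L * ((seq_len(n_acc) - 1L) %% counts[m])
  ssr_genotypes(sprintf("A%02d", seq_len(n_acc)),
                data.frame(marker = sprintf("S%03d", seq_len(n_mk)),
                           chrom = "chr01"),
                a1, a1)
}

small_sim <- function(seed = 1, ...) {
  defaults <- list(n_males = 2, n_females = 12, n_snps = 120, n_ssr = 15,
                   n_qtl_per_trait = 4, traits = c("PH", "BW", "LP"),
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
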