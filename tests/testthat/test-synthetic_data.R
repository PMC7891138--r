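test_that("config validation rejects degenerate settings", {
  expect_error(sim_config(n_males = 0), "at least one parent")
  expect_error(sim_config(n_snps = 0), "at least one marker")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(snp_missing_rate = 1.2), "missing rates")
  expect_error(sim_config(ssr_allele_range = c(3, 2)), "ssr_allele_range")
})

test_that("fst = 0 collapses subpopulation frequencies to one vector", {
  sim <- simulate_parents(small_sim(fst = 0, snp_missing_rate = 0))
  freq <- sim$truth$subpop_freq
  expect_equal(max(apply(freq, 2, stats::var)), 0)
  expect_false(anyNA(sim$snp$geno))
})

test_that("missingness injection matches the configured binomial rate", {
  cfg <- small_sim(seed = 21, n_snps = 100, n_females = 48,
                   snp_missing_rate = 0.3)
  sim <- simulate_parents(cfg)
  n_calls <- length(sim$snp$geno)
  obs <- mean(is.na(sim$snp$geno))
  se <- sqrt(0.3 * 0.7 / n_calls)
  expect_lt(abs(obs - 0.3), 3 * se)
})

test_that("SSR founder allele counts respect the configured range", {
  sim <- simulate_parents(small_sim(seed = 3, n_ssr = 60,
                                    ssr_allele_range = c(1, 10)))
  counts <- vapply(seq_len(60), function(m)
    length(unique(stats::na.omit(c(sim$ssr$a1[, m], sim$ssr$a2[, m])))),
    integer(1))
  expect_true(all(counts >= 1 & counts <= 10))
})

test_that("simulated parents are fully homozygous before dropout", {
  sim <- simulate_parents(small_sim(seed = 2))
  expect_true(all(sim$truth$snp_complete$geno %in% c(0L, 2L)))
  expect_true(all(sim$ssr$a1 == sim$ssr$a2, na.rm = TRUE))
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_parents(small_sim(seed = 99))
  b <- simulate_parents(small_sim(seed = 99))
  expect_identical(a, b)
  c <- simulate_parents(small_sim(seed = 100))
  expect_false(identical(a$snp$geno, c$snp$geno))
})

test_that("NC II design enumerates the complete factorial deterministically", {
  d <- make_ncii_design(paste0("M", 1:4), paste0("F", 1:282))
  expect_equal(nrow(d), 1128L)
  expect_equal(anyDuplicated(d$cross), 0L)
  d2 <- make_ncii_design("m", "f")
  expect_equal(nrow(d2), 1L)
  d3 <- make_ncii_design(paste0("M", 1:3), paste0("F", 1:5))
  expect_equal(nrow(d3), 15L)
  expect_true(all(table(d3$female) == 3L))
  expect_true(all(table(d3$male) == 5L))
  # female-major within male ordering
  expect_equal(d3$male, rep(paste0("M", 1:3), each = 5))
})

test_that("overlapping or duplicated parent sets are design errors", {
  expect_error(make_ncii_design(c("a", "b"), c("b", "c")), "both male and female")
  expect_error(make_ncii_design(c("a", "a"), "c"), "duplicate")
  expect_error(make_ncii_design(character(0), "c"), "non-empty")
})

test_that("F1 genotypes follow the inbred Mendelian rule", {
  geno <- rbind(M1 = c(0L, 0L, 2L, NA),
                F1 = c(2L, 0L, 2L, 0L))
  par <- snp_genotypes(c("M1", "F1"),
                       data.frame(chrom = "chr01", pos = 1:4 * 10L,
                                  ref = "A", alt = "C"), geno)
  d <- make_ncii_design("M1", "F1")
  f1 <- derive_f1_genotypes(par, d)
  expect_equal(unname(f1$geno[1, ]), c(1L, 0L, 2L, NA)) # het, ref, alt, missing
  # heterozygosity equals the fraction of differing sites
  set.seed(31)
  par2 <- random_snp(10, 100, miss = 0, inbred = TRUE)
  d2 <- make_ncii_design(par2$ids[1:2], par2$ids[3:10])
  f2 <- derive_f1_genotypes(par2, d2)
  for (k in sample(nrow(d2), 5)) {
    differ <- mean(par2$geno[d2$male[k], ] != par2$geno[d2$female[k], ])
    expect_equal(mean(f2$geno[k, ] == 1L), differ)
  }
})

test_that("heterozygous parents are rejected by F1 derivation", {
  geno <- rbind(M1 = c(1L, 0L), F1 = c(0L, 0L))
  par <- snp_genotypes(c("M1", "F1"),
                       data.frame(chrom = "chr01", pos = c(10L, 20L),
                                  ref = "A", alt = "C"), geno)
  expect_error(derive_f1_genotypes(par, make_ncii_design("M1", "F1")),
               "inbred")
})

test_that("phenotype model has the stated closed forms", {
  cfg <- small_sim(seed = 5, snp_missing_rate = 0, dominance_mean = 0.4,
                   dominance_sd = 0, env_sd = 0)
  sim <- simulate_parents(cfg)
  d <- make_ncii_design(sim$meta$id[sim$meta$role == "male"],
                        sim$meta$id[sim$meta$role == "female"])
  f1 <- derive_f1_genotypes(sim$truth$snp_complete, d)
  ph <- simulate_phenotypes(sim$truth$snp_complete, f1, d, sim$truth, cfg)
  means <- aggregate_environments(ph)
  het <- compute_heterosis(d, means)
  # noise-free: replicate environments identical per entity x trait
  sp <- split(ph$value, paste(ph$entity, ph$trait))
  expect_true(all(vapply(sp, function(v) max(v) - min(v) == 0, logical(1))))
  # F1 - MP = d * (number of heterozygous QTLs), exactly
  for (tr in cfg$traits) {
    q <- sim$truth$qtl_sites[[tr]]
    h <- rowSums(f1$geno[, q, drop = FALSE] == 1L)
    rows <- het[het$trait == tr, ]
    expect_equal(rows$F1 - rows$MP, 0.4 * h[rows$cross],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("pure additive architecture gives exactly zero mid-parent heterosis", {
  cfg <- small_sim(seed = 6, snp_missing_rate = 0, dominance_mean = 0,
                   dominance_sd = 0, env_sd = 0)
  sim <- simulate_parents(cfg)
  d <- make_ncii_design(sim$meta$id[sim$meta$role == "male"],
                        sim$meta$id[sim$meta$role == "female"])
  f1 <- derive_f1_genotypes(sim$truth$snp_complete, d)
  ph <- simulate_phenotypes(sim$truth$snp_complete, f1, d, sim$truth, cfg)
  het <- compute_heterosis(d, aggregate_environments(ph))
  expect_equal(max(abs(het$MPH)), 0, tolerance = 1e-10)
})

test_that("entities missing a QTL call get flagged-missing trait values", {
  cfg <- small_sim(seed = 7, snp_missing_rate = 0.15)
  sim <- simulate_parents(cfg)
  d <- make_ncii_design(sim$meta$id[sim$meta$role == "male"],
                        sim$meta$id[sim$meta$role == "female"])
  f1 <- derive_f1_genotypes(sim$snp, d) # observed (with dropout) genotypes
  ph <- simulate_phenotypes(sim$snp, f1, d, sim$truth, cfg)
  tr <- cfg$traits[1]
  q <- sim$truth$qtl_sites[[tr]]
  incomplete <- sim$snp$ids[rowSums(is.na(sim$snp$geno[, q, drop = FALSE])) > 0]
  sub <- ph[ph$trait == tr & ph$entity %in% incomplete, ]
  expect_true(all(is.na(sub$value)))
  complete <- setdiff(sim$snp$ids, incomplete)
  expect_false(anyNA(ph$value[ph$trait == tr & ph$entity %in% complete]))
})

test_that("default panel composition follows the three origin classes", {
  sz <- gdheterosis:::subpop_sizes(286, 3)
  expect_equal(unname(sz), c(136L, 103L, 47L))
  expect_equal(names(sz), c("elite", "historic", "exotic"))
  cfg <- sim_config()
  expect_equal(cfg$n_males + cfg$n_females, 286L)
})

test_that("heterozygous-QTL burden rises with parental IBS distance", {
  # constant positive dominance: the count of heterozygous QTLs per cross is
  # the mechanism linking GD to heterosis, so it must correlate positively
  cfg <- sim_config(n_males = 2, n_females = 282, n_snps = 400,
                    n_ssr = 10, n_qtl_per_trait = 20, fst = 0.4,
                    snp_missing_rate = 0, traits = "PH",
                    dominance_mean = 0.5, dominance_sd = 0, seed = 13)
  sim <- simulate_parents(cfg)
  d <- make_ncii_design(sim$meta$id[sim$meta$role == "male"],
                        sim$meta$id[sim$meta$role == "female"])
  f1 <- derive_f1_genotypes(sim$snp, d)
  dm <- gd_snp_matrix(sim$snp)
  gd <- dm[cbind(d$male, d$female)]
  hq <- rowSums(f1$geno[, sim$truth$qtl_sites[["PH"]], drop = FALSE] == 1L,
                na.rm = TRUE)
  ct <- pearson_cor(gd, hq)
  expect_gt(ct$r, 0)
  expect_lt(ct$p, 0.01)
})
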