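test_that("pearson matches the covariance/SD definition and t-transform p", {
  set.seed(73)
  x <- rnorm(15); y <- 2 * x + rnorm(15)
  ct <- pearson_cor(x, y)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(ct$r, r_oracle, tolerance = 1e-12)
  tstat <- r_oracle * sqrt((15 - 2) / (1 - r_oracle^2))
  expect_equal(ct$p, 2 * stats::pt(-abs(tstat), df = 13), tolerance = 1e-12)
  # perfect linear relation
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  # independent series stay near zero at large n
  set.seed(74)
  a <- rnorm(1000); b <- rnorm(1000)
  expect_lt(abs(pearson_cor(a, b)$r), 0.1)
})

test_that("degenerate correlation inputs are flagged, never NaN", {
  ct <- pearson_cor(c(1, 1, 1, 1), c(1, 2, 3, 4))
  expect_true(is.na(ct$r))
  expect_equal(ct$note, "zero variance")
  ct2 <- pearson_cor(c(1, 2, NA), c(1, NA, 3))
  expect_equal(ct2$n, 1L)
  expect_equal(ct2$note, "fewer than 3 complete pairs")
  # pairwise-complete deletion
  x <- c(1, 2, 3, 4, NA); y <- c(2, 4, 6, NA, 10)
  expect_equal(pearson_cor(x, y)$n, 3L)
  expect_equal(pearson_cor(x, y)$r, 1, tolerance = 1e-12)
})

test_that("significance marks reproduce the star convention over random tables", {
  set.seed(79)
  p <- c(runif(50), runif(10, 0, 0.01), runif(10, 0.01, 0.05), NA)
  m <- sig_mark(p)
  expect_equal(m[is.na(p)], "")
  expect_true(all(m[!is.na(p) & p < 0.01] == "**"))
  expect_true(all(m[!is.na(p) & p >= 0.01 & p < 0.05] == "*"))
  expect_true(all(m[!is.na(p) & p >= 0.05] == ""))
})

gd_het_fixture <- function(seed = 83, dominance_mean = 0.5,
                           dominance_sd = 0, n_females = 60) {
  cfg <- sim_config(n_males = 2, n_females = n_females, n_snps = 300,
                    n_ssr = 30, n_qtl_per_trait = 15,
                    dominance_mean = dominance_mean,
                    dominance_sd = dominance_sd,
                    traits = c("PH", "LP"), seed = seed)
  sim <- simulate_parents(cfg)
  d <- make_ncii_design(sim$meta$id[sim$meta$role == "male"],
                        sim$meta$id[sim$meta$role == "female"])
  f1 <- derive_f1_genotypes(sim$truth$snp_complete, d)
  ph <- simulate_phenotypes(sim$truth$snp_complete, f1, d, sim$truth, cfg)
  het <- compute_heterosis(d, aggregate_environments(ph))
  cg <- cross_gd(d, gd_ssr_matrix(sim$ssr), gd_snp_matrix(sim$snp))
  list(design = d, het = het, cg = cg)
}

test_that("GD correlations are stratified by male with both marker systems", {
  fx <- gd_het_fixture()
  tab <- correlate_gd_with("MPH", fx$cg, fx$het)
  expect_equal(nrow(tab), 2 * 2 * 2) # males x traits x marker systems
  expect_setequal(unique(tab$stratum), c("M01", "M02"))
  expect_setequal(unique(tab$x), c("gd_ssr", "gd_snp"))
  expect_true(all(tab$n == 60))
  expect_true(all(abs(tab$r) <= 1))
  # spot-check one cell against a direct computation
  d <- merge(fx$het[fx$het$trait == "PH" & fx$het$male == "M01", ],
             fx$cg, by = "cross")
  expect_equal(tab$r[tab$stratum == "M01" & tab$trait == "PH" &
                       tab$x == "gd_snp"],
               stats::cor(d$gd_snp, d$MPH), tolerance = 1e-12)
})

test_that("constant GD within a stratum yields a flagged undefined row", {
  fx <- gd_het_fixture(seed = 89)
  fx$cg$gd_snp <- 0.25
  tab <- correlate_gd_with("F1", fx$cg, fx$het)
  snp_rows <- tab[tab$x == "gd_snp", ]
  expect_true(all(is.na(snp_rows$r)))
  expect_true(all(snp_rows$note == "zero variance"))
  expect_false(anyNA(tab$r[tab$x == "gd_ssr"]))
})

test_that("additive traits give strong positive parent-offspring correlation", {
  fx <- gd_het_fixture(seed = 97, dominance_mean = 0)
  tab <- correlate_parent_with_f1(fx$het)
  f1_rows <- tab[tab$y == "F1", ]
  expect_true(all(f1_rows$r > 0.5))
  expect_true(all(f1_rows$p < 0.01))
  # mid-parent value exactly reproduced by F1 -> r = 1, all MPH zero
  d <- fx$design
  parents <- unique(c(d$male, d$female))
  pv <- stats::setNames(seq(40, 60, length.out = length(parents)), parents)
  means <- do.call(rbind, lapply(c("PH", "LP"), function(tr)
    rbind(data.frame(entity = parents, trait = tr, mean = unname(pv),
                     n_env = 1L),
          data.frame(entity = d$cross, trait = tr,
                     mean = unname((pv[d$male] + pv[d$female]) / 2),
                     n_env = 1L))))
  het2 <- compute_heterosis(d, means)
  expect_equal(max(abs(het2$MPH), na.rm = TRUE), 0, tolerance = 1e-9)
  tab2 <- correlate_parent_with_f1(het2)
  expect_true(all(abs(tab2$r[tab2$y == "F1"] - 1) < 1e-9))
})

test_that("group comparisons use Welch tests with Holm adjustment", {
  set.seed(101)
  vals <- data.frame(trait = "LP",
                     group = rep(c("g1", "g2", "g3"), each = 40),
                     value = c(rnorm(40, 10), rnorm(40, 10), rnorm(40, 12)))
  cmp <- compare_groups(vals)
  expect_equal(nrow(cmp), 3L)
  expect_true(all(cmp$p_adj >= cmp$p, na.rm = TRUE)) # Holm never lowers p
  row13 <- cmp[cmp$group_a == "g1" & cmp$group_b == "g3", ]
  expect_true(row13$significant)
  tt <- stats::t.test(vals$value[vals$group == "g1"],
                      vals$value[vals$group == "g3"], var.equal = FALSE)
  expect_equal(row13$p, tt$p.value, tolerance = 1e-12)
  # identical groups: nothing significant
  vals$value <- rep(rnorm(40, 10), 3)
  cmp2 <- compare_groups(vals)
  expect_false(any(cmp2$significant))
  # degenerate group flagged untestable
  vals3 <- data.frame(trait = "PH", group = rep(c("a", "b"), c(1, 10)),
                      value = c(5, rnorm(10)))
  cmp3 <- compare_groups(vals3)
  expect_false(cmp3$testable)
  expect_true(is.na(cmp3$p_adj))
})

test_that("directional dominance makes GD predict MPH; no dominance kills it", {
  hits <- 0
  for (s in 1:5) {
    fx <- gd_het_fixture(seed = 200 + s, dominance_mean = 0.6,
                         n_females = 80)
    tab <- correlate_gd_with("MPH", fx$cg, fx$het)
    snp <- tab[tab$x == "gd_snp", ]
    hits <- hits + all(snp$r > 0)
  }
  expect_gte(hits, 4) # positive in nearly all replicates
  fx0 <- gd_het_fixture(seed = 300, dominance_mean = 0, n_females = 80)
  tab0 <- correlate_gd_with("MPH", fx0$cg, fx0$het)
  expect_true(mean(abs(tab0$r[tab0$x == "gd_snp"])) < 0.25)
})
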