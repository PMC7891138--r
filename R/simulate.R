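#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic panel generator.
#' The defaults describe an upland-cotton-style diallel panel: 4 elite male
#' testers crossed to 282 females drawn from three origin classes (elite,
#' historic, exotic, sized 136/103/47 including the males), genotyped at
#' multi-allelic SSR markers (1-10 alleles each) and biallelic SNPs, and
#' phenotyped for ten yield and fiber traits over 2 years x 2 sites.
#'
#' @param n_males,n_females number of male / female parents.
#' @param n_subpops number of origin subpopulations.
#' @param fst divergence of subpopulation allele frequencies from the shared
#'   ancestral frequency, in `[0,1)`; 0 means one panmictic pool.
#' @param n_snps,n_ssr marker counts.
#' @param ssr_allele_range integer `(min,max)` allele count per SSR marker.
#' @param snp_missing_rate,ssr_missing_rate independent per-call dropout
#'   probabilities.
#' @param n_qtl_per_trait QTL count per trait (sampled from the SNP panel).
#' @param additive_sd SD of per-QTL additive effects (trait units).
#' @param dominance_mean,dominance_sd mean and SD of per-QTL dominance
#'   effects (trait units); positive mean gives directional dominance, the
#'   mechanism that makes parental distance predictive of heterosis.
#' @param env_sd SD of the i.i.d. environment residual per year x site.
#' @param n_years,n_sites environment grid.
#' @param traits character vector of trait codes.
#' @param trait_mean baseline value of every trait (trait units).
#' @param seed integer seed; all randomness flows from one stream seeded
#'   once with it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_males = 4, n_females = 282, n_subpops = 3,
                       fst = 0.15, n_snps = 5000, n_ssr = 198,
                       ssr_allele_range = c(1, 10),
                       snp_missing_rate = 0.05, ssr_missing_rate = 0.02,
                       n_qtl_per_trait = 20, additive_sd = 0.5,
                       dominance_mean = 0.3, dominance_sd = 0.1,
                       env_sd = 1, n_years = 2, n_sites = 2,
                       traits = c("PH", "BW", "LP", "BN", "FL",
                                  "FS", "MIC", "FU", "FE", "SCI"),
                       trait_mean = 50, seed = 1) {
  cfg <- list(n_males = as.integer(n_males), n_females = as.integer(n_females),
              n_subpops = as.integer(n_subpops), fst = fst,
              n_snps = as.integer(n_snps), n_ssr = as.integer(n_ssr),
              ssr_allele_range = as.integer(ssr_allele_range),
              snp_missing_rate = snp_missing_rate,
              ssr_missing_rate = ssr_missing_rate,
              n_qtl_per_trait = as.integer(n_qtl_per_trait),
              additive_sd = additive_sd, dominance_mean = dominance_mean,
              dominance_sd = dominance_sd, env_sd = env_sd,
              n_years = as.integer(n_years), n_sites = as.integer(n_sites),
              traits = as.character(traits), trait_mean = trait_mean,
              seed = as.integer(seed))
  with(cfg, {
    if (n_males < 1 || n_females < 1) stop("need at least one parent per sex")
    if (n_snps < 1 || n_ssr < 1) stop("need at least one marker of each type")
    if (n_subpops < 1) stop("n_subpops must be >= 1")
    if (fst < 0 || fst >= 1) stop("fst must be in [0,1)")
    if (any(c(snp_missing_rate, ssr_missing_rate) < 0) ||
        any(c(snp_missing_rate, ssr_missing_rate) > 1))
      stop("missing rates must be in [0,1]")
    if (length(ssr_allele_range) != 2 || ssr_allele_range[1] < 1 ||
        ssr_allele_range[1] > ssr_allele_range[2])
      stop("ssr_allele_range must be (min,max) with 1 <= min <= max")
    if (n_qtl_per_trait < 1 || n_qtl_per_trait > n_snps)
      stop("n_qtl_per_trait must be in [1, n_snps]")
    if (n_years < 1 || n_sites < 1) stop("need >= 1 year and site")
    if (length(traits) < 1) stop("need >= 1 trait")
  })
  structure(cfg, class = "sim_config")
}

# subpopulation sizes; the 3-subpop default mirrors an elite/historic/exotic
# cultivar panel composition of 136/103/47 out of 286
subpop_sizes <- function(n_parents, n_subpops) {
  if (n_subpops == 3) {
    prop <- c(elite = 136, historic = 103, exotic = 47) / 286
  } else {
    prop <- stats::setNames(rep(1 / n_subpops, n_subpops),
                            paste0("subpop", seq_len(n_subpops)))
  }
  raw <- prop * n_parents
  sz <- floor(raw + 1e-9) # guard against 136.0 landing at 135.999...
  rem <- n_parents - sum(sz)
  if (rem > 0) { # largest-remainder apportionment
    ord <- order(-(raw - sz))
    sz[ord[seq_len(rem)]] <- sz[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(sz), names(prop))
}

#' Simulate a structured panel of inbred parents
#'
#' Draws fully homozygous (inbred) parents from `n_subpops` subpopulations.
#' SNP alternate-allele frequencies follow the Balding-Nichols construction:
#' an ancestral frequency `p ~ U(0.05, 0.95)` per site, and each
#' subpopulation frequency `~ Beta(p(1-F)/F, (1-p)(1-F)/F)` (all equal to
#' `p` when `fst = 0`). SSR allele frequencies are Dirichlet: ancestral
#' weights `~ Dirichlet(1,...,1)` over `k` alleles (`k` uniform in
#' `ssr_allele_range`), perturbed per subpopulation as
#' `Dirichlet(w (1-F)/F)`. Missing calls are then injected independently at
#' the configured rates. The complete pre-dropout SNP matrix is kept in the
#' truth object so phenotypes can be generated from the true genomes.
#'
#' @param config a [sim_config].
#' @return A list with elements `ssr` ([ssr_genotypes]), `snp`
#'   ([snp_genotypes]), `meta` (data.frame id / role / origin / subpop) and
#'   `truth` (list: `subpop_of_parent`, `qtl_sites`, `additive_effects`,
#'   `dominance_effects`, `trait_means`, `snp_complete`, `subpop_freq`).
#' @export
simulate_parents <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_par <- cfg$n_males + cfg$n_females
  sz <- subpop_sizes(n_par, cfg$n_subpops)
  classes <- names(sz)

  ids <- c(sprintf("M%02d", seq_len(cfg$n_males)),
           sprintf("F%03d", seq_len(cfg$n_females)))
  # males are elite testers: always subpopulation 1
  subpop <- integer(n_par)
  subpop[seq_len(cfg$n_males)] <- 1L
  pool <- rep(seq_along(sz), sz)
  pool <- pool[-seq_len(min(cfg$n_males, sum(pool == 1L)))]
  if (length(pool) < cfg$n_females)
    pool <- c(pool, rep(1L, cfg$n_females - length(pool)))
  subpop[-seq_len(cfg$n_males)] <- sample(pool, cfg$n_females)

  # --- SNP panel (RNG order: ancestral freqs, subpop freqs, genotypes,
  #     dropout mask) ---
  p_anc <- stats::runif(cfg$n_snps, 0.05, 0.95)
  freq <- matrix(NA_real_, cfg$n_subpops, cfg$n_snps)
  for (s in seq_len(cfg$n_subpops)) {
    if (cfg$fst == 0) {
      freq[s, ] <- p_anc
    } else {
      shp <- (1 - cfg$fst) / cfg$fst
      freq[s, ] <- stats::rbeta(cfg$n_snps, p_anc * shp, (1 - p_anc) * shp)
    }
  }
  geno <- matrix(0L, n_par, cfg$n_snps)
  for (i in seq_len(n_par)) # inbred: one allele draw, doubled
    geno[i, ] <- 2L * (stats::runif(cfg$n_snps) < freq[subpop[i], ])
  snp_complete <- geno
  if (cfg$snp_missing_rate > 0)
    geno[matrix(stats::runif(length(geno)) < cfg$snp_missing_rate,
                nrow(geno))] <- NA_integer_

  n_chrom <- 26L # tetraploid-cotton-style karyotype
  chrom_of <- sort(rep_len(seq_len(n_chrom), cfg$n_snps))
  pos <- unlist(lapply(split(seq_len(cfg$n_snps), chrom_of), function(idx)
    sort(sample.int(1e8, length(idx)))), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  sites <- data.frame(chrom = sprintf("chr%02d", chrom_of), pos = pos,
                      ref = ref, alt = alt, stringsAsFactors = FALSE)
  snp <- snp_genotypes(ids, sites, geno)

  # --- SSR panel ---
  k_alleles <- sample(seq(cfg$ssr_allele_range[1], cfg$ssr_allele_range[2]),
                      cfg$n_ssr, replace = TRUE)
  ssr_a1 <- matrix(NA_integer_, n_par, cfg$n_ssr)
  for (j in seq_len(cfg$n_ssr)) {
    k <- k_alleles[j]
    codes <- sort(sample(seq(100L, 400L, by = 2L), k)) # fragment lengths
    w <- stats::rgamma(k, 1); w <- w / sum(w)          # Dirichlet(1,..,1)
    for (s in seq_len(cfg$n_subpops)) {
      if (cfg$fst == 0 || k == 1) {
        f <- w
      } else {
        g <- stats::rgamma(k, w * (1 - cfg$fst) / cfg$fst)
        f <- if (sum(g) > 0) g / sum(g) else w
      }
      members <- which(subpop == s)
      ssr_a1[members, j] <- codes[sample.int(k, length(members),
                                             replace = TRUE, prob = f)]
    }
  }
  if (cfg$ssr_missing_rate > 0)
    ssr_a1[matrix(stats::runif(length(ssr_a1)) < cfg$ssr_missing_rate,
                  nrow(ssr_a1))] <- NA_integer_
  markers <- data.frame(marker = sprintf("SSR%03d", seq_len(cfg$n_ssr)),
                        chrom = sprintf("chr%02d",
                                        rep_len(seq_len(n_chrom), cfg$n_ssr)),
                        stringsAsFactors = FALSE)
  ssr <- ssr_genotypes(ids, markers, ssr_a1, ssr_a1) # inbred: homozygous

  # --- trait architecture ---
  qtl <- a_eff <- d_eff <- stats::setNames(vector("list", length(cfg$traits)),
                                           cfg$traits)
  for (tr in cfg$traits) {
    qtl[[tr]] <- sort(sample.int(cfg$n_snps, cfg$n_qtl_per_trait))
    a_eff[[tr]] <- stats::rnorm(cfg$n_qtl_per_trait, 0, cfg$additive_sd)
    d_eff[[tr]] <- stats::rnorm(cfg$n_qtl_per_trait, cfg$dominance_mean,
                                cfg$dominance_sd)
  }
  meta <- data.frame(id = ids,
                     role = rep(c("male", "female"),
                                c(cfg$n_males, cfg$n_females)),
                     origin = classes[subpop],
                     subpop = subpop, stringsAsFactors = FALSE)
  truth <- list(subpop_of_parent = stats::setNames(subpop, ids),
                qtl_sites = qtl, additive_effects = a_eff,
                dominance_effects = d_eff,
                trait_means = stats::setNames(rep(cfg$trait_mean,
                                                  length(cfg$traits)),
                                              cfg$traits),
                snp_complete = snp_genotypes(ids, sites, snp_complete),
                subpop_freq = freq)
  list(ssr = ssr, snp = snp, meta = meta, truth = truth)
}

#' Build a North Carolina II factorial mating design
#'
#' Returns the complete factorial: every male crossed to every female, one
#' cross per pair, ordered female-major within male, with deterministic
#' cross ids `"<male>x<female>"`.
#'
#' @param male_ids,female_ids disjoint, duplicate-free id vectors.
#' @return A data.frame of class `ncii_design` with columns `cross`, `male`,
#'   `female`.
#' @export
make_ncii_design <- function(male_ids, female_ids) {
  male_ids <- as.character(male_ids); female_ids <- as.character(female_ids)
  if (length(male_ids) == 0 || length(female_ids) == 0)
    stop("both parent sets must be non-empty")
  if (anyDuplicated(male_ids) || anyDuplicated(female_ids))
    stop("duplicate parent ids within a sex")
  overlap <- intersect(male_ids, female_ids)
  if (length(overlap))
    stop("ids used as both male and female: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  d <- data.frame(male = rep(male_ids, each = length(female_ids)),
                  female = rep(female_ids, times = length(male_ids)),
                  stringsAsFactors = FALSE)
  d <- data.frame(cross = paste0(d$male, "x", d$female), d,
                  stringsAsFactors = FALSE)
  class(d) <- c("ncii_design", "data.frame")
  d
}

#' Derive F1 genotypes from inbred parents
#'
#' Each F1 receives one allele from each homozygous parent, so its dosage is
#' the parental dosage mean; it is heterozygous exactly where the parents
#' carry different alleles, and missing wherever either parent is missing.
#'
#' @param parents an [snp_genotypes] object covering all design parents;
#'   every call must be homozygous or missing.
#' @param design an [make_ncii_design()] table.
#' @return An [snp_genotypes] object with one row per cross (ids = cross ids).
#' @export
derive_f1_genotypes <- function(parents, design) {
  stopifnot(inherits(parents, "snp_genotypes"))
  absent <- setdiff(unique(c(design$male, design$female)), parents$ids)
  if (length(absent))
    stop("design parents missing from genotypes: ",
         paste(utils::head(absent, 5), collapse = ", "))
  if (any(parents$geno == 1L, na.rm = TRUE))
    stop("heterozygous parent call encountered; parents must be inbred")
  f1 <- (parents$geno[design$male, , drop = FALSE] +
           parents$geno[design$female, , drop = FALSE]) / 2L
  snp_genotypes(design$cross, parents$sites,
                matrix(as.integer(f1), nrow(f1), dimnames = NULL))
}

#' Simulate multi-environment phenotypes
#'
#' Trait value for entity `i` in one environment:
#' `mu_t + sum_l a_l x_il + sum_l d_l h_il + e`, where `x_il` codes the
#' QTL genotype -1/0/+1 (alt homozygote / heterozygote / ref homozygote is
#' +1/0/-1 on dosage-1 scale), `h_il` is the heterozygosity indicator and
#' `e ~ N(0, env_sd^2)` independently per year x site. Entities with a
#' missing call at any QTL of a trait get `NA` for that trait.
#'
#' @param parents,f1s [snp_genotypes] for parents and crosses (site sets
#'   must match).
#' @param design the mating design (unused beyond validation that all
#'   crosses are genotyped).
#' @param truth,config the truth and config objects from the simulator.
#' @return A data.frame (`entity`, `trait`, `year`, `site`, `value`): one
#'   record per entity x trait x year x site.
#' @export
simulate_phenotypes <- function(parents, f1s, design, truth, config) {
  stopifnot(inherits(parents, "snp_genotypes"), inherits(f1s, "snp_genotypes"))
  if (!all(design$cross %in% f1s$ids))
    stop("design crosses missing from F1 genotypes")
  geno <- rbind(parents$geno, f1s$geno)
  ids <- c(parents$ids, f1s$ids)
  n_env <- config$n_years * config$n_sites
  envs <- expand.grid(year = seq_len(config$n_years),
                      site = seq_len(config$n_sites))
  recs <- vector("list", length(config$traits))
  for (ti in seq_along(config$traits)) {
    tr <- config$traits[ti]
    q <- truth$qtl_sites[[tr]]
    gq <- geno[, q, drop = FALSE]
    x <- gq - 1L
    h <- (gq == 1L) * 1L
    gval <- truth$trait_means[[tr]] +
      as.vector(x %*% truth$additive_effects[[tr]]) +
      as.vector(h %*% truth$dominance_effects[[tr]])
    gval[rowSums(is.na(gq)) > 0] <- NA_real_
    noise <- if (config$env_sd > 0)
      stats::rnorm(length(ids) * n_env, 0, config$env_sd) else 0
    recs[[ti]] <- data.frame(
      entity = rep(ids, times = n_env),
      trait = tr,
      year = rep(envs$year, each = length(ids)),
      site = rep(envs$site, each = length(ids)),
      value = rep(gval, times = n_env) + noise,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
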