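#' Run the full genetic-distance / heterosis pipeline
#'
#' Orchestrates the stages in analysis order: read and filter genotypes,
#' compute both GD matrices, per-cross GD, UPGMA heterotic grouping of the
#' female parents (groups inherited by the F1s), environment aggregation
#' and heterosis, GD and parent-performance correlations within each male
#' population, and group comparisons of F1 performance. All results are
#' written as TSV (plus Newick trees) into `out_dir` together with a
#' manifest recording package version, parameters and input checksums, so
#' a bundle can be reproduced exactly; rerunning the same configuration
#' gives a byte-identical bundle.
#'
#' @param ssr_path SSR genotype TSV ([read_ssr_table()] dialect).
#' @param vcf_path SNP genotypes, VCF v4.2.
#' @param pheno_path phenotype TSV: `entity`, `trait`, `year`, `site`,
#'   `value`.
#' @param design_path design TSV: `cross`, `male`, `female`.
#' @param out_dir output directory (created if absent).
#' @param max_missing,min_maf SNP filter thresholds (see [filter_snps()]).
#' @param k_snp,k_ssr heterotic group counts cut from the SNP / SSR trees.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @param verbose emit stage messages.
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(ssr_path, vcf_path, pheno_path, design_path,
                         out_dir, max_missing = 0.30, min_maf = 0.05,
                         k_snp = 5, k_ssr = 3, seed = 1, verbose = TRUE) {
  inputs <- c(ssr = ssr_path, vcf = vcf_path, pheno = pheno_path,
              design = design_path)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent))
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  say <- function(...) if (verbose) message("[", ..., "]")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, name) utils::write.table(
    d, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  say("read: genotypes, phenotypes, design")
  ssr <- read_ssr_table(ssr_path)
  snp <- read_vcf(vcf_path)
  pheno <- utils::read.delim(pheno_path, stringsAsFactors = FALSE)
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  class(design) <- c("ncii_design", "data.frame")

  say("filter: SSR polymorphism; SNP missingness <= ", max_missing,
      ", MAF >= ", min_maf)
  ssr_f <- filter_polymorphic_ssr(ssr)
  snp_f <- filter_snps(snp, max_missing = max_missing, min_maf = min_maf)
  ms <- marker_summary(ssr_f, snp_f)
  tsv(data.frame(key = c("n_ssr_markers", "n_polymorphic_alleles",
                         "mean_alleles_per_marker", "n_snp_sites"),
                 value = c(ms$n_markers, ms$n_polymorphic_alleles,
                           round(ms$mean_alleles_per_marker, 2),
                           nrow(snp_f$sites))),
      "marker_summary.tsv")

  say("distance: Nei band-sharing (SSR) and 1-IBS (SNP)")
  dm_ssr <- gd_ssr_matrix(ssr_f)
  dm_snp <- gd_snp_matrix(snp_f)
  write_gd_matrix(dm_ssr, file.path(out_dir, "gd_ssr.tsv"))
  write_gd_matrix(dm_snp, file.path(out_dir, "gd_snp.tsv"))
  cgd <- cross_gd(design, dm_ssr, dm_snp)
  tsv(cgd, "cross_gd.tsv")
  tsv(gd_population_summary(cgd), "gd_population_summary.tsv")

  say("cluster: UPGMA, k=", k_snp, " (SNP) / k=", k_ssr, " (SSR)")
  females <- sort(unique(design$female))
  tree_snp <- upgma_cluster(dm_snp[females, females])
  tree_ssr <- upgma_cluster(dm_ssr[females, females])
  write_newick(tree_snp, file.path(out_dir, "upgma_snp.nwk"))
  write_newick(tree_ssr, file.path(out_dir, "upgma_ssr.nwk"))
  grp_snp <- cut_groups(tree_snp, k = k_snp)
  grp_ssr <- cut_groups(tree_ssr, k = k_ssr)
  f1_grp <- assign_f1_groups(grp_snp, design)
  tsv(data.frame(female = names(grp_snp$groups), group_snp = grp_snp$groups,
                 group_ssr = grp_ssr$groups[names(grp_snp$groups)]),
      "female_groups.tsv")
  tsv(data.frame(cross = names(f1_grp$groups), group = f1_grp$groups),
      "f1_groups.tsv")
  tsv(group_gd_summary(f1_grp, cgd), "group_gd_summary.tsv")

  say("heterosis: aggregate ", length(unique(paste(pheno$year, pheno$site))),
      " environments; MPH/BPH")
  means <- aggregate_environments(pheno)
  het <- compute_heterosis(design, means)
  tsv(round_cols(het, c("F1", "MP", "HP", "MPH", "BPH")), "heterosis.tsv")
  tsv(round_cols(heterosis_summary(het),
                 c("mph_mean", "mph_min", "mph_max",
                   "bph_mean", "bph_min", "bph_max")),
      "heterosis_summary.tsv")
  tsv(round_cols(heterosis_summary(het, by = stats::setNames(het$male, het$cross)),
                 c("mph_mean", "mph_min", "mph_max",
                   "bph_mean", "bph_min", "bph_max")),
      "heterosis_summary_by_male.tsv")

  say("associate: GD vs F1/MPH/BPH; parents vs F1; group comparisons")
  cors <- lapply(c(F1 = "F1", MPH = "MPH", BPH = "BPH"), function(m)
    correlate_gd_with(m, cgd, het))
  for (m in names(cors))
    tsv(round_cols(cors[[m]], c("r", "p"), 4),
        paste0("cor_gd_", tolower(m), ".tsv"))
  cor_pf1 <- correlate_parent_with_f1(het)
  tsv(round_cols(cor_pf1, c("r", "p"), 4), "cor_parent_f1.tsv")
  f1_vals <- het[!is.na(het$F1), c("trait", "cross", "F1")]
  cmp <- compare_groups(data.frame(trait = f1_vals$trait,
                                   group = paste0("G",
                                     f1_grp$groups[f1_vals$cross]),
                                   value = f1_vals$F1))
  tsv(round_cols(cmp, c("mean_a", "mean_b", "statistic", "p", "p_adj"), 4),
      "group_comparison.tsv")

  manifest <- data.frame(
    key = c("package", "version", paste0("input_", names(inputs)),
            paste0("md5_", names(inputs)),
            "max_missing", "min_maf", "k_snp", "k_ssr", "seed"),
    value = c("gdheterosis",
              as.character(utils::packageVersion("gdheterosis")),
              unname(inputs), unname(tools::md5sum(inputs)),
              max_missing, min_maf, k_snp, k_ssr, seed))
  tsv(manifest, "manifest.tsv")
  say("done: bundle at ", out_dir)
  invisible(list(ssr = ssr_f, snp = snp_f, design = design,
                 dm_ssr = dm_ssr, dm_snp = dm_snp, cross_gd = cgd,
                 tree_snp = tree_snp, tree_ssr = tree_ssr,
                 female_groups = grp_snp, f1_groups = f1_grp,
                 means = means, heterosis = het, correlations = cors,
                 cor_parent_f1 = cor_pf1, group_comparison = cmp,
                 marker_summary = ms))
}

round_cols <- function(d, cols, digits = 2) {
  for (cl in intersect(cols, names(d))) d[[cl]] <- round(d[[cl]], digits)
  d
}

#' One-command synthetic demonstration
#'
#' Simulates a panel at the default factorial shape (4 males x 282
#' females, three origin subpopulations) with a reduced SNP count, writes
#' the simulated inputs (VCF, SSR TSV, phenotype TSV, design TSV, plus a
#' ground-truth sidecar TSV), and runs [run_pipeline()] on them. The same
#' seed always reproduces the identical bundle.
#'
#' @param seed integer seed driving the simulation.
#' @param out_dir output directory.
#' @param config a [sim_config]; defaults to `sim_config(seed = seed,
#'   n_snps = 1000)`.
#' @param ... passed to [run_pipeline()] (e.g. `k_snp`).
#' @return Invisibly, the [run_pipeline()] result list, plus `sim` (the
#'   simulated panel).
#' @export
run_demo <- function(seed = 1, out_dir = tempfile("gdhet_demo"),
                     config = sim_config(seed = seed, n_snps = 1000), ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_parents(config)
  males <- sim$meta$id[sim$meta$role == "male"]
  females <- sim$meta$id[sim$meta$role == "female"]
  design <- make_ncii_design(males, females)
  f1 <- derive_f1_genotypes(sim$truth$snp_complete, design)
  pheno <- simulate_phenotypes(sim$truth$snp_complete, f1, design,
                               sim$truth, config)
  paths <- list(ssr = file.path(out_dir, "parents_ssr.tsv"),
                vcf = file.path(out_dir, "parents_snp.vcf"),
                pheno = file.path(out_dir, "phenotypes.tsv"),
                design = file.path(out_dir, "design.tsv"),
                truth = file.path(out_dir, "truth_synthetic.tsv"))
  write_ssr_table(sim$ssr, paths$ssr)
  write_vcf(sim$snp, paths$vcf)
  utils::write.table(pheno, paths$pheno, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(design), paths$design, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(id = sim$meta$id, role = sim$meta$role,
               origin = sim$meta$origin, subpop = sim$meta$subpop),
    paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- run_pipeline(paths$ssr, paths$vcf, paths$pheno, paths$design,
                      out_dir = file.path(out_dir, "results"),
                      seed = seed, ...)
  res$sim <- sim
  invisible(res)
}
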