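#' UPGMA clustering of a genetic distance matrix
#'
#' Average-linkage agglomerative clustering; the merge heights of UPGMA on a
#' proper distance are non-decreasing (ultrametric tree). Labels are sorted
#' lexicographically before clustering so the result does not depend on the
#' input order of accessions; this also makes tie-breaking deterministic.
#'
#' @param dm a `gd_matrix` (no undefined entries among clustered labels).
#' @return An object of class `gd_dendrogram` wrapping the
#'   [stats::hclust] merge history plus the (reordered) distance matrix.
#' @export
upgma_cluster <- function(dm) {
  if (nrow(dm) < 2) stop("need at least two accessions to cluster")
  if (anyNA(dm)) {
    bad <- which(is.na(unclass(dm)) & upper.tri(dm), arr.ind = TRUE)
    stop("undefined distances for pair(s): ",
         paste(utils::head(paste(rownames(dm)[bad[, 1]],
                                 colnames(dm)[bad[, 2]], sep = "-"), 5),
               collapse = ", "))
  }
  ord <- order(rownames(dm))
  m <- unclass(dm)[ord, ord]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  structure(list(hclust = hc, dm = m), class = "gd_dendrogram")
}

#' @exportS3Method base::print
print.gd_dendrogram <- function(x, ...) {
  cat(sprintf("UPGMA dendrogram: %d leaves, merge heights %.3f-%.3f\n",
              length(x$hclust$labels), min(x$hclust$height),
              max(x$hclust$height)))
  invisible(x)
}

#' Cut a dendrogram into k heterotic groups
#'
#' Cuts below the `k-1` highest merges. Group ids are reassigned
#' deterministically: decreasing group size, ties broken by the
#' lexicographically smallest member label. Mean within-group GD is
#' computed from the distance matrix carried by the tree.
#'
#' @param tree a [upgma_cluster()] result.
#' @param k number of groups, `1 <= k <=` leaf count.
#' @return A list of class `cluster_assignment`: `groups` (named integer
#'   vector label -> group id in `1..k`), `k`, `sizes`, `mean_within_gd`.
#' @export
cut_groups <- function(tree, k) {
  stopifnot(inherits(tree, "gd_dendrogram"))
  n <- length(tree$hclust$labels)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  raw <- stats::cutree(tree$hclust, k = k)
  leaders <- vapply(split(names(raw), raw), min, character(1))
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), leaders)
  remap <- integer(length(ord)); remap[ord] <- seq_along(ord)
  groups <- stats::setNames(remap[raw], names(raw))
  wgd <- vapply(seq_len(k), function(g) {
    mem <- names(groups)[groups == g]
    if (length(mem) < 2) return(NA_real_)
    sub <- tree$dm[mem, mem]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  structure(list(groups = groups, k = as.integer(k),
                 sizes = as.integer(table(groups)),
                 mean_within_gd = wgd),
            class = "cluster_assignment")
}

#' @exportS3Method base::print
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("%d groups over %d labels; sizes: %s\n", x$k,
              length(x$groups), paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Propagate female-parent groups to F1 crosses
#'
#' In an NC II factorial every female meets every male, so a female-parent
#' grouping induces a grouping of crosses in which each group is female
#' count times male count large.
#'
#' @param female_groups a `cluster_assignment` over female parents.
#' @param design an [make_ncii_design()] table.
#' @return A `cluster_assignment` over cross ids.
#' @export
assign_f1_groups <- function(female_groups, design) {
  stopifnot(inherits(female_groups, "cluster_assignment"))
  ungrouped <- setdiff(unique(design$female), names(female_groups$groups))
  if (length(ungrouped))
    stop("females without a group: ",
         paste(utils::head(ungrouped, 5), collapse = ", "))
  groups <- stats::setNames(female_groups$groups[design$female], design$cross)
  structure(list(groups = groups, k = female_groups$k,
                 sizes = as.integer(table(factor(groups,
                                                 levels = seq_len(female_groups$k)))),
                 mean_within_gd = rep(NA_real_, female_groups$k)),
            class = "cluster_assignment")
}

#' Mean genetic distance per heterotic group
#'
#' @param assignment a `cluster_assignment` over crosses.
#' @param cross_gd a [cross_gd()] table.
#' @return data.frame (`group`, `n`, `mean_gd_ssr`, `mean_gd_snp`).
#' @export
group_gd_summary <- function(assignment, cross_gd) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  miss <- setdiff(cross_gd$cross, names(assignment$groups))
  if (length(miss))
    stop("crosses without a group: ",
         paste(utils::head(miss, 5), collapse = ", "))
  grp <- assignment$groups[cross_gd$cross]
  agg <- function(v) vapply(split(v, grp), function(z)
    mean(z, na.rm = TRUE), numeric(1))
  data.frame(group = sort(unique(grp)),
             n = as.integer(table(grp)),
             mean_gd_ssr = agg(cross_gd$gd_ssr),
             mean_gd_snp = agg(cross_gd$gd_snp),
             row.names = NULL)
}

#' Export a dendrogram in Newick format
#'
#' Branch lengths are merge-height differences (the ultrametric tree), via
#' \pkg{ape}.
#'
#' @param tree a [upgma_cluster()] result.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "gd_dendrogram"))
  ape::write.tree(ape::as.phylo(tree$hclust), file = path)
  invisible(path)
}
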