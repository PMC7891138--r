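#' Pearson correlation with significance
#'
#' Sample Pearson coefficient over pairwise-complete observations with a
#' two-sided p-value from the t transform `r * sqrt((n-2)/(1-r^2))` on
#' `n-2` degrees of freedom (as [stats::cor.test()] computes it). Fewer
#' than three complete pairs, or zero variance in either series, yields a
#' flagged undefined result rather than propagating NaN.
#'
#' @param x,y numeric vectors of equal length.
#' @return list: `r`, `p`, `n` (complete pairs), `mark` (`""`, `"*"` for
#'   `p < 0.05`, `"**"` for `p < 0.01`), `note` (`""` or the reason the
#'   correlation is undefined).
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3)
    return(list(r = NA_real_, p = NA_real_, n = n, mark = "",
                note = "fewer than 3 complete pairs"))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, mark = "",
                note = "zero variance"))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        alternative = "two.sided")
  p <- ct$p.value
  list(r = unname(ct$estimate), p = p, n = n, mark = sig_mark(p), note = "")
}

#' Significance mark for a p-value
#'
#' `"**"` for `p < 0.01`, `"*"` for `p < 0.05`, `""` otherwise (or for NA).
#' @param p numeric vector of p-values.
#' @return character vector of marks.
#' @export
sig_mark <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

cor_row <- function(stratum, trait, xvar, yvar, x, y) {
  ct <- pearson_cor(x, y)
  data.frame(stratum = stratum, trait = trait, x = xvar, y = yvar,
             n = ct$n, r = ct$r, p = ct$p, mark = ct$mark, note = ct$note,
             stringsAsFactors = FALSE)
}

#' Correlate genetic distance with hybrid performance or heterosis
#'
#' Within each male-parent population (each male's set of crosses is a
#' stratum, because the male is a design factor) and for each trait,
#' computes the Pearson correlation of cross GD — under both marker
#' systems — with the chosen response: aggregated F1 performance, MPH or
#' BPH.
#'
#' @param metric `"F1"`, `"MPH"` or `"BPH"`.
#' @param cross_gd a [cross_gd()] table.
#' @param heterosis a [compute_heterosis()] table.
#' @return A correlation data.frame: `stratum` (male id), `trait`, `x`
#'   (`"gd_ssr"`/`"gd_snp"`), `y`, `n`, `r`, `p`, `mark`, `note`.
#' @export
correlate_gd_with <- function(metric = c("F1", "MPH", "BPH"),
                              cross_gd, heterosis) {
  metric <- match.arg(metric)
  d <- merge(heterosis, cross_gd[, c("cross", "gd_ssr", "gd_snp")],
             by = "cross", sort = FALSE)
  y <- d[[metric]]
  rows <- lapply(split(seq_len(nrow(d)), list(d$male, d$trait), drop = TRUE),
                 function(idx) {
    rbind(cor_row(d$male[idx][1], d$trait[idx][1], "gd_ssr", metric,
                  d$gd_ssr[idx], y[idx]),
          cor_row(d$male[idx][1], d$trait[idx][1], "gd_snp", metric,
                  d$gd_snp[idx], y[idx]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$stratum, out$trait, out$x), ]
}

#' Correlate parent performance with F1 performance and heterosis
#'
#' Per male population and trait: Pearson correlation of the mid-parent
#' value with the F1 value, with MPH and with BPH. The parent statistic is
#' the mid-parent mean (recorded in the `x` column of the output).
#'
#' @param heterosis a [compute_heterosis()] table (carries F1, MP, MPH,
#'   BPH per cross x trait).
#' @return A correlation data.frame as in [correlate_gd_with()].
#' @export
correlate_parent_with_f1 <- function(heterosis) {
  rows <- lapply(split(seq_len(nrow(heterosis)),
                       list(heterosis$male, heterosis$trait), drop = TRUE),
                 function(idx) {
    d <- heterosis[idx, ]
    rbind(cor_row(d$male[1], d$trait[1], "mid_parent", "F1", d$MP, d$F1),
          cor_row(d$male[1], d$trait[1], "mid_parent", "MPH", d$MP, d$MPH),
          cor_row(d$male[1], d$trait[1], "mid_parent", "BPH", d$MP, d$BPH))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$stratum, out$trait, out$y), ]
}

#' Pairwise group comparisons of trait values
#'
#' All pairwise Welch two-sample t-tests between groups, Holm-adjusted
#' within each trait (family-wise alpha 0.05). Pairs where either group has
#' fewer than two observations or zero variance in both groups are flagged
#' untestable.
#'
#' @param values data.frame with columns `trait`, `group`, `value`.
#' @param alpha significance level applied to the adjusted p.
#' @return data.frame: `trait`, `group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `statistic`, `p`, `p_adj`, `significant`,
#'   `testable`.
#' @export
compare_groups <- function(values, alpha = 0.05) {
  need <- c("trait", "group", "value")
  if (!all(need %in% names(values)))
    stop("need columns: ", paste(need, collapse = ", "))
  values <- values[!is.na(values$value), ]
  out <- lapply(split(values, values$trait), function(d) {
    grps <- sort(unique(as.character(d$group)))
    if (length(grps) < 2) return(NULL)
    prs <- utils::combn(grps, 2)
    res <- lapply(seq_len(ncol(prs)), function(i) {
      va <- d$value[d$group == prs[1, i]]
      vb <- d$value[d$group == prs[2, i]]
      testable <- length(va) >= 2 && length(vb) >= 2 &&
        (stats::sd(va) > 0 || stats::sd(vb) > 0)
      if (testable) {
        tt <- stats::t.test(va, vb, var.equal = FALSE)
        stat <- unname(tt$statistic); p <- tt$p.value
      } else {
        stat <- NA_real_; p <- NA_real_
      }
      data.frame(trait = d$trait[1], group_a = prs[1, i], group_b = prs[2, i],
                 n_a = length(va), n_b = length(vb),
                 mean_a = mean(va), mean_b = mean(vb),
                 statistic = stat, p = p, testable = testable,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res$p_adj <- NA_real_
    res$p_adj[res$testable] <- stats::p.adjust(res$p[res$testable],
                                               method = "holm")
    res$significant <- !is.na(res$p_adj) & res$p_adj < alpha
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
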