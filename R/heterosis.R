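#' Aggregate phenotypes over environments
#'
#' Unweighted arithmetic mean over the year x site records of each
#' entity x trait, with the number of contributing (non-missing) records.
#'
#' @param phenotypes data.frame with columns `entity`, `trait`, `year`,
#'   `site`, `value` (one record per entity x trait x environment).
#' @return data.frame (`entity`, `trait`, `mean`, `n_env`); `mean` is `NA`
#'   when every record is missing.
#' @export
aggregate_environments <- function(phenotypes) {
  need <- c("entity", "trait", "value")
  if (!all(need %in% names(phenotypes)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(phenotypes$entity, phenotypes$trait, drop = TRUE)
  mn <- tapply(phenotypes$value, key, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NA_real_
  })
  nn <- tapply(phenotypes$value, key, function(v) sum(!is.na(v)))
  first <- !duplicated(key)
  out <- data.frame(entity = phenotypes$entity[first],
                    trait = phenotypes$trait[first],
                    mean = as.numeric(mn[as.character(key[first])]),
                    n_env = as.integer(nn[as.character(key[first])]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mid-parent and best-parent heterosis per cross and trait
#'
#' With `F1` the hybrid mean, `P1`/`P2` the parental means,
#' `MP = (P1+P2)/2` and `HP = max(P1, P2)`:
#' `MPH = (F1 - MP)/MP * 100` and `BPH = (F1 - HP)/HP * 100` (percent).
#' A row is flagged `"missing"` when any of the three means is absent, and
#' `"undefined"` when `MP` or `HP` is zero; `"nonpositive_parent"` marks
#' rows where a non-positive denominator makes ratio heterosis
#' sign-ambiguous. Percentages are carried at full precision.
#'
#' @param design an [make_ncii_design()] table.
#' @param means entity x trait means from [aggregate_environments()]
#'   (crosses keyed by cross id).
#' @return data.frame of class `heterosis_table`: `cross`, `male`, `female`,
#'   `trait`, `F1`, `MP`, `HP`, `MPH`, `BPH`, `flag`.
#' @export
compute_heterosis <- function(design, means) {
  traits <- unique(means$trait)
  val <- stats::setNames(means$mean, paste(means$entity, means$trait, sep = "\r"))
  rows <- lapply(traits, function(tr) {
    f1 <- unname(val[paste(design$cross, tr, sep = "\r")])
    p1 <- unname(val[paste(design$male, tr, sep = "\r")])
    p2 <- unname(val[paste(design$female, tr, sep = "\r")])
    mp <- (p1 + p2) / 2
    hp <- pmax(p1, p2)
    mph <- (f1 - mp) / mp * 100
    bph <- (f1 - hp) / hp * 100
    flag <- rep("", nrow(design))
    miss <- is.na(f1) | is.na(p1) | is.na(p2)
    undef <- !miss & (mp == 0 | hp == 0)
    caution <- !miss & !undef & (mp < 0 | hp < 0)
    mph[miss | undef] <- NA_real_
    bph[miss | undef] <- NA_real_
    flag[caution] <- "nonpositive_parent"
    flag[undef] <- "undefined"
    flag[miss] <- "missing"
    data.frame(cross = design$cross, male = design$male,
               female = design$female, trait = tr,
               F1 = f1, MP = mp, HP = hp, MPH = mph, BPH = bph,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("heterosis_table", "data.frame")
  out
}

#' Per-trait heterosis summary
#'
#' Mean, min and max of MPH and BPH over defined rows, plus the percentage
#' of crosses with positive MPH and positive BPH (1 decimal), optionally
#' stratified (e.g. by male parent or heterotic group).
#'
#' @param table a [compute_heterosis()] table.
#' @param by optional vector, same length as `nrow(table)` or a named
#'   vector keyed by cross id, defining strata.
#' @return data.frame with one row per (stratum x) trait.
#' @export
heterosis_summary <- function(table, by = NULL) {
  if (!is.null(by) && !is.null(names(by))) by <- unname(by[table$cross])
  strata <- if (is.null(by)) rep("all", nrow(table)) else as.character(by)
  keys <- split(seq_len(nrow(table)),
                list(stratum = strata, trait = table$trait), drop = TRUE)
  rows <- lapply(keys, function(idx) {
    d <- table[idx, ]
    smry <- function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
      c(mean(v), min(v), max(v), round(100 * mean(v > 0), 1))
    }
    m <- smry(d$MPH); b <- smry(d$BPH)
    data.frame(stratum = strata[idx][1], trait = d$trait[1],
               n = sum(!is.na(d$MPH)),
               mph_mean = m[1], mph_min = m[2], mph_max = m[3],
               pct_positive_mph = m[4],
               bph_mean = b[1], bph_min = b[2], bph_max = b[3],
               pct_positive_bph = b[4], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$stratum, out$trait), ]
}
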