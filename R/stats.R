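#' @include AllClasses.R features.R
NULL

#' One-way ANOVA between two groups
#'
#' Classical equal-variance one-way analysis of variance
#' (`F = MS_between / MS_within`, df `(1, n_a + n_b - 2)`) with the
#' p-value from the F distribution's upper tail. For two groups this F is
#' the square of the pooled t statistic.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @return list with `statistic`, `p.value`, and `df` (length 2).
#' @examples
#' anovaOneway(c(1, 2, 3), c(2, 3, 4))$statistic  # 1.5
#' @export
anovaOneway <- function(groupA, groupB) {
  stopIfNot(length(groupA) >= 2L && length(groupB) >= 2L,
            "each group needs at least 2 values")
  stopIfNot(all(is.finite(groupA)) && all(is.finite(groupB)),
            "group values must be finite")
  ssw <- sum((groupA - mean(groupA))^2) + sum((groupB - mean(groupB))^2)
  if (ssw <= 0) stop("degenerate within-group variance")
  v <- c(groupA, groupB)
  g <- factor(rep(c("a", "b"), c(length(groupA), length(groupB))))
  ft <- stats::oneway.test(v ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p.value = unname(ft$p.value),
       df = unname(c(ft$parameter[1], ft$parameter[2])))
}

.starFlag <- function(p, alpha) {
  ifelse(p >= alpha, "ns", ifelse(p < 0.01, "**", "*"))
}

#' Group-level significance map over pairs, bands and features
#'
#' One two-group ANOVA per (pair, band, feature kind) cell, comparing
#' per-epoch feature values (or per-subject means) between the MDD and HC
#' groups. Feature kinds are the asymmetry, the cross-correlation, and
#' their MIX1/MIX2 fusions. Flags follow the usual star convention:
#' `*` for p below `alpha` (default 0.05), `**` for p < 0.01; no
#' multiple-testing correction is applied unless `adjust = "BH"`.
#'
#' The default unit of analysis is the epoch, pooled across subjects
#' within each group; this matches how the classification samples are
#' counted but inflates the effective n, so a per-subject mode is
#' provided.
#'
#' @param features data.frame from [epochFeatures()]; both groups must be
#'   present.
#' @param alpha significance level (default 0.05).
#' @param unit `"epoch"` (pool epochs) or `"subject"` (test subject
#'   means).
#' @param adjust `"none"` (default) or `"BH"` for Benjamini-Hochberg
#'   adjusted p-values (flags then use the adjusted values).
#' @param k1,k2 mixing coefficients for the MIX features.
#' @return data.frame with one row per cell: `pair`, `band`, `feature`,
#'   `f`, `p`, `flag`, `mean_MDD`, `se_MDD`, `mean_HC`, `se_HC`.
#' @export
significanceMap <- function(features, alpha = 0.05,
                            unit = c("epoch", "subject"),
                            adjust = c("none", "BH"),
                            k1 = 0.5, k2 = 0.5) {
  unit <- match.arg(unit)
  adjust <- match.arg(adjust)
  stopIfNot(alpha >= 0 && alpha <= 1, "alpha must lie in [0, 1]")
  grp <- unique(features$group)
  stopIfNot(all(GROUP_LEVELS %in% grp),
            "both MDD and HC groups must be present")

  m <- mixFeatures(features$asymmetry, features$crosscorr, k1, k2)
  kinds <- list(asymmetry = features$asymmetry,
                crosscorr = features$crosscorr,
                mix1 = m$mix1, mix2 = m$mix2)

  out <- list()
  for (kn in names(kinds)) {
    df <- data.frame(pair = features$pair, band = features$band,
                     group = features$group,
                     subjectId = features$subjectId,
                     value = kinds[[kn]], stringsAsFactors = FALSE)
    if (unit == "subject") {
      df <- stats::aggregate(value ~ pair + band + group + subjectId,
                             data = df, FUN = mean)
    }
    cells <- split(df, list(df$pair, df$band), drop = TRUE, sep = "\r")
    res <- lapply(cells, function(cell) {
      a <- cell$value[cell$group == "MDD"]
      b <- cell$value[cell$group == "HC"]
      stopIfNot(length(a) >= 2L && length(b) >= 2L,
                "a cell has fewer than 2 values per group")
      ft <- anovaOneway(a, b)
      data.frame(pair = cell$pair[1], band = cell$band[1], feature = kn,
                 f = ft$statistic, p = ft$p.value,
                 mean_MDD = mean(a), se_MDD = stats::sd(a) / sqrt(length(a)),
                 mean_HC = mean(b), se_HC = stats::sd(b) / sqrt(length(b)),
                 stringsAsFactors = FALSE)
    })
    out[[kn]] <- do.call(rbind, res)
  }
  map <- do.call(rbind, out)
  rownames(map) <- NULL
  if (adjust == "BH") map$p <- stats::p.adjust(map$p, method = "BH")
  map$flag <- .starFlag(map$p, alpha)
  map[c("pair", "band", "feature", "f", "p", "flag",
        "mean_MDD", "se_MDD", "mean_HC", "se_HC")]
}

#' Write a significance map as tab-separated text
#'
#' @param map data.frame from [significanceMap()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSignificanceMap <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
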