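#' Holm step-down multiple-testing adjustment
#'
#' Adjusted p for the i-th smallest raw p is
#' `max_{j <= i} min(1, (m - j + 1) p_(j))`, returned in the input order.
#' Adjusted values never fall below the raw ones and never exceed 1.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values.
#' @examples
#' holmAdjust(c(0.01, 0.04, 0.02))
#' @export
holmAdjust <- function(p) {
  stopIfNot(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Paired Wilcoxon signed-rank test on per-session side counts
#'
#' Compares paired (proximal, distal) transient counts.  Zero-difference
#' pairs are dropped (standard signed-rank convention); if every pair is
#' equal the test is not performed and the result is flagged.
#'
#' @param proximal,distal paired numeric vectors.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `p_value`, `statistic`, `n_used`, `flag`.
#' @export
wilcoxonSideTest <- function(proximal, distal, alternative = "two.sided") {
  stopIfNot(length(proximal) == length(distal), "inputs must be paired")
  d <- distal - proximal
  nz <- d != 0
  if (!any(nz))
    return(list(p_value = NA_real_, statistic = NA_real_, n_used = 0L,
                flag = "all pairs equal; no test performed"))
  wt <- suppressWarnings(wilcox.test(distal[nz], proximal[nz], paired = TRUE,
                                     alternative = alternative))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       n_used = sum(nz), flag = NA_character_)
}

#' Fisher's exact test on a 2x2 perfusion table
#'
#' @param tab 2x2 matrix (e.g. group x perfused/not).  An empty margin
#'   yields p = 1 by convention, flagged.
#' @return list with `p_value`, `flag`.
#' @export
fisherPerfusionTest <- function(tab) {
  stopIfNot(all(dim(tab) == c(2L, 2L)), "need a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, flag = "empty margin; p = 1 by convention"))
  ft <- fisher.test(tab)
  list(p_value = ft$p.value, flag = NA_character_)
}

#' Mann-Whitney U test on per-animal counts
#'
#' Exact where feasible (small n without ties), normal approximation with
#' tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @return list with `p_value`, `U`, `flag`.
#' @export
mannWhitneyTest <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y, exact = NULL))
  list(p_value = wt$p.value, U = unname(wt$statistic), flag = NA_character_)
}
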