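#' Mixing rule for a combined cluster
#'
#' A cluster drawn from a combined (apo + liganded) clustering is "mixed"
#' when its smaller provenance component is at least `threshold` times its
#' larger component: `min(a, l) >= threshold * max(a, l)`. The default 5%
#' cutoff means, e.g., a cluster of 293 apo and 14,287 liganded frames is
#' not mixed (293 < 0.05 * 14287), while 1,554 apo and 3,269 liganded is.
#'
#' @param a_k,l_k frame counts of the two provenance groups in the cluster
#' @param threshold mixing fraction in (0, 1), default 0.05
#' @return logical
#' @export
is_mixed <- function(a_k, l_k, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (any(a_k < 0) || any(l_k < 0)) stop("counts must be non-negative")
  if (any(a_k + l_k < 1)) stop("cluster must contain at least one frame")
  pmin(a_k, l_k) >= threshold * pmax(a_k, l_k)
}

#' Overlap fraction of an apo ensemble with a liganded ensemble
#'
#' The overlap fraction is the fraction of apo frames that fall in mixed
#' clusters (see [is_mixed()]): `phi = sum(a_k over mixed clusters) /
#' sum(a_k over all clusters)`. `phi = 0` means ligand binding eliminated
#' every apo conformation (a complete ensemble shift); `phi = 1` means every
#' cluster containing apo frames is shared with the liganded ensemble.
#'
#' @param table a `cluster_table` from [combined_cluster()] or
#'   [cluster_table()], or any data.frame with columns `count_a` (apo) and
#'   `count_b` (liganded)
#' @param threshold mixing fraction, default 0.05
#' @return object of class `overlap_result`: list with `phi`, per-cluster
#'   `mixed` flags, `threshold`, `apo_total`, `apo_in_mixed`
#' @export
overlap_fraction <- function(table, threshold = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("count_a", "count_b") %in% names(table)))
  apo_total <- sum(table$count_a)
  if (apo_total < 1) stop("no apo frames in the table: fraction undefined")
  mixed <- is_mixed(table$count_a, table$count_b, threshold)
  apo_in_mixed <- sum(table$count_a[mixed])
  structure(list(phi = apo_in_mixed / apo_total, mixed = mixed,
                 threshold = threshold, apo_total = apo_total,
                 apo_in_mixed = apo_in_mixed),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap_result> phi = %.4f (%d of %d apo frames in %d mixed of %d clusters)\n",
    x$phi, x$apo_in_mixed, x$apo_total, sum(x$mixed), length(x$mixed)))
  invisible(x)
}

#' Correlate overlap fractions with ligand activity
#'
#' Pairs per-complex overlap fractions with an activity metric and returns
#' the correlation. For `metric = "log10_ec50"` the EC50 (nM) is
#' log10-transformed and complexes without a measurable EC50 (inactive
#' ligands) are excluded; the number excluded is reported. Fold-fraction
#' metrics divide the fold change at 10 or 100 nM by the complex's Emax.
#'
#' @param phis data.frame with columns `variant`, `ligand`, `phi`
#' @param activities data.frame as returned by [read_activity_csv()]
#' @param metric one of `"log10_ec50"`, `"fold_fraction_10nM"`,
#'   `"fold_fraction_100nM"`
#' @param method `"pearson"` (default) or `"spearman"`
#' @return list with `r`, `p`, `n`, `n_excluded`, `method`, `metric` and the
#'   paired data in `data`
#' @export
correlate_activity <- function(phis, activities,
                               metric = c("log10_ec50", "fold_fraction_10nM",
                                          "fold_fraction_100nM"),
                               method = c("pearson", "spearman")) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  stopifnot(all(c("variant", "ligand", "phi") %in% names(phis)))
  merged <- merge(phis, activities, by = c("variant", "ligand"))
  y <- switch(metric,
              log10_ec50 = log10(merged$ec50),
              fold_fraction_10nM = merged$fold_10nM / merged$emax,
              fold_fraction_100nM = merged$fold_100nM / merged$emax)
  ok <- is.finite(y) & is.finite(merged$phi)
  n_excluded <- sum(!ok)
  x <- merged$phi[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("fewer than 3 complexes with both phi and ", metric)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in phi or ", metric, ": correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       n_excluded = n_excluded, method = method, metric = metric,
       data = data.frame(variant = merged$variant[ok],
                         ligand = merged$ligand[ok], phi = x, value = y))
}
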