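drop_missing <- function(groups) {
  dropped <- sum(vapply(groups, function(g) sum(is.na(g)), integer(1)))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  attr(groups, "n_dropped") <- dropped
  groups
}

#' One-way fixed-effects ANOVA
#'
#' Standard between/within decomposition across condition groups. The
#' experimental unit is the culture: each group holds one parameter value per
#' culture. Missing values are dropped (count recorded in the result).
#'
#' @param groups named list of numeric vectors, one per condition, each with
#'   at least 2 non-missing values.
#' @return An object of class `mea_anova`: `F`, `df_between`, `df_within`,
#'   `p`, `mse` (pooled within-group mean square), per-group `means` and `ns`,
#'   and `n_dropped`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_bad_arg("`groups` must be a list of at least 2 numeric vectors")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- drop_missing(groups)
  ns <- lengths(groups)
  if (any(ns < 2L))
    stop_bad_arg("every group needs at least 2 non-missing values")
  y <- unlist(groups, use.names = FALSE)
  if (max(y) - min(y) == 0)
    stop_bad_arg("degenerate input: all values identical, F undefined")
  g <- factor(rep(names(groups), ns), levels = names(groups))
  tab <- stats::anova(stats::lm(y ~ g))
  structure(
    list(F = tab[["F value"]][1L],
         df_between = tab[["Df"]][1L],
         df_within = tab[["Df"]][2L],
         p = tab[["Pr(>F)"]][1L],
         mse = tab[["Mean Sq"]][2L],
         means = vapply(groups, mean, numeric(1)),
         ns = ns,
         n_dropped = attr(groups, "n_dropped")),
    class = "mea_anova")
}

#' @export
print.mea_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g, MSE = %.4g\n",
              x$df_between, x$df_within, x$F, x$p, x$mse))
  invisible(x)
}

#' Fisher's (protected) least significant difference post-hoc test
#'
#' Pairwise comparisons using the pooled ANOVA error: for groups i, j,
#' `t = (mean_i - mean_j) / sqrt(MSE * (1/n_i + 1/n_j))`, two-sided p on the
#' within-group degrees of freedom, with no multiplicity adjustment. The
#' result records whether the omnibus F test was significant at `alpha`
#' (the "protection" of the protected LSD); pairwise p values are returned
#' either way so the caller may choose protected or unprotected use.
#'
#' @param groups named list of per-condition values (as [one_way_anova()]).
#' @param anova optional precomputed [one_way_anova()] result on `groups`.
#' @param alpha omnibus significance level used for the protection flag.
#' @return Data frame with one row per unordered pair: `group1`, `group2`,
#'   `diff`, `t`, `df`, `p`; attributes `omnibus_p` and `protected`
#'   (logical: omnibus p < alpha).
#' @export
fishers_plsd <- function(groups, anova = NULL, alpha = 0.05) {
  if (is.null(anova)) anova <- one_way_anova(groups)
  nms <- names(anova$means)
  pairs <- utils::combn(nms, 2L)
  diffs <- ts <- ps <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    se <- sqrt(anova$mse * (1 / anova$ns[[i]] + 1 / anova$ns[[j]]))
    diffs[k] <- anova$means[[i]] - anova$means[[j]]
    ts[k] <- diffs[k] / se
    ps[k] <- 2 * stats::pt(-abs(ts[k]), df = anova$df_within)
  }
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    diff = diffs, t = ts, df = anova$df_within, p = ps,
                    stringsAsFactors = FALSE)
  attr(out, "omnibus_p") <- anova$p
  attr(out, "protected") <- anova$p < alpha
  out
}

#' Classify a knockdown effect on one parameter at one timepoint
#'
#' The barcode decision rule: a cell is called `"increase"` when the
#' knockdown differs from both controls (p < alpha versus untransfected and
#' versus NTC), the two controls do not differ from each other (p >= alpha),
#' and the knockdown mean exceeds both control means; `"decrease"` is the
#' mirror image; anything else — including missing p values — is `"none"`.
#'
#' @param kd_vs_ut_p,kd_vs_ntc_p,ut_vs_ntc_p pairwise two-sided p values.
#' @param kd_mean,ut_mean,ntc_mean group means.
#' @param alpha significance level (default 0.05).
#' @return `"increase"`, `"decrease"` or `"none"`.
#' @export
classify_effect <- function(kd_vs_ut_p, kd_vs_ntc_p, ut_vs_ntc_p,
                            kd_mean, ut_mean, ntc_mean, alpha = 0.05) {
  ps <- c(kd_vs_ut_p, kd_vs_ntc_p, ut_vs_ntc_p)
  ms <- c(kd_mean, ut_mean, ntc_mean)
  if (anyNA(ps) || anyNA(ms)) return("none")
  if (kd_vs_ut_p < alpha && kd_vs_ntc_p < alpha && ut_vs_ntc_p >= alpha) {
    if (kd_mean > ut_mean && kd_mean > ntc_mean) return("increase")
    if (kd_mean < ut_mean && kd_mean < ntc_mean) return("decrease")
  }
  "none"
}
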