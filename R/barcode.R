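cell_stats <- function(values_by_condition, kd, ut, ntc, alpha, protected) {
  # returns list(call, F, p_omnibus, p_kd_ut, p_kd_ntc, p_ut_ntc)
  blank <- list(call = "none", F = NA_real_, p_omnibus = NA_real_,
                p_kd_ut = NA_real_, p_kd_ntc = NA_real_, p_ut_ntc = NA_real_)
  groups <- drop_missing(values_by_condition)
  if (any(lengths(groups) < 2L)) return(blank)
  y <- unlist(groups, use.names = FALSE)
  if (max(y) - min(y) == 0) return(blank)   # degenerate cell: no test
  an <- one_way_anova(groups)
  pl <- fishers_plsd(groups, an, alpha = alpha)
  pair_p <- function(a, b) {
    hit <- (pl$group1 == a & pl$group2 == b) | (pl$group1 == b & pl$group2 == a)
    pl$p[hit][1L]
  }
  p_kd_ut <- pair_p(kd, ut)
  p_kd_ntc <- pair_p(kd, ntc)
  p_ut_ntc <- pair_p(ut, ntc)
  call <- if (protected && an$p >= alpha) "none" else
    classify_effect(p_kd_ut, p_kd_ntc, p_ut_ntc,
                    an$means[[kd]], an$means[[ut]], an$means[[ntc]],
                    alpha = alpha)
  list(call = call, F = an$F, p_omnibus = an$p, p_kd_ut = p_kd_ut,
       p_kd_ntc = p_kd_ntc, p_ut_ntc = p_ut_ntc)
}

#' Build the phenotype barcode for one knockdown experiment
#'
#' For each (parameter, DIV) cell, runs a one-way ANOVA with Fisher's PLSD
#' across the three conditions and classifies the knockdown effect as
#' increase / decrease / none ([classify_effect()]). With `protected = TRUE`
#' (the default) pairwise calls are only interpreted when the omnibus F test
#' is itself significant at `alpha`. Cells with degenerate data (a group with
#' fewer than 2 non-missing cultures, or all values identical) are `"none"`.
#'
#' @param param_table per-recording parameter table from
#'   [experiment_params()] (columns `condition`, `culture_id`, `div`, plus
#'   parameter columns).
#' @param kd,ut,ntc condition labels of the knockdown, untransfected control
#'   and non-targeting control groups.
#' @param parameters parameter columns to classify; defaults to the seven
#'   network parameters present in the table.
#' @param divs DIVs to classify; defaults to all present.
#' @param alpha per-cell significance level (no multiplicity correction
#'   across cells).
#' @param protected gate pairwise calls on omnibus significance.
#' @return An object of class `mea_barcode`: a data frame with one row per
#'   (parameter, div) holding `call` plus the underlying F and p values.
#' @export
build_barcode <- function(param_table, kd, ut = "untransfected", ntc = "ntc",
                          parameters = NULL, divs = NULL, alpha = 0.05,
                          protected = TRUE) {
  need <- c("condition", "culture_id", "div")
  if (!all(need %in% names(param_table)))
    stop_bad_arg("`param_table` must have columns ",
                 paste(need, collapse = ", "))
  for (lbl in c(kd, ut, ntc))
    if (!lbl %in% param_table$condition)
      stop_bad_arg("condition '", lbl, "' not present in `param_table`")
  parameters <- parameters %||%
    intersect(network_parameter_names(), names(param_table))
  divs <- divs %||% sort(unique(param_table$div))
  rows <- list()
  for (p in parameters) {
    for (d in divs) {
      sub <- param_table[param_table$div == d, , drop = FALSE]
      vals <- lapply(stats::setNames(c(kd, ut, ntc), c(kd, ut, ntc)),
                     function(cc) sub[[p]][sub$condition == cc])
      cs <- cell_stats(vals, kd, ut, ntc, alpha, protected)
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, div = d, call = cs$call, F = cs$F,
        p_omnibus = cs$p_omnibus, p_kd_ut = cs$p_kd_ut,
        p_kd_ntc = cs$p_kd_ntc, p_ut_ntc = cs$p_ut_ntc,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("mea_barcode", "data.frame"),
            kd = kd, ut = ut, ntc = ntc, alpha = alpha,
            protected = protected)
}

#' @export
as.matrix.mea_barcode <- function(x, ...) {
  pars <- unique(x$parameter)
  divs <- sort(unique(x$div))
  m <- matrix("none", length(pars), length(divs),
              dimnames = list(pars, paste0("DIV", divs)))
  for (i in seq_len(nrow(x)))
    m[x$parameter[i], paste0("DIV", x$div[i])] <- x$call[i]
  m
}

#' @export
print.mea_barcode <- function(x, ...) {
  cat("Phenotype barcode (", attr(x, "kd"), " vs ", attr(x, "ut"), "/",
      attr(x, "ntc"), ", alpha = ", attr(x, "alpha"), ")\n", sep = "")
  m <- as.matrix(x)
  sym <- matrix(c(increase = "+", decrease = "-", none = ".")[m],
                nrow(m), ncol(m), dimnames = dimnames(m))
  print(sym, quote = FALSE)
  cat("(+ increase, - decrease, . none)\n")
  invisible(x)
}

#' Plot a barcode matrix
#'
#' Renders the barcode as a colour matrix: red = significant increase,
#' blue = significant decrease, gray = no call.
#'
#' @param x an `mea_barcode`.
#' @param main plot title.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.mea_barcode <- function(x, main = attr(x, "kd"), ...) {
  m <- as.matrix(x)
  code <- matrix(match(m, c("decrease", "none", "increase")),
                 nrow(m), ncol(m))
  np <- nrow(m); nd <- ncol(m)
  graphics::image(x = seq_len(nd), y = seq_len(np),
                  z = t(code[np:1, , drop = FALSE]),
                  zlim = c(1, 3), col = c("#2166ac", "gray85", "#b2182b"),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(nd), labels = colnames(m), las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(np), labels = rev(rownames(m)), las = 1,
                 cex.axis = 0.8)
  graphics::box()
  invisible(x)
}
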