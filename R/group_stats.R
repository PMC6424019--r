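#' Test the epithelial length increase due to secondary folds
#'
#' One-way ANOVA comparing, within one specimen, the linear lamellar
#' lengths against the semi-boundaries (two groups of n lamellae). With two
#' groups this is equivalent to the two-sample t-test (F = t^2). A paired
#' alternative is offered since the two measurements come from the same
#' lamellae.
#'
#' @param L_lin,L_semi per-lamella linear lengths and semi-boundaries (mm),
#'   equal length >= 2.
#' @param paired use a paired t-test instead of the unpaired ANOVA.
#' @return list with `statistic` (F, or t if paired), `p_value`, `df`, and
#'   `method`. When both groups have zero variance and differ, exact
#'   separation is noted and the p-value reported as below machine
#'   precision.
#' @examples
#' epithelium_increase_test(c(10, 11, 9, 10), c(30, 32, 28, 30))
#' @export
epithelium_increase_test <- function(L_lin, L_semi, paired = FALSE) {
  if (length(L_lin) != length(L_semi) || length(L_lin) < 2)
    stopf("need matching vectors of at least 2 lamellae")
  if (paired) {
    tt <- stats::t.test(L_semi, L_lin, paired = TRUE,
                        alternative = "greater")
    return(list(statistic = unname(tt$statistic), p_value = tt$p.value,
                df = unname(tt$parameter), method = "paired t-test"))
  }
  if (stats::var(L_lin) == 0 && stats::var(L_semi) == 0) {
    if (mean(L_lin) == mean(L_semi))
      return(list(statistic = 0, p_value = 1, df = c(1, 2 * length(L_lin) - 2),
                  method = "one-way ANOVA (no variance, no difference)"))
    return(list(statistic = Inf, p_value = .Machine$double.xmin,
                df = c(1, 2 * length(L_lin) - 2),
                method = "one-way ANOVA (exact separation)"))
  }
  d <- data.frame(len = c(L_lin, L_semi),
                  grp = factor(rep(c("linear", "semi"), each = length(L_lin))))
  fit <- stats::aov(len ~ grp, data = d)
  s <- summary(fit)[[1]]
  list(statistic = s$`F value`[1], p_value = s$`Pr(>F)`[1],
       df = s$Df, method = "one-way ANOVA")
}

star_levels <- c("", ".", "*", "**", "***", "****", "*****")

# Decade star scheme: "." p<0.1, then one star per decade from 0.05.
star_code <- function(p) {
  cuts <- c(Inf, 0.1, 0.05, 0.01, 0.001, 1e-4, 1e-5)
  star_levels[rowSums(outer(p, cuts, `<`))]
}

#' All-pairs Tukey comparison of per-specimen percentage increases
#'
#' One-way ANOVA across specimens on the per-lamella percentage increases,
#' followed by Tukey's HSD (Tukey-Kramer for unbalanced groups) on every
#' specimen pair. Pairwise p-values are coded with a decade star scheme:
#' `.` p < 0.1, `*` < 0.05, `**` < 0.01, `***` < 0.001, `****` < 1e-4,
#' `*****` < 1e-5.
#'
#' @param percentages named list: one numeric vector of per-lamella
#'   percentage increases per specimen (each of length >= 2).
#' @return object of class `significance_matrix`: list with `p` (symmetric
#'   matrix of Tukey p-values, NA diagonal), `stars` (character matrix),
#'   `anova_p`, and `long` (data.frame of pairs).
#' @export
tukey_matrix <- function(percentages) {
  if (length(percentages) < 2) stopf("need at least 2 specimens")
  len <- lengths(percentages)
  if (any(len < 2))
    stopf("specimen(s) with a single value: %s",
          paste(names(percentages)[len < 2], collapse = ", "))
  ids <- names(percentages) %||% paste0("g", seq_along(percentages))
  if (any(grepl("-", ids, fixed = TRUE)))
    stopf("specimen ids must not contain '-' (reserved by the pair labels)")
  d <- data.frame(p = unlist(percentages, use.names = FALSE),
                  grp = factor(rep(ids, len), levels = ids))
  fit <- stats::aov(p ~ grp, data = d)
  anova_p <- summary(fit)[[1]]$`Pr(>F)`[1]
  tk <- stats::TukeyHSD(fit)$grp
  n <- length(ids)
  pm <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  for (i in seq_len(nrow(tk))) {
    pm[pairs[i, 1], pairs[i, 2]] <- tk[i, "p adj"]
    pm[pairs[i, 2], pairs[i, 1]] <- tk[i, "p adj"]
  }
  stars <- matrix("", n, n, dimnames = list(ids, ids))
  off <- !is.na(pm)
  stars[off] <- star_code(pm[off])
  long <- data.frame(a = pairs[, 1], b = pairs[, 2],
                     diff = tk[, "diff"], p_adj = tk[, "p adj"],
                     stars = star_code(tk[, "p adj"]), row.names = NULL)
  structure(list(p = pm, stars = stars, anova_p = anova_p, long = long),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf("Tukey post hoc star matrix (ANOVA p = %.3g)\n", x$anova_p))
  print(x$stars, quote = FALSE)
  invisible(x)
}
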