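#' Box-and-whisker summary statistics
#'
#' Median, quartiles (linear-interpolation quantile rule, R type 7), mean,
#' and Tukey whiskers: the most extreme observations within 1.5 times the
#' interquartile range of the quartiles.
#'
#' @param x numeric vector.
#' @return one-row data.frame: `n`, `mean`, `median`, `q1`, `q3`,
#'   `whisker_lo`, `whisker_hi`.
#' @export
box_stats <- function(x) {
  x <- x[is.finite(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  data.frame(n = length(x), mean = mean(x), median = q[2],
             q1 = q[1], q3 = q[3],
             whisker_lo = min(x[x >= lo_fence]),
             whisker_hi = max(x[x <= hi_fence]))
}

# Dunn's post hoc z-tests on the shared ranks of the pooled sample, with
# the usual tie correction; returns raw two-sided p-values per group pair.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * stats::pnorm(-abs(z)))
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = res["z", ], p_raw = res["p", ],
             row.names = NULL)
}

#' Nonparametric comparison of per-track statistics across conditions
#'
#' Kruskal-Wallis rank-sum omnibus test (with tie correction) followed by
#' Dunn's pairwise post hoc z-tests on the shared ranks, Holm-adjusted.
#' Pairwise Wilcoxon rank-sum tests with Bonferroni adjustment are
#' available as an alternative post hoc family.  Box statistics per group
#' follow the 1.5 x IQR whisker convention (see [box_stats()]).
#'
#' @param values numeric vector of the per-track statistic (e.g.
#'   `neg_log10_D` or `alpha`).
#' @param groups condition label per value.
#' @param posthoc `"dunn_holm"` (default) or `"wilcoxon_bonferroni"`.
#' @return list of class `group_comparison`: `omnibus` (statistic H, df,
#'   p), `posthoc` (pairwise table with raw and adjusted p), `box`
#'   (per-group box statistics), `excluded` (groups dropped for n < 3).
#' @examples
#' v <- c(1, 2, 3, 4, 5, 10, 20, 30, 40, 50)
#' g <- rep(c("a", "b"), each = 5)
#' kruskal_groups(v, g)$omnibus  # H = 6.818
#' @export
kruskal_groups <- function(values, groups,
                           posthoc = c("dunn_holm",
                                       "wilcoxon_bonferroni")) {
  posthoc <- match.arg(posthoc)
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  n_by <- table(groups)
  small <- names(n_by)[n_by < 3]
  if (length(small) > 0) {
    warning("excluding groups with fewer than 3 values: ",
            paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- groups[keep]
  }
  if (length(unique(groups)) < 2)
    stop("need at least 2 groups with >= 3 values each")

  kw <- stats::kruskal.test(values, factor(groups))
  ph <- if (posthoc == "dunn_holm") {
    d <- dunn_test(values, groups)
    d$p_adj <- stats::p.adjust(d$p_raw, method = "holm")
    d$method <- "dunn_holm"
    d
  } else {
    lev <- sort(unique(groups))
    pairs <- utils::combn(lev, 2)
    p_raw <- apply(pairs, 2, function(p) {
      stats::wilcox.test(values[groups == p[1]],
                         values[groups == p[2]], exact = FALSE)$p.value
    })
    data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
               z = NA_real_, p_raw = p_raw,
               p_adj = stats::p.adjust(p_raw, method = "bonferroni"),
               method = "wilcoxon_bonferroni", row.names = NULL)
  }
  box <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    b <- box_stats(values[groups == g]); b$group <- g
    b[, c("group", setdiff(names(b), "group"))]
  }))
  structure(list(
    omnibus = data.frame(H = unname(kw$statistic),
                         df = unname(kw$parameter),
                         p = kw$p.value),
    posthoc = ph, box = box, excluded = small),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Omnibus:\n"); print(x$omnibus)
  cat("Post hoc:\n"); print(x$posthoc)
  invisible(x)
}

#' Motion-class fractions over gate-passing fits
#'
#' @param fits data.frame from [fit_tracks()] (columns `passed_gate`,
#'   `motion_class`).
#' @return data.frame with one row per class: `motion_class`, `count`,
#'   `fraction` (fractions over gate-passing fits sum to 1); attribute
#'   `n_gated_out` records fits excluded by the R^2 gate.
#' @export
class_fractions <- function(fits) {
  ok <- !is.na(fits$passed_gate) & fits$passed_gate
  if (!any(ok)) stop("no fits passed the R^2 gate")
  cls <- factor(fits$motion_class[ok],
                levels = c("anomalous_confined", "brownian", "directed"))
  tab <- table(cls)
  structure(data.frame(motion_class = names(tab),
                       count = as.integer(tab),
                       fraction = as.numeric(tab) / sum(tab)),
            n_gated_out = sum(!ok))
}

#' Compare mean anomalous exponents across conditions (ANOVA + Tukey)
#'
#' One-way ANOVA F-test with Tukey HSD post hoc, the parametric family used
#' for comparing per-condition mean alpha values, plus the same box
#' summaries as [kruskal_groups()].  With a single group only the summary
#' is returned.
#'
#' @param values numeric vector of per-track alpha values.
#' @param groups condition label per value.
#' @return list of class `group_comparison` with `omnibus` (F, df, p;
#'   `NULL` for a single group), `posthoc` (Tukey table or `NULL`), `box`,
#'   and `test_family = "anova_tukey"`.
#' @export
mean_alpha_summary <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups)[keep]
  box <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    b <- box_stats(values[groups == g]); b$group <- g
    b[, c("group", setdiff(names(b), "group"))]
  }))
  if (length(unique(groups)) < 2) {
    return(structure(list(omnibus = NULL, posthoc = NULL, box = box,
                          test_family = "anova_tukey"),
                     class = "group_comparison"))
  }
  fit <- stats::aov(values ~ g, data = data.frame(values = values,
                                                  g = factor(groups)))
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  structure(list(
    omnibus = data.frame(F = an$`F value`[1], df1 = an$Df[1],
                         df2 = an$Df[2], p = an$`Pr(>F)`[1]),
    posthoc = data.frame(group1 = vapply(pairs, `[`, "", 2),
                         group2 = vapply(pairs, `[`, "", 1),
                         diff = tk[, "diff"], p_adj = tk[, "p adj"],
                         method = "tukey_hsd", row.names = NULL),
    box = box, test_family = "anova_tukey"),
    class = "group_comparison")
}
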