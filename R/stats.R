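significance_stars <- function(p, alpha = 0.05, alpha_high = 0.01) {
  ifelse(p < alpha_high, "**", ifelse(p < alpha, "*", "ns"))
}

comparison_result <- function(statistic, df, p, group_stats, method) {
  structure(list(statistic = statistic, df = df, p.value = p,
                 stars = significance_stars(p), groups = group_stats,
                 method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, df %.4g, p %.4g (%s)\n",
              x$method, x$statistic, x$df, x$p.value, x$stars))
  invisible(x)
}

group_descriptives <- function(values) {
  n <- length(values)
  data.frame(n = n, mean = mean(values),
             sem = if (n > 1) stats::sd(values) / sqrt(n) else 0)
}

#' Two-sample t test for group comparisons
#'
#' Two-sided unpaired t test; the default `"student"` variant pools the
#' variances (classical Student's t), `"welch"` uses the unequal-variance
#' form. When both groups have zero variance, p is 1 for equal means and 0
#' otherwise (by convention). A caveat is emitted when the variance ratio
#' exceeds 4 under the pooled variant.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param variant `"student"` (pooled, default) or `"welch"`.
#' @return A `comparison_result` with statistic, df, p value, significance
#'   stars (`*` p < 0.05, `**` p < 0.01) and per-group n/mean/SEM.
#' @export
t_test_groups <- function(group_a, group_b,
                          variant = c("student", "welch")) {
  variant <- match.arg(variant)
  for (g in list(a = group_a, b = group_b)) {
    if (length(g) < 2 || any(!is.finite(g))) {
      stop("each group needs >= 2 finite values", call. = FALSE)
    }
  }
  va <- stats::var(group_a)
  vb <- stats::var(group_b)
  df <- length(group_a) + length(group_b) - 2
  if (va == 0 && vb == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    res <- comparison_result(if (equal) 0 else Inf, df,
                             if (equal) 1 else 0,
                             rbind(group_descriptives(group_a),
                                   group_descriptives(group_b)),
                             paste0(variant, " t test"))
    return(res)
  }
  if (variant == "student" && min(va, vb) > 0 && max(va, vb) / min(va, vb) > 4) {
    message("variance ratio > 4: pooled t test may be inaccurate; ",
            "consider variant = \"welch\"")
  }
  tt <- stats::t.test(group_a, group_b, var.equal = (variant == "student"))
  comparison_result(unname(tt$statistic), unname(tt$parameter),
                    tt$p.value,
                    rbind(group_descriptives(group_a),
                          group_descriptives(group_b)),
                    paste0(variant, " t test"))
}

#' One-way ANOVA with Bonferroni post test
#'
#' Omnibus one-way ANOVA across >= 3 groups followed by all pairwise
#' Student t tests with Bonferroni adjustment
#' (`p_adj = min(1, m * p_raw)`, `m` = number of pairs). Used for
#' frequency-distribution comparisons across multiple conditions.
#'
#' @param groups Named list of >= 3 numeric vectors, each of length >= 2.
#' @return List with `omnibus` (a `comparison_result` carrying F and its
#'   p value) and `pairwise` (data frame: `group_a`, `group_b`, `t`, `df`,
#'   `p_raw`, `p_adj`, `stars`).
#' @export
anova_bonferroni <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stop("need >= 3 groups; use t_test_groups() for pairwise comparisons",
         call. = FALSE)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("group_", seq_along(groups))
  }
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2 || any(!is.finite(groups[[g]]))) {
      stop("group '", g, "' needs >= 2 finite values", call. = FALSE)
    }
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)),
                   levels = names(groups))
  fit <- stats::aov(values ~ labels)
  tab <- summary(fit)[[1]]
  omnibus <- comparison_result(tab[["F value"]][1], tab[["Df"]][1],
                               tab[["Pr(>F)"]][1],
                               do.call(rbind, lapply(groups,
                                                     group_descriptives)),
                               "one-way ANOVA")
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  pw <- lapply(seq_len(m), function(k) {
    a <- pairs[1, k]
    b <- pairs[2, k]
    tt <- t_test_groups(groups[[a]], groups[[b]], variant = "student")
    data.frame(group_a = a, group_b = b, t = tt$statistic, df = tt$df,
               p_raw = tt$p.value, p_adj = min(1, m * tt$p.value),
               stringsAsFactors = FALSE)
  })
  pw <- do.call(rbind, pw)
  pw$stars <- significance_stars(pw$p_adj)
  list(omnibus = omnibus, pairwise = pw)
}

#' Mean +/- SEM summary with percent change vs a control group
#'
#' @param groups Named list of numeric vectors.
#' @param control Name of the control group (must be present).
#' @param test Add a pairwise Student t test of each group against the
#'   control (`p` column)?
#' @return Data frame with columns `group`, `n`, `mean`, `sem`,
#'   `pct_change` (`100 * (1 - mean / control mean)`; NA with a warning
#'   when the control mean is 0) and `p`.
#' @export
summarize_groups <- function(groups, control, test = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (!control %in% names(groups)) {
    stop("unknown control group: ", control, call. = FALSE)
  }
  cm <- mean(groups[[control]])
  if (cm == 0) warning("control mean is 0: percent change undefined")
  rows <- lapply(names(groups), function(g) {
    d <- group_descriptives(groups[[g]])
    p <- if (test && g != control && d$n >= 2 &&
             length(groups[[control]]) >= 2) {
      t_test_groups(groups[[control]], groups[[g]])$p.value
    } else NA_real_
    data.frame(group = g, n = d$n, mean = d$mean, sem = d$sem,
               n_flag = as.integer(d$n == 1),
               pct_change = if (cm == 0) NA_real_
                            else 100 * (1 - d$mean / cm),
               p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
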