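# The statistical battery applied to MMN feature tables: one-way ANOVA with
# Tukey HSD across groups, repeated-measures ANOVA with Bonferroni-adjusted
# paired comparisons across deviant types within each group, rank tests and
# two-sample t tests for the demographic variables, plus summary-statistic
# forms of ANOVA and t that operate directly on printed means/SDs.

as_group_list <- function(values, group = NULL) {
  if (is.list(values) && !is.data.frame(values)) return(values)
  stop_if_not(!is.null(group), "supply either a list of groups or values + group")
  split(values, group)
}

#' One-way fixed-effects ANOVA
#'
#' @param values Either a named list of numeric vectors (one per group) or a
#'   numeric vector accompanied by `group`.
#' @param group Optional grouping factor when `values` is a vector.
#' @return An `mmn_anova`: list with `F`, `df_between`, `df_within`, `p`.
#' @export
anova_oneway <- function(values, group = NULL) {
  g <- as_group_list(values, group)
  stop_if_not(length(g) >= 2, "need at least two groups")
  stop_if_not(all(lengths(g) >= 2), "every group needs n >= 2")
  stop_if_not(any(vapply(g, var, numeric(1)) > 0),
              "zero within-group variance in all groups")
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g) %||% seq_along(g), lengths(g)))
  ow <- oneway.test(y ~ f, var.equal = TRUE)
  structure(
    list(F = unname(ow$statistic), df_between = unname(ow$parameter[1]),
         df_within = unname(ow$parameter[2]), p = ow$p.value),
    class = "mmn_anova"
  )
}

#' One-way ANOVA from group summary statistics
#'
#' Recovers the one-way ANOVA F from per-group means, SDs and sizes alone:
#' between-group sum of squares `sum(n_i (mean_i - grand mean)^2)` over
#' `k - 1` df against the pooled within-group mean square
#' `sum((n_i - 1) sd_i^2) / (N - k)`. Feeding a dataset's own moments
#' reproduces [anova_oneway()] on that dataset exactly.
#'
#' @param mean,sd,n Numeric vectors of per-group means, SDs and sizes.
#' @return An `mmn_anova`.
#' @export
anova_from_summary <- function(mean, sd, n) {
  k <- length(mean)
  stop_if_not(k >= 2 && length(sd) == k && length(n) == k,
              "mean, sd, n must have equal length >= 2")
  stop_if_not(all(n >= 2), "every group needs n >= 2")
  N <- sum(n)
  gm <- sum(n * mean) / N
  msb <- sum(n * (mean - gm)^2) / (k - 1)
  msw <- sum((n - 1) * sd^2) / (N - k)
  stop_if_not(msw > 0, "zero pooled within-group variance")
  F <- msb / msw
  structure(
    list(F = F, df_between = as.numeric(k - 1), df_within = as.numeric(N - k),
         p = pf(F, k - 1, N - k, lower.tail = FALSE)),
    class = "mmn_anova"
  )
}

#' Pooled-variance two-sample t from summary statistics
#'
#' Student's t with `n1 + n2 - 2` df computed from printed moments.
#'
#' @param mean1,sd1,n1 First group's mean, SD, size.
#' @param mean2,sd2,n2 Second group's mean, SD, size.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stop_if_not(n1 >= 2 && n2 >= 2, "both groups need n >= 2")
  df <- as.numeric(n1 + n2 - 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  stop_if_not(sp2 > 0, "zero pooled variance")
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range family-wise adjusted pairwise comparisons following a
#' one-way ANOVA.
#'
#' @inheritParams anova_oneway
#' @return Tibble with `pair`, `diff`, `p_adjusted`, `method = "tukey"`.
#' @export
tukey_hsd <- function(values, group = NULL) {
  g <- as_group_list(values, group)
  stop_if_not(length(g) >= 2 && all(lengths(g) >= 2),
              "need >= 2 groups with n >= 2")
  y <- unlist(g, use.names = FALSE)
  f <- factor(rep(names(g) %||% seq_along(g), lengths(g)))
  tk <- TukeyHSD(aov(y ~ f))$f
  tibble::tibble(
    pair = rownames(tk), diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
    method = "tukey"
  )
}

#' One-factor repeated-measures ANOVA
#'
#' Within-subject decomposition of a complete subjects-by-conditions matrix:
#' the condition effect is tested against the condition-by-subject
#' interaction, `F = MS_condition / MS_(condition x subject)` with
#' `(c - 1)` and `(c - 1)(n - 1)` df. No sphericity correction by default;
#' `gg = TRUE` applies the Greenhouse-Geisser epsilon to the df and p.
#'
#' @param mat Numeric matrix, subjects in rows, conditions in columns,
#'   no missing cells.
#' @param gg Apply the Greenhouse-Geisser correction.
#' @return An `mmn_rm_anova`: `F`, `df_effect`, `df_error`, `p` (and
#'   `epsilon` when `gg = TRUE`).
#' @export
rm_anova <- function(mat, gg = FALSE) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  c <- ncol(mat)
  stop_if_not(n >= 2 && c >= 2, "need >= 2 subjects and >= 2 conditions")
  stop_if_not(all(is.finite(mat)), "missing cells in the repeated-measures matrix")
  df <- data.frame(
    y = as.vector(mat),
    subj = factor(rep(seq_len(n), times = c)),
    cond = factor(rep(seq_len(c), each = n))
  )
  fit <- aov(y ~ cond + Error(subj), data = df)
  tab <- summary(fit)[["Error: Within"]][[1]]
  F <- tab["cond", "F value"]
  df1 <- tab["cond", "Df"]
  df2 <- tab["Residuals", "Df"]
  p <- tab["cond", "Pr(>F)"]
  ss_tot <- sum((mat - mean(mat))^2)
  if (!is.finite(F) || tab["cond", "Sum Sq"] <= 1e-12 * max(ss_tot, 1e-300)) {
    F <- 0; p <- 1                          # no condition effect at all
  }
  res <- list(F = unname(F), df_effect = unname(df1), df_error = unname(df2),
              p = unname(p))
  if (gg) {
    S <- cov(mat)
    dbar <- mean(diag(S))
    sbar <- mean(S)
    rowm <- rowMeans(S)
    eps <- (c * (dbar - sbar))^2 /
      ((c - 1) * (sum(S^2) - 2 * c * sum(rowm^2) + c^2 * sbar^2))
    res$epsilon <- eps
    res$p <- pf(res$F, df1 * eps, df2 * eps, lower.tail = FALSE)
  }
  structure(res, class = "mmn_rm_anova")
}

#' Bonferroni-adjusted paired comparisons across conditions
#'
#' Paired t test for every pair of conditions; p-values multiplied by the
#' number of pairs and capped at 1.
#'
#' @param mat Subjects-by-conditions matrix (complete).
#' @return Tibble with `pair`, `statistic`, `p_raw`, `p_adjusted`,
#'   `method = "bonferroni"`.
#' @export
bonferroni_pairwise <- function(mat) {
  mat <- as.matrix(mat)
  stop_if_not(nrow(mat) >= 2 && ncol(mat) >= 2, "need >= 2 subjects and conditions")
  stop_if_not(all(is.finite(mat)), "missing cells in the repeated-measures matrix")
  cn <- colnames(mat) %||% as.character(seq_len(ncol(mat)))
  pairs <- combn(ncol(mat), 2)
  rows <- apply(pairs, 2, function(ij) {
    d <- mat[, ij[1]] - mat[, ij[2]]
    if (sd(d) < .Machine$double.eps^0.5 * max(1, abs(mean(d)))) {
      # degenerate differences: no variability to test against
      if (abs(mean(d)) < .Machine$double.eps^0.5) c(stat = 0, p = 1)
      else c(stat = sign(mean(d)) * Inf, p = 0)
    } else {
      tt <- t.test(mat[, ij[1]], mat[, ij[2]], paired = TRUE)
      c(stat = unname(tt$statistic), p = tt$p.value)
    }
  })
  p_raw <- rows["p", ]
  tibble::tibble(
    pair = paste(cn[pairs[1, ]], cn[pairs[2, ]], sep = "-"),
    statistic = rows["stat", ],
    p_raw = p_raw,
    p_adjusted = pmin(1, p_raw * ncol(pairs)),
    method = "bonferroni"
  )
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples: exact p for small
#' tie-free samples, tie-corrected two-sided normal approximation otherwise
#' (as implemented by [stats::wilcox.test()]).
#'
#' @param a,b Numeric vectors.
#' @return List with `U` and `p`.
#' @export
mann_whitney <- function(a, b) {
  stop_if_not(length(a) > 0 && length(b) > 0, "both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Run the full group-statistics battery on a feature table
#'
#' For every feature (amplitude, latency, AUC) and deviant kind: a one-way
#' ANOVA across groups plus Tukey HSD. For every group and feature: a
#' one-factor repeated-measures ANOVA over deviant kinds plus
#' Bonferroni-adjusted paired comparisons. With a single group the
#' between-group tests are skipped with a warning.
#'
#' @param features Feature tibble in the [extract_features()] dialect.
#' @param feature_cols Feature columns to analyse.
#' @return An `mmn_stats_bundle`: list with tibbles `oneway`, `tukey`, `rm`,
#'   `pairwise` (empty tibbles where skipped).
#' @export
run_study <- function(features,
                      feature_cols = c("amplitude_uV", "latency_ms", "auc_uVms")) {
  stop_if_not(all(c("subject_id", "group", "deviant_kind", feature_cols) %in%
                    names(features)), "feature table lacks required columns")
  kinds <- sort(unique(features$deviant_kind))
  groups <- sort(unique(features$group))
  oneway <- list(); tukey <- list(); rm_res <- list(); pw <- list()

  if (length(groups) >= 2) {
    for (fc in feature_cols) for (k in kinds) {
      sub <- features[features$deviant_kind == k, ]
      vals <- split(sub[[fc]], sub$group)
      if (any(vapply(vals, function(v) any(!is.finite(v)), logical(1)))) {
        stop("incomplete design: missing ", fc, " values for deviant '", k, "'",
             call. = FALSE)
      }
      a <- anova_oneway(vals)
      oneway[[length(oneway) + 1]] <- tibble::tibble(
        feature = fc, deviant_kind = k, F = a$F, df1 = a$df_between,
        df2 = a$df_within, p = a$p
      )
      tk <- tukey_hsd(vals)
      tk$feature <- fc
      tk$deviant_kind <- k
      tukey[[length(tukey) + 1]] <- tk
    }
  } else {
    warning("single group: between-group ANOVA skipped")
  }

  for (g in groups) for (fc in feature_cols) {
    sub <- features[features$group == g, ]
    m <- tapply(sub[[fc]], list(sub$subject_id, sub$deviant_kind), identity)
    m <- matrix(unlist(m), nrow = nrow(m), dimnames = dimnames(m))
    if (any(!is.finite(m))) {
      stop("incomplete design: missing ", fc, " cells in group '", g, "'",
           call. = FALSE)
    }
    r <- rm_anova(m)
    rm_res[[length(rm_res) + 1]] <- tibble::tibble(
      group = g, feature = fc, F = r$F, df1 = r$df_effect, df2 = r$df_error,
      p = r$p
    )
    b <- bonferroni_pairwise(m)
    b$group <- g
    b$feature <- fc
    pw[[length(pw) + 1]] <- b
  }

  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  structure(
    list(
      oneway = bind(oneway, tibble::tibble(feature = character(),
                                           deviant_kind = character(),
                                           F = numeric(), df1 = numeric(),
                                           df2 = numeric(), p = numeric())),
      tukey = bind(tukey, NULL),
      rm = bind(rm_res, NULL),
      pairwise = bind(pw, NULL)
    ),
    class = "mmn_stats_bundle"
  )
}

#' Write / read a stats bundle as JSON
#'
#' @param bundle An `mmn_stats_bundle`.
#' @param path JSON path.
#' @export
write_stats_bundle <- function(bundle, path) {
  jsonlite::write_json(unclass(bundle), path, dataframe = "rows",
                       digits = NA, auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_stats_bundle
#' @export
read_stats_bundle <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  structure(lapply(x, tibble::as_tibble), class = "mmn_stats_bundle")
}
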