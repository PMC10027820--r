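# Reader-level statistics: the combined comprehension ability score,
# correlations between network metrics and ability, and skilled vs.
# less-skilled group comparisons.

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NULL)
  (x - mean(x)) / s
}

#' Combined comprehension ability score
#'
#' For each reader, sums the within-cohort z-scores of (a) post-reading
#' assessment accuracy, (b) standardized reading-test score, and (c) the
#' reversed total reading time, computed as the cohort maximum minus the raw
#' reading time so that faster readers score higher. Sample (n - 1) standard
#' deviations are used throughout. The score is invariant to affine rescaling
#' of any component.
#'
#' @param outcomes Data frame with columns `participant_id`, `assessment`,
#'   `gsrt`, `total_rt_ms`.
#' @return `outcomes` with a `comprehension_ability` column appended.
#' @export
comprehension_score <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            all(c("participant_id", "assessment", "gsrt", "total_rt_ms") %in%
                  names(outcomes)))
  if (nrow(outcomes) < 2L) stop("need at least 2 readers to z-score a cohort")
  za <- zscore(outcomes$assessment)
  zg <- zscore(outcomes$gsrt)
  zr <- zscore(max(outcomes$total_rt_ms) - outcomes$total_rt_ms)
  for (comp in c("assessment", "gsrt", "total_rt_ms")) {
    z <- switch(comp, assessment = za, gsrt = zg, total_rt_ms = zr)
    if (is.null(z)) {
      stop("component '", comp, "' is constant across the cohort; ",
           "comprehension ability undefined")
    }
  }
  outcomes$comprehension_ability <- za + zg + zr
  outcomes
}

#' Pearson correlation with two-tailed p value
#'
#' Pearson's r with the two-tailed p value from the t transform of r on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither constant.
#' @return List with `r`, `p`, `n`, `df`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}

#' Median split into skilled and less-skilled readers
#'
#' Stable split on the comprehension ability score: readers are ordered by
#' decreasing ability (ties broken by `participant_id` order, with a message
#' when a tie spans the boundary), the top half become the skilled group, and
#' with an odd cohort the median reader joins the lower group.
#'
#' @param outcomes Data frame with `comprehension_ability` (see
#'   [comprehension_score()]).
#' @return List with data frames `skilled` and `less_skilled`.
#' @export
split_groups <- function(outcomes) {
  stopifnot(is.data.frame(outcomes),
            "comprehension_ability" %in% names(outcomes))
  n <- nrow(outcomes)
  if (n < 2L) stop("need at least 2 readers to split")
  ord <- order(-outcomes$comprehension_ability, outcomes$participant_id)
  sorted <- outcomes[ord, , drop = FALSE]
  n_top <- n %/% 2L
  if (sorted$comprehension_ability[n_top] ==
      sorted$comprehension_ability[n_top + 1L]) {
    message("ability tie spans the median; split resolved by participant_id order")
  }
  list(skilled = sorted[seq_len(n_top), , drop = FALSE],
       less_skilled = sorted[(n_top + 1L):n, , drop = FALSE])
}

#' Independent-samples t test with Cohen's d
#'
#' Student's pooled-variance two-sample t test (two-tailed,
#' df = n1 + n2 - 2) plus Cohen's d computed with the pooled standard
#' deviation. The pooled form matches conventional psychology reporting for
#' equal-sized groups (e.g. df = 50 for a 26 vs 26 split).
#'
#' @param a,b Numeric vectors (each of length at least 2).
#' @param metric Label carried into the result.
#' @return Object of class `group_comparison`: list with `metric`, `mean_a`,
#'   `mean_b`, `t`, `df`, `p`, `cohens_d`, `n_a`, `n_b`.
#' @export
t_test_groups <- function(a, b, metric = "") {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled variance; t test undefined")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  structure(
    list(metric = metric, mean_a = mean(a), mean_b = mean(b),
         t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
         cohens_d = (mean(a) - mean(b)) / sqrt(sp2), n_a = n1, n_b = n2),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: M1 = %.4g, M2 = %.4g, t(%d) = %.3f, p = %.4g, d = %.3f\n",
              if (nzchar(x$metric)) x$metric else "group comparison",
              x$mean_a, x$mean_b, x$df, x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Share of fixation time spent on function words
#'
#' Total fixation duration on function-word tokens divided by total fixation
#' duration, for one scanpath. The stimulus must carry function-word flags.
#'
#' @param sp A [scanpath()].
#' @param stimulus The matching [text_stimulus()] with `function_flags`.
#' @return Proportion in \[0, 1\].
#' @export
function_word_time_share <- function(sp, stimulus) {
  stopifnot(inherits(sp, "scanpath"), inherits(stimulus, "text_stimulus"))
  if (is.null(stimulus$function_flags)) {
    stop("stimulus carries no function-word flags")
  }
  e <- sp$entries
  total <- sum(e$duration_ms)
  if (total <= 0) stop("zero total fixation duration")
  is_fn <- mapply(function(s, w) stimulus$function_flags[[s]][w],
                  e$sentence_index, e$word_index)
  sum(e$duration_ms[is_fn]) / total
}

#' Correlation table over network metrics and ability
#'
#' Full symmetric matrix of pairwise Pearson correlations (and two-tailed p
#' values) across the chosen columns — the metric-by-metric association table
#' of a cohort analysis.
#'
#' @param df Data frame with one row per reader.
#' @param vars Columns to correlate (default: ability plus the five metrics,
#'   intersected with what is present).
#' @return Object of class `cor_table`: list with matrices `r` and `p` and
#'   the sample size `n`.
#' @export
metric_score_table <- function(df, vars = NULL) {
  stopifnot(is.data.frame(df))
  if (is.null(vars)) {
    vars <- intersect(c("comprehension_ability", "density", "centralization",
                        "transitivity", "efficiency", "small_worldness"),
                      names(df))
  }
  stopifnot(length(vars) >= 2L, all(vars %in% names(df)))
  k <- length(vars)
  r <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      pr <- pearson_r(df[[vars[i]]], df[[vars[j]]])
      r[i, j] <- r[j, i] <- pr$r
      p[i, j] <- p[j, i] <- pr$p
    }
  }
  structure(list(r = r, p = p, n = nrow(df)), class = "cor_table")
}

#' @export
print.cor_table <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations (n = %d); p values in brackets\n", x$n))
  k <- ncol(x$r)
  disp <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      disp[i, j] <- sprintf("%s [%s]", formatC(x$r[i, j], digits = digits,
                                               format = "f"),
                            formatC(x$p[i, j], digits = digits, format = "g"))
    }
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write a correlation table to CSV
#'
#' Writes the r matrix with p values interleaved row-wise beneath each
#' variable, one block per variable.
#'
#' @param tab A `cor_table` from [metric_score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cor_table <- function(tab, path) {
  stopifnot(inherits(tab, "cor_table"))
  vars <- rownames(tab$r)
  rows <- list()
  for (v in vars) {
    rows[[paste0(v, "_r")]] <- tab$r[v, ]
    rows[[paste0(v, "_p")]] <- tab$p[v, ]
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = TRUE)
  invisible(path)
}
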