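#' Paired t test with Cohen's d from difference scores
#'
#' Two-sided paired t on POST - PRE differences, with the standardized
#' within-subject effect size `d = mean(post - pre) / sd(post - pre)`. The
#' POST - PRE sign convention means improvements in undershoot or RMSE come
#' out negative.
#'
#' @param pre,post Paired measurements, equal length `n >= 2`.
#' @return List with `t`, `df`, `p`, `d`, `mean_diff`, `sd_diff`. With
#'   zero-variance differences `d` is `NA` and `degenerate` is `TRUE`.
#' @export
paired_t_and_d <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  diff <- post - pre
  n <- length(diff)
  sdd <- stats::sd(diff)
  if (sdd == 0) {
    return(list(t = 0, df = n - 1L, p = 1, d = NA_real_,
                mean_diff = mean(diff), sd_diff = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(post, pre, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, d = mean(diff) / sdd,
       mean_diff = mean(diff), sd_diff = sdd, degenerate = FALSE)
}

#' Group-by-epoch interaction from change scores
#'
#' The interaction in a 2 (group) x 2 (epoch) mixed design is tested by a
#' pooled-variance independent t test on the PRE-to-POST change scores; the
#' squared statistic is reported as `F(1, n_a + n_b - 2)`.
#'
#' @param group_a_changes,group_b_changes Change scores per group, each
#'   `n >= 2`.
#' @return List with `F`, `df1 = 1`, `df2`, `p`, and the underlying `t`.
#' @export
interaction_from_change_scores <- function(group_a_changes, group_b_changes) {
  na <- length(group_a_changes)
  nb <- length(group_b_changes)
  stopifnot(na >= 2, nb >= 2)
  sp2 <- ((na - 1) * stats::var(group_a_changes) +
          (nb - 1) * stats::var(group_b_changes)) / (na + nb - 2)
  if (sp2 == 0) stop("zero pooled variance of change scores", call. = FALSE)
  tt <- stats::t.test(group_a_changes, group_b_changes, var.equal = TRUE)
  Fv <- unname(tt$statistic)^2
  list(F = Fv, df1 = 1L, df2 = na + nb - 2L, p = tt$p.value,
       t = unname(tt$statistic))
}

#' Holm step-down adjustment of p values
#'
#' Step-down Holm adjustment controlling the family-wise error rate:
#' sorted p values are multiplied by `m, m-1, ..., 1`, cumulative maxima
#' enforce monotonicity, and values are capped at 1. Delegates to
#' [stats::p.adjust()]; order of the input is preserved.
#'
#' @param p_values Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, same order.
#' @export
holm_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "holm")
}

#' Test-retest intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC between
#' two sessions:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with `k = 2`
#' sessions, from the two-way (subject, session) mean squares.
#'
#' @param session1,session2 Paired measurements, `n >= 3`.
#' @return List with `icc`, the mean squares (`msr`, `msc`, `mse`), `n`,
#'   and a `degenerate` flag set when the subject and error mean squares
#'   are both zero.
#' @export
icc_test_retest <- function(session1, session2) {
  n <- length(session1)
  stopifnot(length(session2) == n, n >= 3)
  # balanced two-way decomposition (n subjects x k sessions), closed form
  k <- 2
  y <- cbind(session1, session2)
  grand <- mean(y)
  rmean <- rowMeans(y)
  cmean <- colMeans(y)
  msr <- k * sum((rmean - grand)^2) / (n - 1)
  msc <- n * sum((cmean - grand)^2) / (k - 1)
  resid <- y - outer(rmean, rep(1, k)) - rep(cmean, each = n) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) {
    return(list(icc = NA_real_, msr = msr, msc = msc, mse = mse, n = n,
                degenerate = TRUE))
  }
  list(icc = (msr - mse) / denom, msr = msr, msc = msc, mse = mse, n = n,
       degenerate = FALSE)
}

#' Baseline-adjusted group comparison (ANCOVA)
#'
#' Ordinary least squares of the POST values on a group indicator plus the
#' baseline (PRE) covariate; returns the group coefficient and its
#' two-sided p value.
#'
#' @param post POST values.
#' @param baseline PRE values (covariate).
#' @param group Two-level group labels.
#' @return List with `beta` (group coefficient, second level vs first),
#'   `p`, `se`, and the fitted `model`.
#' @export
ancova_baseline <- function(post, baseline, group) {
  group <- factor(group)
  stopifnot(length(post) == length(baseline),
            length(post) == length(group), nlevels(group) == 2,
            length(post) > 3)
  fit <- stats::lm(post ~ group + baseline)
  cf <- stats::summary.lm(fit)$coefficients
  grow <- grep("^group", rownames(cf))
  if (length(grow) != 1 || any(is.na(stats::coef(fit))))
    stop("group effect not estimable (collinear baseline/group)",
         call. = FALSE)
  list(beta = cf[grow, 1], se = cf[grow, 2], p = cf[grow, 4], model = fit)
}

#' Pearson correlation between change scores
#'
#' @param delta_x,delta_y Change scores (POST - PRE), equal length `n >= 3`.
#' @return List with `r`, `p`, `n`.
#' @export
change_score_correlation <- function(delta_x, delta_y) {
  stopifnot(length(delta_x) == length(delta_y), length(delta_x) >= 3)
  if (stats::sd(delta_x) == 0 || stats::sd(delta_y) == 0)
    stop("zero variance in change scores", call. = FALSE)
  ct <- stats::cor.test(delta_x, delta_y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(delta_x))
}

#' Metrics whose within-group tests form the Holm family
#'
#' The three primary outcomes -- undershoot, RMSE and 1--3 Hz band power --
#' are Holm-corrected together within each group; coherence-band tests are
#' reported unadjusted.
#'
#' @return Character vector of metric names.
#' @export
primary_metrics <- function() c("undershoot", "rmse", "band_power_1_3")

#' Run the full pre/post two-group statistical battery
#'
#' Takes a long-format study table (columns `id`, `group` with levels
#' `sham`/`tdcs`, `metric`, `pre`, `post`) and computes, per metric:
#' group-by-epoch cell means and SDs, within-group paired t tests with
#' Cohen's d (POST - PRE), Holm-adjusted p values within each group across
#' the primary metrics, the change-score interaction `F(1, df2)`, the sham
#' group's PRE-POST ICC(2,1), and the baseline-adjusted ANCOVA group
#' effect. When the three primary metrics are all present, Pearson
#' correlations between the 1--3 Hz power change scores and the
#' undershoot / RMSE change scores are reported overall and per group.
#'
#' @param table Long-format study table data frame.
#' @return An object of class `"stats_report"`: list with `metrics` (one
#'   data-frame row per metric) and `change_correlations`.
#' @export
build_report <- function(table) {
  req <- c("id", "group", "metric", "pre", "post")
  if (!all(req %in% names(table)))
    stop("study table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (anyNA(table[req]))
    stop("study table contains missing values", call. = FALSE)
  groups <- sort(unique(table$group))
  if (!identical(groups, c("sham", "tdcs")))
    stop("group must have levels 'sham' and 'tdcs'", call. = FALSE)
  dup <- duplicated(table[c("id", "metric")])
  if (any(dup))
    stop("duplicate id x metric rows in study table", call. = FALSE)

  metrics <- unique(table$metric)
  rows <- lapply(metrics, function(m) {
    tm <- table[table$metric == m, ]
    sham <- tm[tm$group == "sham", ]
    tdcs <- tm[tm$group == "tdcs", ]
    t_sham <- paired_t_and_d(sham$pre, sham$post)
    t_tdcs <- paired_t_and_d(tdcs$pre, tdcs$post)
    inter <- interaction_from_change_scores(tdcs$post - tdcs$pre,
                                            sham$post - sham$pre)
    icc <- icc_test_retest(sham$pre, sham$post)
    anc <- ancova_baseline(tm$post, tm$pre, tm$group)
    data.frame(
      metric = m,
      sham_pre_mean = mean(sham$pre), sham_pre_sd = stats::sd(sham$pre),
      sham_post_mean = mean(sham$post), sham_post_sd = stats::sd(sham$post),
      tdcs_pre_mean = mean(tdcs$pre), tdcs_pre_sd = stats::sd(tdcs$pre),
      tdcs_post_mean = mean(tdcs$post), tdcs_post_sd = stats::sd(tdcs$post),
      sham_t = t_sham$t, sham_p = t_sham$p, sham_d = t_sham$d,
      tdcs_t = t_tdcs$t, tdcs_p = t_tdcs$p, tdcs_d = t_tdcs$d,
      interaction_F = inter$F, interaction_df2 = inter$df2,
      interaction_p = inter$p,
      icc_sham = icc$icc,
      ancova_beta = anc$beta, ancova_p = anc$p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)

  # Holm family: the primary metrics within each group
  fam <- intersect(primary_metrics(), out$metric)
  out$sham_p_holm <- NA_real_
  out$tdcs_p_holm <- NA_real_
  if (length(fam)) {
    sel <- match(fam, out$metric)
    out$sham_p_holm[sel] <- holm_adjust(out$sham_p[sel])
    out$tdcs_p_holm[sel] <- holm_adjust(out$tdcs_p[sel])
  }

  corr <- NULL
  if (all(c("band_power_1_3", "undershoot", "rmse") %in% metrics)) {
    wide <- function(m, rows_sel) {
      tm <- table[table$metric == m & rows_sel, ]
      tm <- tm[order(tm$id), ]
      tm$post - tm$pre
    }
    per_scope <- function(rows_sel, label) {
      dp <- wide("band_power_1_3", rows_sel)
      du <- wide("undershoot", rows_sel)
      dr <- wide("rmse", rows_sel)
      cu <- change_score_correlation(dp, du)
      cr <- change_score_correlation(dp, dr)
      data.frame(scope = label,
                 r_power_undershoot = cu$r, p_power_undershoot = cu$p,
                 r_power_rmse = cr$r, p_power_rmse = cr$p,
                 n = cu$n, stringsAsFactors = FALSE)
    }
    corr <- rbind(per_scope(rep(TRUE, nrow(table)), "all"),
                  per_scope(table$group == "sham", "sham"),
                  per_scope(table$group == "tdcs", "tdcs"))
  }

  structure(list(metrics = out, change_correlations = corr),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, digits = 3, ...) {
  m <- x$metrics
  cat("Summary of pre/post statistics (mean +/- SD per cell)\n")
  hdr <- sprintf("%-16s %-15s %-15s %-15s %-15s %7s %9s %9s",
                 "Metric", "Sham PRE", "Sham POST", "tDCS PRE", "tDCS POST",
                 "tDCS d", "Int. p", "tDCS p")
  cat(hdr, "\n")
  cell <- function(mu, sd) sprintf("%.2f +/- %.2f", mu, sd)
  for (i in seq_len(nrow(m))) {
    pt <- if (is.na(m$tdcs_p_holm[i])) m$tdcs_p[i] else m$tdcs_p_holm[i]
    cat(sprintf("%-16s %-15s %-15s %-15s %-15s %7.2f %9.3f %9.3f\n",
                m$metric[i],
                cell(m$sham_pre_mean[i], m$sham_pre_sd[i]),
                cell(m$sham_post_mean[i], m$sham_post_sd[i]),
                cell(m$tdcs_pre_mean[i], m$tdcs_pre_sd[i]),
                cell(m$tdcs_post_mean[i], m$tdcs_post_sd[i]),
                m$tdcs_d[i], m$interaction_p[i], pt))
  }
  if (!is.null(x$change_correlations)) {
    cat("Change-score correlations (delta 1-3 Hz power vs delta metric):\n")
    cc <- x$change_correlations
    for (i in seq_len(nrow(cc)))
      cat(sprintf("  %-5s undershoot r=%.2f (p=%.3f); rmse r=%.2f (p=%.3f)\n",
                  cc$scope[i], cc$r_power_undershoot[i],
                  cc$p_power_undershoot[i], cc$r_power_rmse[i],
                  cc$p_power_rmse[i]))
  }
  invisible(x)
}
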