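#' Two-sample Mann-Whitney U test
#'
#' Rank-sum test with midranks for ties. With `method = "auto"`, the p-value
#' is exact (full enumeration of the permutation distribution of U) when both
#' groups have at most `exact_max` observations and the pooled data are
#' tie-free; otherwise a tie-corrected normal approximation with continuity
#' correction is used. Two-tailed exact p is twice the smaller tail
#' probability, capped at 1.
#'
#' @param a,b Numeric vectors (both nonempty).
#' @param method `"auto"`, `"exact"` or `"normal_approx"`.
#' @param exact_max Per-group size limit for the exact path under `"auto"`
#'   (default 8: enumeration cost is at worst `choose(16, 8)`).
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return A `vq_test` object: `test`, `statistic` (U for `a` vs `b`),
#'   `p_two_tailed`, `method` used, `tie_correction_applied`, group sizes.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal_approx"),
                           exact_max = 8L, continuity = TRUE) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b) || anyNA(a) || anyNA(b)) {
    stop("mann_whitney_u: both groups must be nonempty and free of NA",
         call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- switch(method,
    auto = !ties && length(a) <= exact_max && length(b) <= exact_max,
    exact = if (ties) stop("mann_whitney_u: exact method requires tie-free data",
                           call. = FALSE) else TRUE,
    normal_approx = FALSE)
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = continuity))
  structure(list(test = "mann_whitney_u",
                 statistic = unname(wt$statistic),
                 p_two_tailed = min(wt$p.value, 1),
                 method = if (use_exact) "exact" else "normal_approx",
                 tie_correction_applied = ties && !use_exact,
                 n = c(length(a), length(b))),
            class = "vq_test")
}

#' Kruskal-Wallis rank test across several groups
#'
#' Tie-corrected H statistic with p from the chi-squared approximation on
#' k - 1 degrees of freedom. Fully degenerate data (every pooled value
#' identical) make the tie correction 0/0; by convention this returns H = 0,
#' p = 1 with a warning.
#'
#' @param groups List of two or more nonempty numeric vectors.
#' @return A `vq_test` object (statistic = H, `method = "chisq_approx"`).
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("kruskal_wallis: need a list of >= 2 groups", call. = FALSE)
  }
  if (any(!vapply(groups, length, 0L))) {
    stop("kruskal_wallis: every group must be nonempty", call. = FALSE)
  }
  x <- unlist(groups, use.names = FALSE)
  ties <- anyDuplicated(x) > 0L
  if (length(unique(x)) == 1L) {
    warning("kruskal_wallis: all observations identical; H = 0, p = 1",
            call. = FALSE)
    return(structure(list(test = "kruskal_wallis", statistic = 0,
                          p_two_tailed = 1, method = "chisq_approx",
                          tie_correction_applied = TRUE,
                          n = lengths(groups)),
                     class = "vq_test"))
  }
  kt <- stats::kruskal.test(groups)
  structure(list(test = "kruskal_wallis", statistic = unname(kt$statistic),
                 p_two_tailed = kt$p.value, method = "chisq_approx",
                 tie_correction_applied = ties, n = lengths(groups)),
            class = "vq_test")
}

#' @export
print.vq_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-tailed p = %.4g (%s%s; n = %s)\n",
              x$test, x$statistic, x$p_two_tailed, x$method,
              if (x$tie_correction_applied) ", tie-corrected" else "",
              paste(x$n, collapse = "/")))
  invisible(x)
}

median_range <- function(x) {
  x <- x[!is.na(x)]
  c(n = length(x), median = stats::median(x), min = suppressWarnings(min(x)),
    max = suppressWarnings(max(x)))
}

#' Group comparison report across tissue types
#'
#' Reproduces the study's comparison layout for each outcome and stratum:
#' a Kruskal-Wallis omnibus test over the endometrial tissue groups (control
#' endometrium, eutopic and ectopic endometrium of cases) followed by
#' pairwise Mann-Whitney post hoc tests, plus the adenomyosis-vs-control
#' myometrium pairwise comparison; group medians (range) throughout, with
#' significance flags at the configured two-tailed alpha. No multiple-testing
#' correction is applied by default, mirroring the original analysis; Holm
#' adjustment of the pairwise p-values is available.
#'
#' @param outcomes Per-specimen data frame: columns `specimen_id`, `group`,
#'   `tissue_type`, `cycle_phase`, `medication` plus outcome columns.
#' @param outcome_cols Outcome columns to compare (default the vessel
#'   outcomes present in the table).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param stratify_by `"cycle_phase"` (default), `"medication"`, or `NULL`
#'   for pooled.
#' @param adjust `"none"` (default) or `"holm"` for pairwise p-values within
#'   an outcome x stratum family.
#' @return A `comparison_report`: `tests` (one row per omnibus/pairwise test
#'   with statistic, p, significance flag and median difference) and
#'   `summaries` (n, median, min, max per group), plus `alpha`.
#' @export
compare_tissues <- function(outcomes,
                            outcome_cols = intersect(
                              c("bvd_per_mm2", "lvd_per_mm2", "pct_cd31_area",
                                "pct_pdpn_area", "mature_ratio",
                                "ihs_stroma", "ihs_glands", "ihs_myometrium"),
                              names(outcomes)),
                            alpha = 0.05, stratify_by = "cycle_phase",
                            adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(outcomes), alpha > 0, alpha < 1,
            all(c("specimen_id", "group", "tissue_type") %in% names(outcomes)))
  strata <- if (is.null(stratify_by)) list(pooled = outcomes) else
    split(outcomes, outcomes[[stratify_by]])

  endo_levels <- c(control = "control_endometrium",
                   eutopic = "eutopic_endometrium",
                   ectopic = "ectopic_endometrium")
  tests <- list(); summaries <- list()
  add_summary <- function(outcome, stratum, label, x) {
    s <- median_range(x)
    summaries[[length(summaries) + 1L]] <<- data.frame(
      outcome = outcome, stratum = stratum, group = label, n = s[["n"]],
      median = s[["median"]], min = s[["min"]], max = s[["max"]],
      stringsAsFactors = FALSE)
  }
  add_test <- function(outcome, stratum, comparison, tt, delta = NA_real_) {
    tests[[length(tests) + 1L]] <<- data.frame(
      outcome = outcome, stratum = stratum, comparison = comparison,
      test = tt$test, statistic = tt$statistic, p = tt$p_two_tailed,
      method = tt$method, median_diff = delta,
      significant = tt$p_two_tailed < alpha, stringsAsFactors = FALSE)
  }

  for (stratum in names(strata)) {
    d <- strata[[stratum]]
    for (outcome in outcome_cols) {
      grp <- lapply(endo_levels, function(tt) {
        x <- d[[outcome]][d$tissue_type == tt]
        x[!is.na(x)]
      })
      for (nm in names(grp)) {
        add_summary(outcome, stratum, paste0(nm, "_endometrium"), grp[[nm]])
      }
      nonempty <- grp[lengths(grp) > 0L]
      if (length(nonempty) >= 2L) {
        add_test(outcome, stratum, "endometrium_omnibus",
                 kruskal_wallis(nonempty))
        prs <- utils::combn(names(nonempty), 2L, simplify = FALSE)
        pair_rows <- integer(0)
        for (pr in prs) {
          tt <- mann_whitney_u(nonempty[[pr[1]]], nonempty[[pr[2]]])
          add_test(outcome, stratum, paste0(pr[1], "_vs_", pr[2]), tt,
                   delta = stats::median(nonempty[[pr[1]]]) -
                           stats::median(nonempty[[pr[2]]]))
          pair_rows <- c(pair_rows, length(tests))
        }
        if (adjust == "holm" && length(pair_rows)) {
          ps <- vapply(tests[pair_rows], function(r) r$p, 0)
          ph <- stats::p.adjust(ps, "holm")
          for (k in seq_along(pair_rows)) {
            tests[[pair_rows[k]]]$p <- ph[k]
            tests[[pair_rows[k]]]$significant <- ph[k] < alpha
          }
        }
      } else {
        warning(sprintf(
          "compare_tissues: < 2 nonempty endometrial groups for %s in stratum %s; tests omitted",
          outcome, stratum), call. = FALSE)
      }
      # myometrium: adenomyosis vs control, pairwise only
      myo_a <- d[[outcome]][d$tissue_type == "myometrium" & d$group == "adenomyosis"]
      myo_c <- d[[outcome]][d$tissue_type == "myometrium" & d$group == "control"]
      myo_a <- myo_a[!is.na(myo_a)]; myo_c <- myo_c[!is.na(myo_c)]
      if (length(myo_a) || length(myo_c)) {
        add_summary(outcome, stratum, "adenomyosis_myometrium", myo_a)
        add_summary(outcome, stratum, "control_myometrium", myo_c)
        if (length(myo_a) && length(myo_c)) {
          add_test(outcome, stratum, "adenomyosis_vs_control_myometrium",
                   mann_whitney_u(myo_a, myo_c),
                   delta = stats::median(myo_a) - stats::median(myo_c))
        }
      }
    }
  }
  structure(list(tests = do.call(rbind, tests),
                 summaries = do.call(rbind, summaries), alpha = alpha,
                 stratify_by = stratify_by %||% "pooled", adjust = adjust),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> alpha = %g, stratified by %s\n", x$alpha,
              x$stratify_by))
  sig <- x$tests[x$tests$significant, , drop = FALSE]
  cat(sprintf("  %d tests, %d significant\n", nrow(x$tests), nrow(sig)))
  if (nrow(sig)) {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  * %s | %s | %s: p = %.4g\n", sig$outcome[i],
                  sig$stratum[i], sig$comparison[i], sig$p[i]))
    }
  }
  invisible(x)
}

#' Anti-angiogenic medication subgroup comparison
#'
#' Pooled-phase Mann-Whitney comparison of eutopic-endometrium blood and
#' lymph vessel density between specimens from patients using medication
#' with an anti-angiogenic profile (NSAIDs, tranexamic acid) and the rest.
#'
#' @param outcomes Per-specimen outcome table (see [compare_tissues()]).
#' @param outcome_cols Outcomes to compare (default BVD and LVD).
#' @param alpha Two-tailed significance level.
#' @return A `comparison_report` (tests omitted, with a warning, when a
#'   subgroup is empty).
#' @export
medication_subgroup <- function(outcomes,
                                outcome_cols = intersect(
                                  c("bvd_per_mm2", "lvd_per_mm2"),
                                  names(outcomes)),
                                alpha = 0.05) {
  stopifnot(is.data.frame(outcomes), "medication" %in% names(outcomes))
  d <- outcomes[outcomes$tissue_type == "eutopic_endometrium", , drop = FALSE]
  tests <- list(); summaries <- list()
  for (outcome in outcome_cols) {
    yes <- d[[outcome]][d$medication == "antiangiogenic"]
    no <- d[[outcome]][d$medication == "none_other"]
    yes <- yes[!is.na(yes)]; no <- no[!is.na(no)]
    s1 <- median_range(yes); s0 <- median_range(no)
    summaries[[length(summaries) + 1L]] <- data.frame(
      outcome = outcome, stratum = "pooled",
      group = c("antiangiogenic", "none_other"),
      n = c(s1[["n"]], s0[["n"]]), median = c(s1[["median"]], s0[["median"]]),
      min = c(s1[["min"]], s0[["min"]]), max = c(s1[["max"]], s0[["max"]]),
      stringsAsFactors = FALSE)
    if (!length(yes) || !length(no)) {
      warning("medication_subgroup: empty subgroup for ", outcome,
              "; test omitted", call. = FALSE)
      next
    }
    tt <- mann_whitney_u(yes, no)
    tests[[length(tests) + 1L]] <- data.frame(
      outcome = outcome, stratum = "pooled",
      comparison = "antiangiogenic_vs_none", test = tt$test,
      statistic = tt$statistic, p = tt$p_two_tailed, method = tt$method,
      median_diff = stats::median(yes) - stats::median(no),
      significant = tt$p_two_tailed < alpha, stringsAsFactors = FALSE)
  }
  structure(list(tests = if (length(tests)) do.call(rbind, tests) else NULL,
                 summaries = do.call(rbind, summaries), alpha = alpha,
                 stratify_by = "medication", adjust = "none"),
            class = "comparison_report")
}
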