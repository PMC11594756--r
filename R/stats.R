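#' Kruskal-Wallis group comparison
#'
#' Nonparametric omnibus comparison of two or more groups by rank sums, with
#' tie correction, as used for group-level comparison of activity parameters
#' (significance conventionally at p <= 0.05). The H statistic and the
#' chi-square approximation with k - 1 degrees of freedom come from
#' [stats::kruskal.test()]; the degenerate case of all observations being
#' identical (rank variance zero) is reported as H = 0, p = 1.
#'
#' For small samples (total N <= 10) an exact permutation p-value is
#' available: the proportion of all distinct assignments of the pooled
#' values to the given group sizes whose H reaches the observed one.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length as `values`; at least two groups,
#'   each nonempty.
#' @param exact_permutation compute the exact permutation p-value (only for
#'   N <= 10).
#' @return List of class `htest` with `statistic` (H), `parameter` (df),
#'   `p.value`, and (when requested) `p.value.permutation`.
#' @export
kruskal_wallis <- function(values, groups, exact_permutation = FALSE) {
  values <- as.numeric(values)
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values and groups lengths differ")
  if (anyNA(values) || anyNA(groups)) stop("missing values not allowed")
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) == 0L)) stop("every group must be nonempty")
  if (length(values) < 3L) stop("need at least 3 observations in total")
  k <- nlevels(g)
  if (diff(range(values)) == 0) {
    out <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                parameter = c(df = k - 1L), p.value = 1,
                method = "Kruskal-Wallis rank sum test (degenerate: all values tied)",
                data.name = "values by groups")
    class(out) <- "htest"
    return(out)
  }
  out <- stats::kruskal.test(values, g)
  if (exact_permutation) {
    n <- length(values)
    if (n > 10L) stop("exact permutation p-value supported only for N <= 10")
    sizes <- as.integer(table(g))
    assigns <- .group_assignments(n, sizes)
    h_obs <- unname(out$statistic)
    h_all <- vapply(assigns, function(a) {
      unname(stats::kruskal.test(values, factor(a))$statistic)
    }, numeric(1))
    out$p.value.permutation <- mean(h_all >= h_obs - 1e-12)
    out$method <- paste(out$method, "with exact permutation p-value")
  }
  out
}

# All distinct assignments of n items to groups of the given sizes, as a list
# of integer label vectors. Sizes must sum to n.
.group_assignments <- function(n, sizes) {
  stopifnot(sum(sizes) == n)
  res <- list()
  recurse <- function(remaining, labels, gi) {
    if (gi == length(sizes)) {
      labels[remaining] <- gi
      res[[length(res) + 1L]] <<- labels
      return(invisible(NULL))
    }
    for (pick in utils::combn(remaining, sizes[gi], simplify = FALSE)) {
      lab2 <- labels
      lab2[pick] <- gi
      recurse(setdiff(remaining, pick), lab2, gi + 1L)
    }
  }
  recurse(seq_len(n), integer(n), 1L)
  res
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-sample relative mRNA expression from qPCR cycle-threshold
#' (Ct) values: `dCt = Ct_target - Ct_reference` per sample,
#' `ddCt = dCt - mean(dCt)` over the control group, and relative expression
#' `2^(-ddCt)`. A control sample sitting exactly at the control mean has
#' expression 1; `ddCt = -1` doubles expression.
#'
#' @param ct data frame with columns `sample_id`, `group`, `ct_target`,
#'   `ct_reference`. Ct values must be finite and positive.
#' @param control_group label of the control (calibrator) group.
#' @return The input with `delta_ct`, `delta_delta_ct` and `rel_expression`
#'   columns appended.
#' @export
delta_delta_ct <- function(ct, control_group = "control") {
  req <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(req %in% names(ct))) {
    stop("ct table needs columns: ", paste(req, collapse = ", "))
  }
  if (anyNA(ct$ct_reference)) stop("missing reference-gene Ct values")
  if (anyNA(ct$ct_target)) stop("missing target-gene Ct values")
  if (any(!is.finite(ct$ct_target)) || any(!is.finite(ct$ct_reference)) ||
      any(ct$ct_target <= 0) || any(ct$ct_reference <= 0)) {
    stop("Ct values must be finite and positive")
  }
  if (!any(ct$group == control_group)) {
    stop("no samples in control group '", control_group, "'")
  }
  out <- ct
  out$delta_ct <- out$ct_target - out$ct_reference
  calib <- mean(out$delta_ct[out$group == control_group])
  out$delta_delta_ct <- out$delta_ct - calib
  out$rel_expression <- 2^(-out$delta_delta_ct)
  out
}

#' Fold changes of longitudinal metrics versus a baseline DIV
#'
#' For every (group, DIV, metric), the ratio of the group mean at that DIV to
#' the group's mean at the baseline DIV. Zero or missing baselines yield
#' `NA` ratios.
#'
#' @param summary data frame as from [longitudinal_summary()] (columns
#'   `group`, `div` plus metric columns).
#' @param baseline_div baseline day in vitro (default 14).
#' @param metrics metric column names; defaults to the standard activity
#'   parameters present in `summary`.
#' @return Data frame with columns `group`, `div`, `metric`, `mean`,
#'   `baseline_mean`, `fold_change`.
#' @export
fold_change_report <- function(summary, baseline_div = 14L, metrics = NULL) {
  stopifnot(all(c("group", "div") %in% names(summary)))
  if (is.null(metrics)) metrics <- intersect(.metric_cols, names(summary))
  if (!length(metrics)) stop("no metric columns found")
  rows <- list()
  for (g in unique(summary$group)) {
    sg <- summary[summary$group == g, , drop = FALSE]
    base <- sg[sg$div == baseline_div, , drop = FALSE]
    for (dv in sort(unique(sg$div))) {
      sd_ <- sg[sg$div == dv, , drop = FALSE]
      for (m in metrics) {
        mu <- mean(sd_[[m]], na.rm = TRUE)
        b <- if (nrow(base)) mean(base[[m]], na.rm = TRUE) else NA_real_
        fc <- if (!is.finite(b) || b == 0 || !is.finite(mu)) NA_real_ else mu / b
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, div = dv, metric = m,
          mean = if (is.finite(mu)) mu else NA_real_,
          baseline_mean = if (is.finite(b)) b else NA_real_,
          fold_change = fc, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison table for a longitudinal summary
#'
#' Runs [kruskal_wallis()] on one or more metrics at every DIV with at least
#' two groups represented (and at least 3 recordings in total).
#'
#' @param summary data frame as from [longitudinal_summary()].
#' @param metrics metric columns to test.
#' @return Data frame with columns `div`, `metric`, `n`, `H`, `df`, `p`.
#' @export
group_comparisons <- function(summary,
                              metrics = c("pct_spikes_in_bursts", "n_large_per_min")) {
  stopifnot(all(c("group", "div") %in% names(summary)))
  metrics <- intersect(metrics, names(summary))
  rows <- list()
  for (dv in sort(unique(summary$div))) {
    sd_ <- summary[summary$div == dv, , drop = FALSE]
    for (m in metrics) {
      ok <- is.finite(sd_[[m]])
      if (length(unique(sd_$group[ok])) < 2L || sum(ok) < 3L) next
      kt <- kruskal_wallis(sd_[[m]][ok], sd_$group[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        div = dv, metric = m, n = sum(ok),
        H = unname(kt$statistic), df = unname(kt$parameter),
        p = kt$p.value, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(div = integer(0), metric = character(0), n = integer(0),
                      H = numeric(0), df = numeric(0), p = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
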