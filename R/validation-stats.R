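# Validation arithmetic for small two-group (h)MeDIP studies: comparative-CT
# qPCR enrichment, MassARRAY-style per-CpG amplicon methylation summaries,
# and the two-group tests (pooled t, Mann-Whitney) used for clinical
# characteristic tables.

group_comparison <- function(statistic, df, p_value, test) {
  structure(list(statistic = statistic, df = df,
                 p_value = p_value, test = test),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g%s, p = %.4g\n", x$test, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %g", x$df),
              x$p_value))
  invisible(x)
}

#' Comparative-CT relative enrichment
#'
#' Relative IP enrichment over input from qPCR cycle thresholds:
#' `2^(ct_input - ct_ip)`. Equal Cts give 1; each cycle of earlier IP
#' amplification doubles the enrichment.
#'
#' @param ct_input,ct_ip cycle-threshold values (vectorized, finite).
#' @return Fold enrichment, `2^(ct_input - ct_ip)`.
#' @export
qpcr_relative_enrichment <- function(ct_input, ct_ip) {
  if (any(!is.finite(ct_input)) || any(!is.finite(ct_ip))) {
    stop("Ct values must be finite")
  }
  2^(ct_input - ct_ip)
}

#' Pooled-variance two-sample Student's t-test
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @return A `GroupComparison` with the t statistic, `df = nx + ny - 2` and
#'   the two-sided p-value. If both samples have zero variance the test is
#'   degenerate: equal means give p = 1, unequal means p = 0 (each with a
#'   warning).
#' @export
pooled_t_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 values per group")
  df <- length(x) + length(y) - 2
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("zero pooled variance with equal means; p = 1")
      return(group_comparison(0, df, 1, "pooled-t"))
    }
    warning("zero pooled variance with unequal means; p = 0")
    return(group_comparison(sign(mean(x) - mean(y)) * Inf, df, 0, "pooled-t"))
  }
  fit <- stats::t.test(x, y, var.equal = TRUE)
  group_comparison(unname(fit$statistic), unname(fit$parameter),
                   fit$p.value, "pooled-t")
}

welch_t_test <- function(x, y) {
  fit <- stats::t.test(x, y)
  group_comparison(unname(fit$statistic), unname(fit$parameter),
                   fit$p.value, "welch-t")
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact mode enumerates all `choose(n1 + n2, n1)` group assignments of the
#' midrank-tied pooled sample and reports the two-sided probability of a U
#' statistic at least as far from its null mean as observed; it is feasible
#' for `n1 + n2 <= 12`. Asymptotic mode uses the normal approximation with
#' tie-corrected variance and no continuity correction; both-samples-constant
#' ties give U at its null mean and p = 1.
#'
#' @param x,y numeric vectors.
#' @param mode `"exact"` or `"asymptotic"`.
#' @return A `GroupComparison`; `statistic` is U for `x` (df is `NA`).
#' @export
mann_whitney <- function(x, y, mode = c("exact", "asymptotic")) {
  mode <- match.arg(mode)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))                      # midranks for ties
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (mode == "exact") {
    if (n > 12) {
      stop("exact enumeration limited to n1 + n2 <= 12; use mode = 'asymptotic'")
    }
    sets <- combn(n, n1)
    base <- n1 * (n1 + 1) / 2
    u_all <- colSums(matrix(r[sets], nrow = n1)) - base
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    return(group_comparison(u_obs, NA_real_, p, "mann-whitney-exact"))
  }
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(group_comparison(u_obs, NA_real_, 1, "mann-whitney-asymptotic"))
  }
  z <- (u_obs - mu) / sqrt(sigma2)
  group_comparison(u_obs, NA_real_, 2 * pnorm(-abs(z)),
                   "mann-whitney-asymptotic")
}

#' Summarize per-CpG amplicon methylation ratios
#'
#' Missing (`NA`) readings are excluded. Each sample's amplicon methylation
#' is the mean of its non-missing CpG-unit ratios; each group's level is the
#' mean of its sample means. Per CpG unit, the groups are compared with a
#' pooled t-test.
#'
#' @param records data.frame with columns `amplicon_id`, `cpg_unit_id`,
#'   `sample_id`, `group` (`"case"`/`"control"`), `ratio` (in `[0, 1]` or
#'   `NA`).
#' @return List with `amplicon_summary` (data.frame: `amplicon_id`, `group`,
#'   `mean_ratio`, `n_samples`) and `cpg_tests` (data.frame: `amplicon_id`,
#'   `cpg_unit_id`, `mean_case`, `mean_control`, `statistic`, `p_value`).
#'   Amplicons with a group entirely missing are skipped with a message.
#' @export
amplicon_methylation_summary <- function(records) {
  need <- c("amplicon_id", "cpg_unit_id", "sample_id", "group", "ratio")
  stopifnot(all(need %in% names(records)))
  rec <- records[!is.na(records$ratio), , drop = FALSE]
  if (any(rec$ratio < 0 | rec$ratio > 1)) {
    stop("methylation ratios must lie in [0, 1]")
  }
  if (!all(rec$group %in% GROUPS)) stop("group must be 'case' or 'control'")
  summaries <- list(); tests <- list()
  for (amp in unique(rec$amplicon_id)) {
    a <- rec[rec$amplicon_id == amp, , drop = FALSE]
    if (length(unique(a$group)) < 2) {
      message("amplicon ", amp, " skipped: one group entirely missing")
      next
    }
    sm <- aggregate(ratio ~ sample_id + group, a, mean)
    gm <- aggregate(ratio ~ group, sm, mean)
    ns <- aggregate(sample_id ~ group, sm, function(s) length(unique(s)))
    summaries[[amp]] <- data.frame(
      amplicon_id = amp, group = gm$group, mean_ratio = gm$ratio,
      n_samples = ns$sample_id[match(gm$group, ns$group)],
      stringsAsFactors = FALSE)
    for (unit in unique(a$cpg_unit_id)) {
      u <- a[a$cpg_unit_id == unit, , drop = FALSE]
      xs <- u$ratio[u$group == "case"]; ys <- u$ratio[u$group == "control"]
      stat <- p <- NA_real_
      if (length(xs) >= 2 && length(ys) >= 2) {
        cmp <- suppressWarnings(pooled_t_test(xs, ys))
        stat <- cmp$statistic; p <- cmp$p_value
      }
      tests[[paste(amp, unit)]] <- data.frame(
        amplicon_id = amp, cpg_unit_id = unit,
        mean_case = if (length(xs)) mean(xs) else NA_real_,
        mean_control = if (length(ys)) mean(ys) else NA_real_,
        statistic = stat, p_value = p, stringsAsFactors = FALSE)
    }
  }
  reset <- function(x) {
    if (!length(x)) return(NULL)
    out <- do.call(rbind, x)
    rownames(out) <- NULL
    out
  }
  list(amplicon_summary = reset(summaries), cpg_tests = reset(tests))
}

#' Compare clinical characteristics between groups
#'
#' Applies a pooled t-test per characteristic by default, with optional
#' per-row overrides (`"welch-t"`, `"mann-whitney-exact"`,
#' `"mann-whitney-asymptotic"`), reproducing the usual demographics-table
#' layout of small case/control studies.
#'
#' @param table data.frame: first column `characteristic`, remaining columns
#'   one per subject.
#' @param groups named character vector mapping subject columns to
#'   `"case"`/`"control"`.
#' @param overrides optional named list/vector mapping characteristic names
#'   to an alternative test.
#' @return data.frame with `characteristic`, `mean_case`, `mean_control`,
#'   `statistic`, `df`, `p_value`, `test` (rows whose test errors carry `NA`
#'   and the error message in `note`).
#' @export
clinical_table_compare <- function(table, groups, overrides = NULL) {
  stopifnot(names(table)[1] == "characteristic")
  subj <- setdiff(names(table), "characteristic")
  groups <- groups[subj]
  if (any(is.na(groups)) || !all(groups %in% GROUPS)) {
    stop("`groups` must map every subject column to 'case' or 'control'")
  }
  run <- function(test, x, y) {
    switch(test,
           "pooled-t" = pooled_t_test(x, y),
           "welch-t" = welch_t_test(x, y),
           "mann-whitney-exact" = mann_whitney(x, y, "exact"),
           "mann-whitney-asymptotic" = mann_whitney(x, y, "asymptotic"),
           stop("unknown test '", test, "'"))
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    ch <- table$characteristic[i]
    vals <- as.numeric(table[i, subj])
    x <- vals[groups == "case"]; y <- vals[groups == "control"]
    test <- if (!is.null(overrides) && ch %in% names(overrides))
      overrides[[ch]] else "pooled-t"
    out <- data.frame(characteristic = ch, mean_case = mean(x),
                      mean_control = mean(y), statistic = NA_real_,
                      df = NA_real_, p_value = NA_real_, test = test,
                      note = "", stringsAsFactors = FALSE)
    res <- tryCatch(suppressWarnings(run(test, x, y)),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$note <- res
    } else {
      out$statistic <- res$statistic
      out$df <- res$df
      out$p_value <- res$p_value
    }
    out
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Read the bundled clinical characteristics table
#'
#' A per-subject clinical table (one row per characteristic, one column per
#' subject, columns prefixed `case_` / `control_`) suitable for
#' [clinical_table_compare()].
#'
#' @param path TSV path; defaults to the table shipped with the package.
#' @return List with `table` (data.frame) and `groups` (named vector).
#' @export
read_clinical_table <- function(path = system.file("extdata",
                                                   "clinical_table1.tsv",
                                                   package = "medipdiff")) {
  tab <- read.delim(path, check.names = FALSE)
  names(tab)[1] <- "characteristic"
  subj <- setdiff(names(tab), "characteristic")
  groups <- ifelse(startsWith(subj, "case"), "case", "control")
  names(groups) <- subj
  list(table = tab, groups = groups)
}
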