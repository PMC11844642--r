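# Classic qPCR quantification: dCT, ddCT, 2^-ddCT and their t-tests ---------

.check_gene <- function(x, gene) {
  if (!gene %in% ct_genes(x))
    stop_user("unknown gene '", gene, "'; available: ",
              paste(ct_genes(x), collapse = ", "))
}

.two_levels <- function(treatment, control_level) {
  treatment <- as.character(treatment)
  lev <- sort(unique(treatment))
  if (length(lev) > 2)
    stop_user(length(lev), " treatment levels found (",
              paste(lev, collapse = ", "),
              "); analyse one two-level contrast at a time")
  if (length(lev) < 2)
    stop_user("need two treatment levels with samples, found: ",
              paste(lev, collapse = ", "))
  if (!control_level %in% lev)
    stop_user("control level '", control_level, "' not among: ",
              paste(lev, collapse = ", "))
  list(control = control_level, treated = setdiff(lev, control_level))
}

qpcr_test_result <- function(estimate, statistic, df, p_value, method, data_name,
                             estimate_name = "difference in means") {
  est <- estimate
  names(est) <- estimate_name
  structure(list(statistic = c(t = statistic),
                 parameter = c(df = df),
                 p.value = p_value,
                 estimate = est,
                 alternative = "two.sided",
                 method = method,
                 data.name = data_name),
            class = c("qpcr_test", "htest"))
}

# pooled two-sample t with the degenerate zero-variance convention:
# equal constants -> t = 0, p = 1; unequal constants -> p = 0 with a warning
.pooled_t <- function(x, y, method, data_name) {
  n1 <- length(x); n2 <- length(y)
  est <- mean(x) - mean(y)
  df <- n1 + n2 - 2
  if (n1 < 1 || n2 < 1) stop_user("both groups need at least one sample")
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / df
  if (df <= 0 || pooled_var == 0) {
    if (est == 0)
      return(qpcr_test_result(0, 0, max(df, 0), 1, method, data_name))
    warning("zero within-group variance with unequal means; p set to 0",
            call. = FALSE)
    return(qpcr_test_result(est, sign(est) * Inf, max(df, 0), 0, method, data_name))
  }
  ht <- stats::t.test(x, y, var.equal = TRUE)
  qpcr_test_result(est, unname(ht$statistic), unname(ht$parameter),
                   ht$p.value, method, data_name)
}

#' Per-sample delta-CT
#'
#' Computes the per-sample difference `target CT - reference CT`, the
#' normalisation step of the 2^-ddCT workflow. Samples with either cell
#' missing are dropped (their ids are attached as the `"dropped"`
#' attribute); sample order is preserved.
#'
#' @param x a [ct_table] (technical replicates are mean-collapsed first).
#' @param target,reference gene names (case-sensitive).
#' @return Named numeric vector of delta-CT values (CT units), one per
#'   retained sample.
#' @examples
#' tab <- read_ct_table(system.file("extdata", "table2.csv", package = "qpcrmlm"))
#' delta_ct(tab, "MMP10", "GAPDH")
#' @export
delta_ct <- function(x, target, reference) {
  x <- .collapsed(x)
  .check_gene(x, target); .check_gene(x, reference)
  d <- x[[target]] - x[[reference]]
  names(d) <- as.character(.role_col(x, "sample"))
  keep <- !is.na(d)
  out <- d[keep]
  attr(out, "dropped") <- names(d)[!keep]
  out
}

#' Delta-delta-CT between two treatment groups
#'
#' The difference of group-mean delta-CT values, treated minus control. With
#' the treated-minus-control sign convention, a positive ddCT means higher
#' CT (less transcript) under treatment, so [fold_change()] of a positive
#' ddCT is below 1.
#'
#' @param deltas per-sample delta-CT vector, e.g. from [delta_ct()].
#' @param treatment treatment label per element of `deltas`.
#' @param control_level the control label; the other level is "treated".
#' @return `mean(deltas[treated]) - mean(deltas[control])`, in CT units.
#' @examples
#' d <- delta_ct(read_ct_table(system.file("extdata", "table2.csv",
#'                                         package = "qpcrmlm")), "MMP10", "GAPDH")
#' tab <- read_ct_table(system.file("extdata", "table2.csv", package = "qpcrmlm"))
#' delta_delta_ct(d, tab$Treatment, "DMSO")
#' @export
delta_delta_ct <- function(deltas, treatment, control_level) {
  stopifnot(length(deltas) == length(treatment))
  lev <- .two_levels(treatment, control_level)
  treatment <- as.character(treatment)
  mean(deltas[treatment == lev$treated]) - mean(deltas[treatment == lev$control])
}

#' Fold change from a delta-delta-CT
#'
#' Back-transforms a ddCT (log2-scale difference assuming perfect doubling)
#' to a fold change, `2^-ddCT`. CT is inversely related to starting
#' template, hence the minus sign. Statistical testing is better done on
#' the CT (log) scale; this back-transform is for reporting only.
#'
#' @param ddct delta-delta-CT value (CT units).
#' @return Fold change (dimensionless).
#' @export
fold_change <- function(ddct) {
  stopifnot(is.numeric(ddct), all(is.finite(ddct)))
  2^(-ddct)
}

#' t-test on delta-CT between treatment groups (the 2^-ddCT test)
#'
#' Unpaired form: pooled-variance (Student) two-sample t-test of delta-CT
#' between treated and control samples. Paired form (with `paired_by`): a
#' one-sample t-test on the within-subject treated-minus-control delta-CT
#' differences. The estimate equals [delta_delta_ct()] on the same input.
#' `method = "wilcoxon"` switches to the rank-based alternative
#' (rank-sum, or signed-rank when paired).
#'
#' @inheritParams delta_delta_ct
#' @param paired_by optional subject identifier per element of `deltas`;
#'   each subject must have exactly one sample per treatment level.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @param var_equal use the pooled-variance t (default `TRUE`); `FALSE`
#'   gives Welch.
#' @return A `qpcr_test` (printable as an `htest`): estimate (CT units),
#'   t statistic, df, two-sided p-value.
#' @export
ddct_test <- function(deltas, treatment, control_level, paired_by = NULL,
                      method = c("t", "wilcoxon"), var_equal = TRUE) {
  method <- match.arg(method)
  lev <- .two_levels(treatment, control_level)
  treatment <- as.character(treatment)
  x <- deltas[treatment == lev$treated]
  y <- deltas[treatment == lev$control]
  dn <- paste0("dCT by treatment (control = ", control_level, ")")

  if (!is.null(paired_by)) {
    paired_by <- as.character(paired_by)
    per <- table(paired_by, treatment)
    bad <- rownames(per)[per[, lev$treated] != 1 | per[, lev$control] != 1]
    if (length(bad))
      stop_user("pairing error: subject(s) without exactly one sample per level: ",
                paste(bad, collapse = ", "))
    subj <- sort(unique(paired_by))
    diffs <- deltas[treatment == lev$treated][match(subj, paired_by[treatment == lev$treated])] -
      deltas[treatment == lev$control][match(subj, paired_by[treatment == lev$control])]
    if (method == "wilcoxon") {
      ht <- stats::wilcox.test(diffs)
      return(qpcr_test_result(mean(diffs), unname(ht$statistic), NA_real_,
                              ht$p.value, "Wilcoxon signed rank on paired dCT", dn))
    }
    if (stats::sd(diffs) == 0) {
      if (mean(diffs) == 0)
        return(qpcr_test_result(0, 0, length(diffs) - 1, 1, "Paired t-test on dCT", dn))
      warning("zero variance of paired differences; p set to 0", call. = FALSE)
      return(qpcr_test_result(mean(diffs), sign(mean(diffs)) * Inf,
                              length(diffs) - 1, 0, "Paired t-test on dCT", dn))
    }
    ht <- stats::t.test(diffs)
    return(qpcr_test_result(mean(diffs), unname(ht$statistic), unname(ht$parameter),
                            ht$p.value, "Paired t-test on dCT", dn))
  }

  if (method == "wilcoxon") {
    ht <- stats::wilcox.test(x, y)
    return(qpcr_test_result(mean(x) - mean(y), unname(ht$statistic), NA_real_,
                            ht$p.value, "Wilcoxon rank sum on dCT", dn))
  }
  if (!var_equal) {
    ht <- stats::t.test(x, y, var.equal = FALSE)
    return(qpcr_test_result(mean(x) - mean(y), unname(ht$statistic),
                            unname(ht$parameter), ht$p.value,
                            "Welch two-sample t-test on dCT", dn))
  }
  .pooled_t(x, y, "Pooled two-sample t-test on dCT", dn)
}

#' Reference-free t-test on raw target CT (the dCT method)
#'
#' Pooled-variance two-sample t-test on the raw target-gene CT between
#' treatment groups, ignoring any reference gene. This is the valid
#' approach when the reference gene itself responds to treatment.
#'
#' @param x a [ct_table].
#' @param target target gene name.
#' @param control_level control treatment label.
#' @param var_equal pooled-variance t by default; `FALSE` for Welch.
#' @return A `qpcr_test` with estimate (CT units), t, df, two-sided p.
#' @export
dct_test <- function(x, target, control_level, var_equal = TRUE) {
  x <- .collapsed(x)
  .check_gene(x, target)
  treatment <- as.character(.role_col(x, "treatment"))
  v <- x[[target]]
  keep <- !is.na(v)
  if (any(!keep))
    message("dropping ", sum(!keep), " sample(s) with missing ", target, " CT")
  v <- v[keep]; treatment <- treatment[keep]
  lev <- .two_levels(treatment, control_level)
  if (!var_equal) {
    ht <- stats::t.test(v[treatment == lev$treated], v[treatment == lev$control],
                        var.equal = FALSE)
    return(qpcr_test_result(mean(v[treatment == lev$treated]) -
                              mean(v[treatment == lev$control]),
                            unname(ht$statistic), unname(ht$parameter), ht$p.value,
                            "Welch two-sample t-test on target CT",
                            paste0(target, " CT by treatment")))
  }
  .pooled_t(v[treatment == lev$treated], v[treatment == lev$control],
            "Pooled two-sample t-test on target CT",
            paste0(target, " CT by treatment"))
}

#' Amplification efficiency
#'
#' Represents the per-cycle fractional gain `e` of qPCR product, in (0, 1]:
#' `e = 1` is perfect doubling, making CT an exact base-2 log of starting
#' template; `e < 1` makes CT a base-(1+e) log.
#'
#' @param e fractional efficiency in (0, 1].
#' @return An object of class `qpcr_efficiency`.
#' @export
qpcr_efficiency <- function(e) {
  if (!is.numeric(e) || length(e) != 1 || !is.finite(e) || e <= 0 || e > 1)
    stop_user("efficiency must be a single number in (0, 1], got: ",
              paste(format(e), collapse = ", "))
  structure(list(e = e), class = "qpcr_efficiency")
}

#' @export
print.qpcr_efficiency <- function(x, ...) {
  cat("qPCR amplification efficiency: ", format(x$e),
      " (per-cycle gain ", format(1 + x$e), "x)\n", sep = "")
  invisible(x)
}

#' Rescale CT values for amplification efficiency
#'
#' With efficiency `e`, one cycle multiplies template by `1 + e`, so the
#' observed CT is a base-(1+e) log of abundance. By the change-of-base
#' identity, `ct * log2(1 + e)` converts it to the base-2 scale that CT
#' units nominally assume. In the ANCOVA model such a rescaling of either
#' gene is a pure change of scale and leaves all other terms' t-statistics
#' and p-values unchanged.
#'
#' @param ct numeric CT value(s).
#' @param eff a [qpcr_efficiency] or a plain number in (0, 1].
#' @return `ct * log2(1 + e)`, same length as `ct`.
#' @examples
#' efficiency_scaled_ct(20, 0.9)  # 20 * log2(1.9)
#' @export
efficiency_scaled_ct <- function(ct, eff) {
  if (!inherits(eff, "qpcr_efficiency")) eff <- qpcr_efficiency(eff)
  stopifnot(is.numeric(ct))
  ct * log2(1 + eff$e)
}
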