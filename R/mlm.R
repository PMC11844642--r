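# ANCOVA (multivariable linear model) for CT data ---------------------------
#
# The model regresses the target-gene CT on the treatment factor, optional
# categorical nuisance factors (e.g. donor), and the reference-gene CT as a
# numeric covariate whose weight k is *estimated* rather than fixed at the
# ddCT method's implicit k = 1. Because OLS t-statistics are invariant to
# rescaling a covariate (or the response), amplification-efficiency
# differences between genes -- which multiply CT columns by log2(1+e) --
# leave the inference on every other term unchanged.

#' Declare an ANCOVA model for a CT table
#'
#' Specifies the response gene, the categorical factors (treatment plus
#' nuisance factors such as donor) and the reference genes entering as
#' numeric covariates. Usually built from a formula via
#' [parse_model_spec()].
#'
#' @param response response gene name.
#' @param factors character vector of annotation column names to encode as
#'   treatment-contrast factors.
#' @param covariates character vector of reference-gene names entering as
#'   numeric covariates.
#' @param control optional control (baseline) level for the treatment
#'   factor; by default every factor's baseline is its lexicographically
#'   first level.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response, factors = character(), covariates = character(),
                       control = NULL) {
  stopifnot(is.character(response), length(response) == 1)
  if (response %in% covariates)
    stop_user("response '", response, "' cannot also be a covariate")
  structure(list(response = response, factors = factors,
                 covariates = covariates, control = control),
            class = "model_spec")
}

#' Parse a model formula against a CT table
#'
#' Turns `MMP10 ~ Donor + Treatment + GAPDH` (formula or string) into a
#' [model_spec()]: the response must be a gene; each additive right-hand
#' term is classified as a covariate if it names a gene and as a factor if
#' it names an annotation column. Interactions are not supported.
#'
#' @param formula model formula or its character form.
#' @param x the [ct_table] the names are resolved against.
#' @param control optional control level for the treatment factor.
#' @return A `model_spec`.
#' @export
parse_model_spec <- function(formula, x, control = NULL) {
  if (is.character(formula)) formula <- stats::as.formula(formula)
  stopifnot(inherits(formula, "formula"), length(formula) == 3)
  terms_obj <- stats::terms(formula)
  if (any(attr(terms_obj, "order") > 1))
    stop_user("interaction terms are not supported; use additive terms only")
  response <- all.vars(formula[[2]])
  rhs <- attr(terms_obj, "term.labels")
  genes <- ct_genes(x)
  if (!response %in% genes)
    stop_user("response '", response, "' is not a gene column; genes: ",
              paste(genes, collapse = ", "))
  unknown <- setdiff(rhs, c(genes, names(x)))
  if (length(unknown))
    stop_user("unknown model term(s): ", paste(unknown, collapse = ", "))
  model_spec(response,
             factors = rhs[!rhs %in% genes],
             covariates = rhs[rhs %in% genes],
             control = control)
}

#' Build the ANCOVA design matrix
#'
#' Constructs the n x p design: an intercept column of ones, then
#' treatment-contrast dummy columns for each factor (baseline = the
#' lexicographically first level, or the declared control level for the
#' treatment factor), then the reference-gene CT covariates. Factors always
#' precede covariates regardless of formula order. Samples with any
#' required cell missing are dropped and their count reported. Rank
#' deficiency is a hard error naming the collinear columns -- at qPCR
#' sample sizes, silently dropping a column would change the meaning of the
#' remaining terms.
#'
#' @param x a [ct_table] (replicates are mean-collapsed first).
#' @param spec a [model_spec()], or a formula passed to
#'   [parse_model_spec()].
#' @param control optional control level, used when `spec` is a formula.
#' @return A list of class `ct_design`: `X` (design matrix with named
#'   columns), `y` (response CT vector), `baselines` (named list factor ->
#'   omitted level), `sample_ids`, `dropped` (ids of removed samples),
#'   `spec`.
#' @export
build_design <- function(x, spec, control = NULL) {
  x <- .collapsed(x)
  if (!inherits(spec, "model_spec")) spec <- parse_model_spec(spec, x, control)
  .check_gene(x, spec$response)
  for (g in spec$covariates) .check_gene(x, g)
  miss_f <- setdiff(spec$factors, names(x))
  if (length(miss_f))
    stop_user("unknown factor column(s): ", paste(miss_f, collapse = ", "))

  used <- cbind(x[[spec$response]],
                do.call(cbind, c(lapply(spec$covariates, function(g) x[[g]]),
                                 list(deparse.level = 0))))
  fac_vals <- lapply(spec$factors, function(f) as.character(x[[f]]))
  keep <- stats::complete.cases(used) &
    Reduce(`&`, c(lapply(fac_vals, function(v) !is.na(v)), list(rep(TRUE, nrow(x)))))
  dropped <- as.character(.role_col(x, "sample"))[!keep]
  if (length(dropped))
    message("dropping ", length(dropped), " sample(s) with missing cells: ",
            paste(dropped, collapse = ", "))
  x <- x[keep, , drop = FALSE]

  n <- nrow(x)
  treatment_role <- .role(x, "treatment")
  cols <- list("(Intercept)" = rep(1, n))
  baselines <- list()
  for (f in spec$factors) {
    v <- as.character(x[[f]])
    lev <- sort(unique(v))
    if (length(lev) < 2)
      stop_user("factor '", f, "' has a single observed level ('", lev,
                "'); cannot estimate its effect")
    base <- lev[1]
    if (!is.null(spec$control) && identical(f, treatment_role)) {
      if (!spec$control %in% lev)
        stop_user("control level '", spec$control, "' not a level of '", f, "'")
      base <- spec$control
    }
    baselines[[f]] <- base
    for (l in setdiff(lev, base)) cols[[paste0(f, l)]] <- as.numeric(v == l)
  }
  for (g in spec$covariates) cols[[g]] <- x[[g]]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop_user("rank-deficient design: column(s) ",
              paste(aliased, collapse = ", "),
              " are collinear with earlier columns")
  }
  if (n <= ncol(X))
    stop_user("insufficient data: ", n, " observations for ", ncol(X),
              " parameters; need n > p (and preferably n >= 2p)")
  structure(list(X = X, y = x[[spec$response]], baselines = baselines,
                 sample_ids = as.character(.role_col(x, "sample")),
                 dropped = dropped, spec = spec),
            class = "ct_design")
}

#' Ordinary least squares with t inference
#'
#' Fits the linear model by QR (orthogonal) decomposition -- better
#' conditioned than explicit normal equations when covariates are nearly
#' collinear -- and returns coefficient-level inference: standard errors
#' from the `sigma^2 (X'X)^-1` diagonal and two-sided p-values from the
#' Student t distribution with `n - p` residual degrees of freedom (the
#' normal approximation is not defensible at qPCR sample sizes).
#'
#' @param design a `ct_design` from [build_design()], or a plain numeric
#'   design matrix with column names (then `response` is required).
#' @param response response vector, when `design` is a matrix.
#' @return An object of class `qpcr_fit` with elements `coefficients`,
#'   `standard_errors`, `t_statistics`, `p_values` (all named by column),
#'   `residual_df`, `sigma`, `r_squared`, `fitted`, `residuals`,
#'   `cov_unscaled`, plus the inputs.
#' @export
fit_ols <- function(design, response = NULL) {
  if (inherits(design, "ct_design")) {
    X <- design$X; y <- design$y
    baselines <- design$baselines; sample_ids <- design$sample_ids
    spec <- design$spec; dropped <- design$dropped
  } else {
    X <- as.matrix(design); y <- response
    if (is.null(y)) stop_user("response vector required with a matrix design")
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    baselines <- list(); sample_ids <- NULL; spec <- NULL; dropped <- character()
  }
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p)
    stop_user("insufficient data: ", n, " observations for ", p,
              " parameters; need n > p (and preferably n >= 2p)")
  qrx <- qr(X)
  if (qrx$rank < p) {
    aliased <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    stop_user("rank-deficient design: column(s) ",
              paste(aliased, collapse = ", "),
              " are collinear with earlier columns")
  }
  coefs <- drop(qr.coef(qrx, y))
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  df <- n - p
  rss <- sum(resid^2)
  sigma <- sqrt(rss / df)
  Rinv <- backsolve(qr.R(qrx), diag(p))
  cov_piv <- Rinv %*% t(Rinv)
  cov_unscaled <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  cov_unscaled[qrx$pivot, qrx$pivot] <- cov_piv
  se <- sigma * sqrt(diag(cov_unscaled))
  tstat <- coefs / se
  pval <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  has_intercept <- any(apply(X, 2, function(c) all(c == c[1] & c[1] != 0)))
  tss <- if (has_intercept) sum((y - mean(y))^2) else sum(y^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  structure(list(coefficients = coefs, standard_errors = se,
                 t_statistics = tstat, p_values = pval,
                 residual_df = df, sigma = sigma, r_squared = r2,
                 fitted = fitted, residuals = resid,
                 cov_unscaled = cov_unscaled,
                 X = X, y = y, baselines = baselines,
                 sample_ids = sample_ids, dropped = dropped, spec = spec),
            class = "qpcr_fit")
}

#' Fit an ANCOVA model to a CT table
#'
#' The main fitting interface: regress a target gene's CT on treatment (and
#' other categorical factors) with reference-gene CT as an estimated
#' covariate, e.g.
#' `qpcr_mlm(MMP10 ~ Donor + Treatment + GAPDH, data = tab)`.
#' Estimates are in CT units; the treatment coefficient is the adjusted CT
#' shift of the treated group relative to the control (baseline) level, so
#' a positive coefficient means less transcript under treatment. Inference
#' (t-statistics, p-values) is invariant to multiplying any gene column by
#' a positive constant, which is how the model absorbs
#' amplification-efficiency differences between genes.
#'
#' @param formula model formula, genes and annotation columns by name, e.g.
#'   `MMP10 ~ Donor + Treatment + GAPDH`.
#' @param data a [ct_table].
#' @param control optional control level of the treatment factor (defaults
#'   to its lexicographically first level).
#' @return An object of class `qpcr_mlm` (inherits `qpcr_fit`), with
#'   methods `print`, `summary`, `coef`, `vcov`, `confint`, `fitted`,
#'   `residuals`, `predict`, `simulate`, and `plot`.
#' @examples
#' tab <- read_ct_table(system.file("extdata", "table2.csv", package = "qpcrmlm"))
#' fit <- qpcr_mlm(MMP10 ~ Donor + Treatment + GAPDH, data = tab)
#' summary(fit)
#' coefficient_test(fit, "TreatmentETI")
#' @export
qpcr_mlm <- function(formula, data, control = NULL) {
  stopifnot(inherits(data, "ct_table"))
  des <- build_design(data, formula, control = control)
  fit <- fit_ols(des)
  fit$call <- match.call()
  fit$formula <- if (is.character(formula)) stats::as.formula(formula) else formula
  class(fit) <- c("qpcr_mlm", class(fit))
  fit
}

#' Extract one coefficient as a test result
#'
#' Packages a fitted coefficient as a single hypothesis-test outcome:
#' estimate, t statistic, residual df and two-sided p-value.
#'
#' @param fit a `qpcr_fit` / `qpcr_mlm`.
#' @param term design-column label, e.g. `"TreatmentETI"` or `"GAPDH"`.
#' @return A `qpcr_test` (printable as an `htest`).
#' @export
coefficient_test <- function(fit, term) {
  stopifnot(inherits(fit, "qpcr_fit"))
  if (!term %in% names(fit$coefficients))
    stop_user("unknown term '", term, "'; available: ",
              paste(names(fit$coefficients), collapse = ", "))
  qpcr_test_result(unname(fit$coefficients[term]),
                   unname(fit$t_statistics[term]),
                   fit$residual_df,
                   unname(fit$p_values[term]),
                   "ANCOVA coefficient t-test",
                   paste0("term ", term),
                   estimate_name = term)
}

#' One-step ANCOVA summary table
#'
#' Fits the ANCOVA model and returns a coefficient summary with one row per
#' non-intercept term (factors first, then covariates), mirroring the
#' layout of a published qPCR ANCOVA table; the intercept is kept as an
#' attribute.
#'
#' @inheritParams qpcr_mlm
#' @param spec a formula, a formula string, or a [model_spec()].
#' @return A data.frame of class `ancova_summary` with columns `term`,
#'   `estimate`, `std_error`, `t`, `p_value`; attributes `intercept`
#'   (one-row data.frame), `fit` (the `qpcr_fit`), `dropped`.
#' @export
analyze_ancova <- function(data, spec, control = NULL) {
  des <- build_design(data, spec, control = control)
  fit <- fit_ols(des)
  keep <- setdiff(names(fit$coefficients), "(Intercept)")
  out <- data.frame(term = keep,
                    estimate = unname(fit$coefficients[keep]),
                    std_error = unname(fit$standard_errors[keep]),
                    t = unname(fit$t_statistics[keep]),
                    p_value = unname(fit$p_values[keep]),
                    stringsAsFactors = FALSE)
  attr(out, "intercept") <- data.frame(
    term = "(Intercept)",
    estimate = unname(fit$coefficients["(Intercept)"]),
    std_error = unname(fit$standard_errors["(Intercept)"]),
    t = unname(fit$t_statistics["(Intercept)"]),
    p_value = unname(fit$p_values["(Intercept)"]))
  attr(out, "fit") <- fit
  attr(out, "dropped") <- fit$dropped
  class(out) <- c("ancova_summary", "data.frame")
  out
}

#' @export
print.ancova_summary <- function(x, digits = 4, ...) {
  cat("ANCOVA coefficient summary (response in CT units)\n")
  df <- as.data.frame(x)
  df$estimate <- signif(df$estimate, digits)
  df$std_error <- signif(df$std_error, digits)
  df$t <- signif(df$t, digits)
  df$p_value <- format.pval(df$p_value, digits = digits)
  print(df, row.names = FALSE, ...)
  invisible(x)
}
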