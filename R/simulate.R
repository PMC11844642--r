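# Monte-Carlo evaluation of MLM vs ddCT vs dCT ------------------------------
#
# Each simulated experiment is a two-gene, two-group design: 5 treated and
# 5 control independent donors by default. Reference and target CT are
# unit-variance margins (Gaussian or standardised-exponential for skew)
# linearly mixed to a chosen Pearson correlation; treatment effects are
# mean shifts in SD units, applied to the target (power scenarios) and/or
# the reference (contaminated-reference scenarios).

.shapes <- c("gaussian", "right_skewed", "left_skewed")

#' Define a simulation scenario
#'
#' One fully parameterised cell of the simulation grid.
#'
#' @param n_per_group samples per treatment group (>= 3; default 5 donors).
#' @param rho target-reference Pearson correlation in `[-1, 1]`.
#' @param shape marginal distribution: `"gaussian"`, `"right_skewed"`, or
#'   `"left_skewed"` (standardised exponential, skewness +/-2).
#' @param target_effect treated-group shift of the target CT, in SD units
#'   (0 under the null).
#' @param reference_effect treated-group shift of the reference CT, in SD
#'   units (nonzero = a reference gene that responds to treatment).
#' @param alpha two-sided test level in (0, 1).
#' @param n_reps Monte-Carlo replicates (default 10000; MC standard error
#'   at a 5% rate is then about 0.22 percentage points).
#' @param seed integer seed; every replicate's random stream is derived
#'   deterministically from it.
#' @return An object of class `qpcr_scenario`.
#' @export
qpcr_scenario <- function(n_per_group = 5, rho = 0, shape = .shapes,
                          target_effect = 0, reference_effect = 0,
                          alpha = 0.05, n_reps = 10000, seed = 1L) {
  shape <- match.arg(shape)
  if (!is.numeric(n_per_group) || n_per_group < 3 || n_per_group != round(n_per_group))
    stop_user("n_per_group must be an integer >= 3")
  if (!is.numeric(rho) || !is.finite(rho) || abs(rho) > 1)
    stop_user("rho must be a number in [-1, 1]")
  if (!all(is.finite(c(target_effect, reference_effect))))
    stop_user("effects must be finite")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_user("alpha must be in (0, 1)")
  if (!is.numeric(n_reps) || n_reps < 1 || n_reps != round(n_reps))
    stop_user("n_reps must be a positive integer")
  structure(list(n_per_group = as.integer(n_per_group), rho = rho,
                 shape = shape, target_effect = target_effect,
                 reference_effect = reference_effect, alpha = alpha,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "qpcr_scenario")
}

#' @export
print.qpcr_scenario <- function(x, ...) {
  cat("qPCR simulation scenario: ", x$n_per_group, " vs ", x$n_per_group,
      " samples, rho = ", x$rho, ", ", x$shape,
      ", target effect ", x$target_effect, " SD, reference effect ",
      x$reference_effect, " SD, alpha ", x$alpha, ", ", x$n_reps,
      " reps, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Zero-mean unit-variance draws with optional skew
#'
#' i.i.d. draws from the current RNG stream: standard Gaussian
#' (`direction = "none"`), standardised exponential `Exp(1) - 1` (skewness
#' +2, `"right"`), or its negation (skewness -2, `"left"`). With the same
#' RNG state, the left draw is exactly minus the right draw.
#'
#' @param n number of draws.
#' @param direction `"none"`, `"right"`, or `"left"`.
#' @return Numeric vector of length `n` with population mean 0, variance 1.
#' @export
skewed_margin <- function(n, direction = c("none", "right", "left")) {
  direction <- match.arg(direction)
  stopifnot(n >= 1)
  switch(direction,
         none = stats::rnorm(n),
         right = stats::rexp(n) - 1,
         left = 1 - stats::rexp(n))
}

.shape_direction <- function(shape) {
  switch(shape, gaussian = "none", right_skewed = "right", left_skewed = "left")
}

#' Generate one synthetic two-gene experiment
#'
#' Draws `2 * n_per_group` independent samples. The reference CT is a unit-
#' variance margin `zR`; the target CT is `rho * zR + sqrt(1 - rho^2) * zE`
#' with `zE` an independent margin of the same shape -- linear mixing makes
#' the Pearson correlation exactly `rho` whatever the margins, though it
#' attenuates the target margin's skewness. Treated samples then receive
#' `target_effect` on the target and `reference_effect` on the reference.
#' Uses the current RNG state; seed control lives in [rejection_rates()].
#'
#' @param scenario a [qpcr_scenario()].
#' @return data.frame with columns `sample_id`, `treatment` (factor,
#'   levels `control`, `treated`), `target`, `reference`.
#' @export
generate_experiment <- function(scenario) {
  stopifnot(inherits(scenario, "qpcr_scenario"))
  n <- scenario$n_per_group
  N <- 2L * n
  dir <- .shape_direction(scenario$shape)
  zR <- skewed_margin(N, dir)
  zE <- skewed_margin(N, dir)
  reference <- zR
  target <- scenario$rho * zR + sqrt(1 - scenario$rho^2) * zE
  treated <- rep(c(FALSE, TRUE), each = n)
  target[treated] <- target[treated] + scenario$target_effect
  reference[treated] <- reference[treated] + scenario$reference_effect
  data.frame(sample_id = sprintf("s%02d", seq_len(N)),
             treatment = factor(ifelse(treated, "treated", "control"),
                                levels = c("control", "treated")),
             target = target, reference = reference,
             stringsAsFactors = FALSE)
}

#' Apply the three analysis methods to one experiment
#'
#' Runs, on a dataset shaped like [generate_experiment()] output:
#' \describe{
#'   \item{MLM}{ANCOVA `target ~ treatment + reference`, treatment-term
#'     two-sided t p-value (identical to the [analyze_ancova()] /
#'     [coefficient_test()] route on the same data);}
#'   \item{ddCT}{pooled two-sample t on `target - reference`;}
#'   \item{dCT}{pooled two-sample t on the raw target CT.}
#' }
#'
#' @param dataset data.frame with `treatment` (two levels, control first),
#'   `target`, `reference`.
#' @param alpha rejection level.
#' @return data.frame with columns `method` (`MLM`, `ddCT`, `dCT`),
#'   `p_value`, `reject`.
#' @export
run_methods <- function(dataset, alpha = 0.05) {
  tr <- as.integer(dataset$treatment == levels(factor(dataset$treatment))[2])
  X <- cbind("(Intercept)" = 1, treatmenttreated = tr,
             reference = dataset$reference)
  p_mlm <- tryCatch({
    fit <- fit_ols(X, dataset$target)
    unname(fit$p_values["treatmenttreated"])
  }, error = function(e) NA_real_)
  d <- dataset$target - dataset$reference
  p_ddct <- .pooled_t(d[tr == 1], d[tr == 0], "ddCT", "d")$p.value
  p_dct <- .pooled_t(dataset$target[tr == 1], dataset$target[tr == 0],
                     "dCT", "t")$p.value
  p <- c(MLM = p_mlm, ddCT = p_ddct, dCT = p_dct)
  data.frame(method = names(p), p_value = unname(p), reject = unname(p) < alpha,
             stringsAsFactors = FALSE)
}

#' Empirical rejection rates for one scenario
#'
#' Runs `n_reps` independent generate/analyse cycles and reports, per
#' method, the fraction of replicates with p below `alpha`, with the
#' binomial Monte-Carlo standard error `sqrt(rate (1 - rate) / n_reps)`.
#' Replicate `i` uses a seed derived deterministically from
#' `(scenario$seed, i)`, so results are reproducible and independent of
#' any parallel execution order.
#'
#' @param scenario a [qpcr_scenario()].
#' @return An object of class `rejection_rates`: list with `rates` and
#'   `mc_se` (named numeric over MLM, ddCT, dCT), `n_reps`, `scenario`.
#' @export
rejection_rates <- function(scenario) {
  stopifnot(inherits(scenario, "qpcr_scenario"))
  if (scenario$n_reps < 100)
    warning("n_reps = ", scenario$n_reps,
            " gives a Monte-Carlo standard error too large to be meaningful",
            call. = FALSE)
  counts <- c(MLM = 0L, ddCT = 0L, dCT = 0L)
  for (i in seq_len(scenario$n_reps)) {
    set.seed(derive_seed(scenario$seed, i))
    res <- run_methods(generate_experiment(scenario), scenario$alpha)
    counts <- counts + ifelse(is.na(res$reject), 0L, as.integer(res$reject))
  }
  rates <- counts / scenario$n_reps
  structure(list(rates = rates,
                 mc_se = sqrt(rates * (1 - rates) / scenario$n_reps),
                 n_reps = scenario$n_reps, scenario = scenario),
            class = "rejection_rates")
}

#' @export
print.rejection_rates <- function(x, ...) {
  cat("Empirical rejection rates (", x$n_reps, " reps, alpha ",
      x$scenario$alpha, "):\n", sep = "")
  out <- data.frame(method = names(x$rates),
                    rate = sprintf("%.1f%%", 100 * x$rates),
                    mc_se = sprintf("%.2f pp", 100 * x$mc_se))
  print(out, row.names = FALSE)
  invisible(x)
}

#' Type-I-error and power grid over correlation and distribution shape
#'
#' For every (shape, rho) combination, runs a null scenario
#' (`target_effect = 0`, giving empirical type I error) and an alternative
#' scenario (`target_effect = target_effect`, giving power), both
#' inheriting `n_per_group`, `reference_effect`, `alpha`, `n_reps` from
#' `base`. Row seeds are derived deterministically from `base$seed`, so
#' the whole table is reproducible bit for bit.
#'
#' @param rhos numeric vector of Pearson correlations.
#' @param shapes character vector of margin shapes.
#' @param base a [qpcr_scenario()] supplying the shared parameters.
#' @param target_effect treated-group target shift (SD units) for the
#'   power block; defaults to `base$target_effect` if nonzero, else 2.
#' @return A data.frame of class `rejection_table` with columns
#'   `correlation`, `distribution`, `typeI_MLM`, `typeI_ddCT`, `typeI_dCT`,
#'   `power_MLM`, `power_ddCT`, `power_dCT` (rates in `[0, 1]`);
#'   attributes `mc_se` (same layout), `n_reps`, `base`.
#' @export
scenario_grid <- function(rhos, shapes, base, target_effect = NULL) {
  stopifnot(inherits(base, "qpcr_scenario"), length(rhos) >= 1, length(shapes) >= 1)
  shapes <- match.arg(shapes, .shapes, several.ok = TRUE)
  if (is.null(target_effect))
    target_effect <- if (base$target_effect != 0) base$target_effect else 2
  rows <- list(); ses <- list(); k <- 0L
  for (shape in shapes) for (rho in rhos) {
    k <- k + 1L
    null_sc <- qpcr_scenario(n_per_group = base$n_per_group, rho = rho,
                             shape = shape, target_effect = 0,
                             reference_effect = base$reference_effect,
                             alpha = base$alpha, n_reps = base$n_reps,
                             seed = derive_seed(base$seed, 2L * k - 1L))
    alt_sc <- qpcr_scenario(n_per_group = base$n_per_group, rho = rho,
                            shape = shape, target_effect = target_effect,
                            reference_effect = base$reference_effect,
                            alpha = base$alpha, n_reps = base$n_reps,
                            seed = derive_seed(base$seed, 2L * k))
    r0 <- rejection_rates(null_sc)
    r1 <- rejection_rates(alt_sc)
    rows[[k]] <- data.frame(correlation = rho, distribution = shape,
                            typeI_MLM = r0$rates[["MLM"]],
                            typeI_ddCT = r0$rates[["ddCT"]],
                            typeI_dCT = r0$rates[["dCT"]],
                            power_MLM = r1$rates[["MLM"]],
                            power_ddCT = r1$rates[["ddCT"]],
                            power_dCT = r1$rates[["dCT"]],
                            stringsAsFactors = FALSE)
    ses[[k]] <- data.frame(correlation = rho, distribution = shape,
                           typeI_MLM = r0$mc_se[["MLM"]],
                           typeI_ddCT = r0$mc_se[["ddCT"]],
                           typeI_dCT = r0$mc_se[["dCT"]],
                           power_MLM = r1$mc_se[["MLM"]],
                           power_ddCT = r1$mc_se[["ddCT"]],
                           power_dCT = r1$mc_se[["dCT"]],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "mc_se") <- do.call(rbind, ses)
  attr(out, "n_reps") <- base$n_reps
  attr(out, "base") <- base
  class(out) <- c("rejection_table", "data.frame")
  out
}

#' @export
print.rejection_table <- function(x, ...) {
  cat("Empirical type I error and power (", attr(x, "n_reps"),
      " reps per cell)\n", sep = "")
  df <- as.data.frame(x)
  for (col in names(df)[-(1:2)]) df[[col]] <- sprintf("%.1f%%", 100 * df[[col]])
  print(df, row.names = FALSE, ...)
  invisible(x)
}

#' Write a rejection table as CSV
#'
#' Column order mirrors the published layout: correlation, distribution,
#' the three type-I-error columns (MLM, ddCT, dCT), then the three power
#' columns.
#'
#' @param x a `rejection_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_rejection_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a scenario (or scenario-grid) configuration file
#'
#' YAML or JSON with the [qpcr_scenario()] fields as keys; the list-valued
#' keys `rhos` and `shapes` turn the file into a grid specification.
#' Unknown keys are an error.
#'
#' @param path configuration file path.
#' @return A list with elements `base` (a `qpcr_scenario`), and `rhos`,
#'   `shapes` (possibly length one).
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop_user("scenario file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("rhos", "shapes", "n_per_group", "rho", "shape", "target_effect",
             "reference_effect", "alpha", "n_reps", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop_user("unknown scenario key(s): ", paste(bad, collapse = ", "))
  rhos <- unlist(cfg$rhos %||% cfg$rho %||% 0)
  shapes <- unlist(cfg$shapes %||% cfg$shape %||% "gaussian")
  base <- qpcr_scenario(n_per_group = cfg$n_per_group %||% 5,
                        rho = rhos[1], shape = shapes[1],
                        target_effect = cfg$target_effect %||% 0,
                        reference_effect = cfg$reference_effect %||% 0,
                        alpha = cfg$alpha %||% 0.05,
                        n_reps = cfg$n_reps %||% 10000,
                        seed = cfg$seed %||% 1L)
  list(base = base, rhos = rhos, shapes = shapes)
}
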