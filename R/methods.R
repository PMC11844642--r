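# S3 methods for fitted ANCOVA models ---------------------------------------

#' @export
print.qpcr_fit <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) {
    cat("Call:\n"); print(x$call); cat("\n")
  }
  cat("Coefficients (CT units):\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' @export
coef.qpcr_fit <- function(object, ...) object$coefficients

#' @export
vcov.qpcr_fit <- function(object, ...) object$sigma^2 * object$cov_unscaled

#' @export
fitted.qpcr_fit <- function(object, ...) {
  f <- object$fitted
  if (!is.null(object$sample_ids)) names(f) <- object$sample_ids
  f
}

#' @export
residuals.qpcr_fit <- function(object, ...) {
  r <- object$residuals
  if (!is.null(object$sample_ids)) names(r) <- object$sample_ids
  r
}

#' @export
confint.qpcr_fit <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  if (missing(parm)) parm <- names(cf)
  a <- (1 - level) / 2
  q <- stats::qt(1 - a, object$residual_df)
  out <- cbind(cf[parm] - q * object$standard_errors[parm],
               cf[parm] + q * object$standard_errors[parm])
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  out
}

#' @export
summary.qpcr_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients,
               `Std. Error` = object$standard_errors,
               `t value` = object$t_statistics,
               `Pr(>|t|)` = object$p_values)
  structure(list(call = object$call, coefficients = tab,
                 sigma = object$sigma, residual_df = object$residual_df,
                 r_squared = object$r_squared,
                 n_dropped = length(object$dropped)),
            class = "summary.qpcr_fit")
}

#' @export
print.summary.qpcr_fit <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) {
    cat("Call:\n"); print(x$call); cat("\n")
  }
  cat("Coefficients:\n")
  stats::printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
                      has.Pvalue = TRUE)
  cat("\nResidual standard error:", signif(x$sigma, digits), "CT on",
      x$residual_df, "degrees of freedom\n")
  cat("Multiple R-squared:", signif(x$r_squared, digits), "\n")
  if (x$n_dropped > 0)
    cat("(", x$n_dropped, " sample(s) dropped for missing cells)\n", sep = "")
  invisible(x)
}

#' Predict CT values from a fitted ANCOVA model
#'
#' Rebuilds the design for `newdata` using the baseline levels stored in
#' the fit; a factor level unseen at fit time is an error.
#'
#' @param object a `qpcr_mlm`.
#' @param newdata a [ct_table] or data.frame with the model's factor and
#'   covariate columns; omitted for in-sample fitted values.
#' @param ... unused.
#' @return Numeric vector of predicted response CT values.
#' @export
predict.qpcr_mlm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  spec <- object$spec
  n <- nrow(newdata)
  cols <- list("(Intercept)" = rep(1, n))
  for (f in spec$factors) {
    v <- as.character(newdata[[f]])
    known <- c(object$baselines[[f]],
               sub(paste0("^", f), "",
                   grep(paste0("^", f), names(object$coefficients), value = TRUE)))
    bad <- setdiff(unique(v), known)
    if (length(bad))
      stop_user("factor '", f, "' has level(s) unseen at fit time: ",
                paste(bad, collapse = ", "))
    for (l in setdiff(known, object$baselines[[f]]))
      cols[[paste0(f, l)]] <- as.numeric(v == l)
  }
  for (g in spec$covariates) cols[[g]] <- newdata[[g]]
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X <- X[, names(object$coefficients), drop = FALSE]
  drop(X %*% object$coefficients)
}

#' Simulate responses from a fitted ANCOVA model
#'
#' Draws `nsim` response vectors as fitted values plus i.i.d. Gaussian
#' noise with the fitted residual standard deviation.
#'
#' @param object a `qpcr_mlm`.
#' @param nsim number of simulated response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A data.frame with `nsim` columns, one simulated response per
#'   column, as for [stats::simulate()].
#' @export
simulate.qpcr_mlm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$fitted)
  out <- as.data.frame(replicate(nsim, object$fitted +
                                   stats::rnorm(n, 0, object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  if (!is.null(object$sample_ids)) rownames(out) <- object$sample_ids
  out
}

#' Diagnostic plots for a fitted ANCOVA model
#'
#' Residuals versus fitted values and a normal Q-Q plot of residuals --
#' the two checks that matter at qPCR sample sizes.
#'
#' @param x a `qpcr_mlm`.
#' @param ... passed to the underlying plot calls.
#' @return `x`, invisibly.
#' @export
plot.qpcr_mlm <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$fitted, x$residuals, xlab = "Fitted CT",
                 ylab = "Residual (CT)", main = "Residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  stats::qqnorm(x$residuals, main = "Normal Q-Q")
  stats::qqline(x$residuals)
  invisible(x)
}
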