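# Fixtures and independent oracles used across the suite --------------------

table2_path <- function() {
  system.file("extdata", "table2.csv", package = "qpcrmlm")
}

table2 <- function() read_ct_table(table2_path())

# minimal 4-sample two-gene table builder
tiny_table <- function(tgt = c(5, 6, 7, 8), ref = c(1, 1, 2, 2),
                       treatment = c("ctrl", "ctrl", "trt", "trt")) {
  ct_table(data.frame(sample = paste0("s", seq_along(tgt)),
                      subject = paste0("d", seq_along(tgt)),
                      treatment = treatment, TGT = tgt, REF = ref,
                      stringsAsFactors = FALSE),
           sample = "sample", subject = "subject", treatment = "treatment",
           genes = c("TGT", "REF"))
}

# brute-force least squares via SVD pseudo-inverse (independent of qr path)
pinv_coef <- function(X, y) {
  s <- svd(X)
  drop(s$v %*% ((t(s$u) %*% y) / s$d))
}

# textbook pooled two-sample t
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(estimate = mean(x) - mean(y), statistic = tt, df = n1 + n2 - 2,
       p = 2 * pt(abs(tt), n1 + n2 - 2, lower.tail = FALSE))
}

# textbook one-sample (paired-difference) t
paired_t_oracle <- function(d) {
  tt <- mean(d) / (sd(d) / sqrt(length(d)))
  list(estimate = mean(d), statistic = tt, df = length(d) - 1,
       p = 2 * pt(abs(tt), length(d) - 1, lower.tail = FALSE))
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

random_design <- function(n, p) {
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  X
}
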