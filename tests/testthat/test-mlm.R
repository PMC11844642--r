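# ANCOVA design construction, OLS inference, and model methods

test_that("the worked-example design is 10 x 7 with lexicographic baselines", {
  des <- build_design(table2(), MMP10 ~ Donor + Treatment + GAPDH)
  expect_equal(dim(des$X), c(10, 7))
  expect_identical(colnames(des$X),
                   c("(Intercept)", "DonorKK22F", "DonorKK27H", "DonorKK29H",
                     "DonorKK32G", "TreatmentETI", "GAPDH"))
  expect_identical(des$baselines, list(Donor = "KK18G", Treatment = "DMSO"))
  expect_equal(unname(des$X[, "(Intercept)"]), rep(1, 10))
  expect_equal(des$y, table2()$MMP10)
})

test_that("minimal and degenerate designs are handled explicitly", {
  tab4 <- tiny_table()
  expect_equal(dim(build_design(tab4, TGT ~ treatment)$X), c(4, 2))
  # a covariate listed twice is exactly collinear -> hard rank error
  expect_error(build_design(tab4, model_spec("TGT", "treatment", c("REF", "REF"))),
               "rank-deficient.*REF")
  # single observed factor level cannot be estimated
  one_lvl <- tiny_table(treatment = rep("ctrl", 4))
  expect_error(build_design(one_lvl, TGT ~ treatment), "single observed level")
  # more parameters than observations
  expect_error(fit_ols(random_design(3, 3), rnorm(3)), "insufficient data")
  # samples with missing required cells are dropped with a message
  tab <- table2(); tab$GAPDH[1] <- NA
  expect_message(des <- build_design(tab, MMP10 ~ Treatment + GAPDH),
                 "dropping 1 sample")
  expect_equal(nrow(des$X), 9)
})

test_that("the worked example reproduces the published ANCOVA fit", {
  fit <- qpcr_mlm(MMP10 ~ Donor + Treatment + GAPDH, data = table2(),
                  control = "DMSO")
  # values frozen from the exact least-squares solution on the printed CTs
  expect_equal(unname(coef(fit)["TreatmentETI"]), 0.944, tolerance = 1e-3)
  expect_equal(unname(fit$p_values["TreatmentETI"]), 0.01377, tolerance = 1e-3)
  expect_equal(unname(coef(fit)["GAPDH"]), 0.34247, tolerance = 1e-4)
  expect_equal(unname(fit$p_values["GAPDH"]), 0.60788, tolerance = 1e-4)
  expect_equal(unname(coef(fit)["DonorKK22F"]), 0.85592, tolerance = 1e-4)
  expect_equal(fit$residual_df, 3)
  # cross-check the whole coefficient vector against stats::lm
  lmfit <- lm(MMP10 ~ Donor + Treatment + GAPDH, data = as.data.frame(table2()))
  expect_equal(coef(fit), coef(lmfit), tolerance = 1e-10)
  expect_equal(unname(fit$p_values),
               unname(coef(summary(lmfit))[, 4]), tolerance = 1e-10)
})

test_that("an exactly linear response is fitted without residual", {
  tab <- table2()
  tab$MMP10 <- tab$GAPDH
  fit <- fit_ols(build_design(tab, MMP10 ~ Treatment + GAPDH))
  expect_equal(unname(fit$coefficients["GAPDH"]), 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[c("(Intercept)", "TreatmentETI")]),
               c(0, 0), tolerance = 1e-10)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
})

test_that("OLS agrees with a pseudo-inverse oracle on random small designs", {
  set.seed(402)
  for (i in 1:40) {
    n <- sample(6:12, 1)
    p <- sample(2:min(6, n - 1), 1)
    X <- random_design(n, p)
    y <- rnorm(n)
    fit <- fit_ols(X, y)
    expect_equal(unname(fit$coefficients), pinv_coef(X, y), tolerance = 1e-8)
    # residuals orthogonal to every design column
    expect_lt(max(abs(crossprod(X, fit$residuals))), 1e-8 * max(abs(X)) * n)
    # fitted + residuals reconstruct the response
    expect_equal(fit$fitted + fit$residuals, y, tolerance = 1e-12)
  }
})

test_that("coefficient inference is invariant to positive rescaling of any gene", {
  tab0 <- table2()
  base <- attr(analyze_ancova(tab0, MMP10 ~ Donor + Treatment + GAPDH), "fit")
  keep <- setdiff(names(base$coefficients), "GAPDH")
  for (c_scale in c(0.5, log2(1.9), 3)) {
    tab <- tab0
    tab$GAPDH <- tab$GAPDH * c_scale
    f1 <- attr(analyze_ancova(tab, MMP10 ~ Donor + Treatment + GAPDH), "fit")
    # reference coefficient rescales exactly; everything else untouched
    expect_equal(unname(f1$coefficients["GAPDH"]),
                 unname(base$coefficients["GAPDH"]) / c_scale,
                 tolerance = 1e-10)
    expect_equal(f1$t_statistics[keep], base$t_statistics[keep],
                 tolerance = 1e-10)
    expect_equal(f1$p_values[keep], base$p_values[keep], tolerance = 1e-12)
    # rescaling every CT column (response included) preserves all t and p
    tab2 <- tab0
    tab2$GAPDH <- tab2$GAPDH * c_scale
    tab2$MMP10 <- tab2$MMP10 * c_scale
    f2 <- attr(analyze_ancova(tab2, MMP10 ~ Donor + Treatment + GAPDH), "fit")
    expect_equal(f2$t_statistics, base$t_statistics, tolerance = 1e-10)
    expect_equal(f2$p_values, base$p_values, tolerance = 1e-12)
  }
})

test_that("treatment-only ANCOVA collapses to the pooled two-sample t", {
  tab <- table2()
  smry <- analyze_ancova(tab, MMP10 ~ Treatment)
  tt <- dct_test(tab, "MMP10", "DMSO")
  expect_equal(smry$p_value[smry$term == "TreatmentETI"], tt$p.value,
               tolerance = 1e-12)
  expect_equal(smry$estimate[smry$term == "TreatmentETI"],
               unname(tt$estimate), tolerance = 1e-12)
  # duplicating the control rows as fake treated rows gives a zero effect
  dup <- as.data.frame(tab[tab$Treatment == "DMSO", ])
  dup$Treatment <- "ETI"; dup$Group <- paste0(dup$Group, "*")
  both <- ct_table(rbind(as.data.frame(tab[tab$Treatment == "DMSO", ]), dup),
                   "Group", "Donor", "Treatment", c("GAPDH", "MMP10"))
  s2 <- analyze_ancova(both, MMP10 ~ Treatment + GAPDH)
  expect_equal(s2$estimate[s2$term == "TreatmentETI"], 0, tolerance = 1e-12)
})

test_that("analyze_ancova mirrors the published table layout", {
  smry <- analyze_ancova(table2(), MMP10 ~ Donor + Treatment + GAPDH)
  expect_identical(smry$term,
                   c("DonorKK22F", "DonorKK27H", "DonorKK29H", "DonorKK32G",
                     "TreatmentETI", "GAPDH"))
  expect_false("(Intercept)" %in% smry$term)
  expect_equal(attr(smry, "intercept")$term, "(Intercept)")
  res <- coefficient_test(attr(smry, "fit"), "TreatmentETI")
  expect_equal(unname(res$estimate),
               smry$estimate[smry$term == "TreatmentETI"])
  expect_equal(res$p.value, smry$p_value[smry$term == "TreatmentETI"])
  expect_error(coefficient_test(attr(smry, "fit"), "Donor KK22F"),
               "unknown term.*DonorKK22F")
})

test_that("model methods behave like a classic fitted-model object", {
  tab <- table2()
  fit <- qpcr_mlm(MMP10 ~ Donor + Treatment + GAPDH, data = tab)
  expect_output(print(fit), "Coefficients")
  expect_output(print(summary(fit)), "Residual standard error")
  expect_equal(unname(predict(fit)), unname(fitted(fit)))
  expect_equal(predict(fit, newdata = as.data.frame(tab)), unname(fitted(fit)),
               tolerance = 1e-12)
  nd <- as.data.frame(tab)[1, ]; nd$Donor <- "NEW"
  expect_error(predict(fit, newdata = nd), "unseen at fit time")
  expect_equal(residuals(fit) + fitted(fit),
               structure(tab$MMP10, names = tab$Group))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(10, 3))
  expect_equal(dim(vcov(fit)), c(7, 7))
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
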