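# Synthetic two-gene experiments and the Monte-Carlo pipeline

test_that("scenario validation enforces the parameter domains", {
  expect_s3_class(qpcr_scenario(), "qpcr_scenario")
  expect_error(qpcr_scenario(n_per_group = 2), "integer >= 3")
  expect_error(qpcr_scenario(rho = 1.2), "\\[-1, 1\\]")
  expect_error(qpcr_scenario(alpha = 0), "\\(0, 1\\)")
  expect_error(qpcr_scenario(shape = "bimodal"), "arg")
  expect_error(qpcr_scenario(target_effect = Inf), "finite")
})

test_that("margins have mean 0, variance 1 and the requested skew", {
  set.seed(403)
  g <- skewed_margin(1e5, "none")
  expect_lt(abs(mean(g)), 0.01)
  expect_lt(abs(var(g) - 1), 0.02)
  r <- skewed_margin(1e5, "right")
  expect_lt(abs(mean(r)), 0.01)
  expect_lt(abs(var(r) - 1), 0.03)
  expect_gt(sample_skewness(r), 1.8)
  expect_lt(sample_skewness(r), 2.2)
  # reflection symmetry: left is exactly minus right under the same stream
  set.seed(404); a <- skewed_margin(100, "right")
  set.seed(404); b <- skewed_margin(100, "left")
  expect_equal(b, -a)
})

test_that("generated experiments realize the nominal Pearson correlation", {
  big <- function(rho, shape) {
    sc <- qpcr_scenario(n_per_group = 50000, rho = rho, shape = shape)
    d <- generate_experiment(sc)
    cor(d$target, d$reference)
  }
  set.seed(405)
  expect_lt(abs(big(0.9, "gaussian") - 0.9), 0.01)
  expect_lt(abs(big(0, "gaussian")), 0.01)
  expect_lt(abs(big(0.5, "right_skewed") - 0.5), 0.01)
  expect_lt(abs(big(-0.7, "left_skewed") + 0.7), 0.01)
})

test_that("null generation leaves group means equal and effects shift them", {
  set.seed(406)
  sc0 <- qpcr_scenario(n_per_group = 5000)
  d0 <- generate_experiment(sc0)
  tr <- d0$treatment == "treated"
  expect_lt(abs(mean(d0$target[tr]) - mean(d0$target[!tr])),
            4 * sqrt(2 / 5000))
  sc1 <- qpcr_scenario(n_per_group = 5000, target_effect = 1.5,
                       reference_effect = 0.5)
  d1 <- generate_experiment(sc1)
  tr <- d1$treatment == "treated"
  expect_equal(mean(d1$target[tr]) - mean(d1$target[!tr]), 1.5,
               tolerance = 0.1)
  expect_equal(mean(d1$reference[tr]) - mean(d1$reference[!tr]), 0.5,
               tolerance = 0.1)
})

test_that("run_methods applies MLM, ddCT and dCT consistently", {
  set.seed(407)
  sc <- qpcr_scenario()
  d <- generate_experiment(sc)
  # shift onto a realistic CT scale; all three tests are location-invariant
  d$target <- d$target + 25
  d$reference <- d$reference + 20
  res <- run_methods(d, alpha = 0.05)
  expect_identical(res$method, c("MLM", "ddCT", "dCT"))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))

  # MLM p equals the analyze_ancova / coefficient_test route exactly
  tab <- ct_table(data.frame(sample = d$sample_id, subject = d$sample_id,
                             treatment = as.character(d$treatment),
                             target = d$target, reference = d$reference,
                             stringsAsFactors = FALSE),
                  "sample", "subject", "treatment", c("target", "reference"))
  smry <- analyze_ancova(tab, target ~ treatment + reference)
  expect_equal(res$p_value[res$method == "MLM"],
               smry$p_value[smry$term == "treatmenttreated"])

  # target identical to reference: ddCT sees no signal at all
  d2 <- d; d2$target <- d2$reference
  res2 <- run_methods(d2, 0.05)
  expect_equal(res2$p_value[res2$method == "ddCT"], 1)

  # an extreme shift is found by all three methods
  sc_big <- qpcr_scenario(target_effect = 10)
  d3 <- generate_experiment(sc_big)
  expect_true(all(run_methods(d3, 0.05)$reject))

  # alpha = 1 rejects everything
  expect_true(all(run_methods(d, 1)$reject))
})

test_that("the Monte-Carlo pipeline is deterministic given the seed", {
  sc <- qpcr_scenario(n_reps = 150, seed = 99)
  r1 <- rejection_rates(sc)
  r2 <- rejection_rates(sc)
  expect_identical(r1$rates, r2$rates)
  expect_equal(r1$mc_se, sqrt(r1$rates * (1 - r1$rates) / 150))
  r3 <- rejection_rates(qpcr_scenario(n_reps = 150, seed = 100))
  expect_false(identical(r1$rates, r3$rates))
  expect_warning(rejection_rates(qpcr_scenario(n_reps = 50)), "standard error")
})

test_that("scenario grids have the published layout and are reproducible", {
  base <- qpcr_scenario(n_reps = 120, seed = 7)
  tab <- scenario_grid(c(0, 0.5, 0.9),
                       c("gaussian", "right_skewed", "left_skewed"), base)
  expect_equal(nrow(tab), 9)
  expect_identical(names(tab)[1:2], c("correlation", "distribution"))
  expect_identical(names(tab)[3:8],
                   c("typeI_MLM", "typeI_ddCT", "typeI_dCT",
                     "power_MLM", "power_ddCT", "power_dCT"))
  tab2 <- scenario_grid(c(0, 0.5, 0.9),
                        c("gaussian", "right_skewed", "left_skewed"), base)
  expect_identical(as.data.frame(tab), as.data.frame(tab2))
  one <- scenario_grid(0.5, "gaussian", base)
  expect_equal(nrow(one), 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_rejection_table(tab, f)
  expect_equal(nrow(read.csv(f)), 9)
})

test_that("scenario files round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("rhos: [0.0, 0.9]", "shapes: [gaussian]", "n_reps: 150",
               "reference_effect: 1.0", "seed: 3"), f)
  sc <- read_scenario(f)
  expect_equal(sc$rhos, c(0, 0.9))
  expect_equal(sc$base$reference_effect, 1)
  expect_equal(sc$base$n_reps, 150)
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("replicates: 10", bad)
  expect_error(read_scenario(bad), "unknown scenario key.*replicates")
})
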