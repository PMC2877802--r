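test_that("simple regression recovers exact lines and is order-invariant", {
  x <- c(0, 1, 2, 3, 4)
  fit <- regress_auc_on_na(3 * x + 1, x)
  expect_equal(fit$slope, 3)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)
  set.seed(20)
  y <- 3 * x + rnorm(5)
  a <- regress_auc_on_na(y, x)
  perm <- sample(5)
  b <- regress_auc_on_na(y[perm], x[perm])
  expect_equal(a$slope, b$slope)
  expect_equal(a$intercept, b$intercept)
  expect_error(regress_auc_on_na(1:5, rep(2, 5)), "constant predictor")
})

test_that("a noiseless simulated study puts the slope at the kernel integral", {
  cfg <- sim_config(n_subjects = 10, noise_sd = 0, drift_slope = 0,
                    seed = 21)
  st <- simulate_study(cfg)
  aucs <- auc_batch(lapply(st$epochs, `[[`, "record"))
  fit <- regress_auc_on_na(aucs$auc, st$manifest$sum_amplitude_true)
  c0 <- rf_integral(cfg$kernel)
  expect_equal(fit$slope, c0, tolerance = 0.02)
  expect_lt(abs(fit$intercept), 0.05 * mean(aucs$auc))
})

test_that("scale_conventional rescales elementwise and preserves ANOVA", {
  expect_equal(scale_conventional(0, 2), 0)
  expect_equal(scale_conventional(c(1, 3), 2), c(2, 6))
  expect_error(scale_conventional(1, -1), "> 0")
  # treatment F within the conventional method is invariant to c
  set.seed(22)
  na <- matrix(rexp(20), 10, 2)   # subjects x treatment
  per_method <- function(cc) {
    d <- cc * (na[, 2] - na[, 1])
    10 * mean(d)^2 / var(d)
  }
  expect_equal(per_method(1), per_method(3.61), tolerance = 1e-12)
})

test_that("2x2 repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(23)
  for (rep_i in 1:20) {
    ns <- sample(3:12, 1)
    arr <- array(rnorm(ns * 4, mean = rep(rnorm(ns, sd = 2), 4)),
                 dim = c(ns, 2, 2))
    tab <- rm_anova_2x2(arr)
    oracle <- anova_ss_oracle(arr)
    expect_equal(tab$F, unname(oracle[c("treatment", "method",
                                        "interaction")]),
                 tolerance = 1e-10)
    expect_equal(tab$df2, rep(ns - 1L, 3))
  }
})

test_that("ANOVA agrees with aov error strata and ignores subject offsets", {
  set.seed(24)
  ns <- 8
  arr <- array(rnorm(ns * 4), dim = c(ns, 2, 2))
  tab <- rm_anova_2x2(arr)
  df <- expand.grid(subject = factor(1:ns), treatment = factor(1:2),
                    method = factor(1:2))
  df$value <- as.vector(arr)
  fit <- stats::aov(value ~ treatment * method +
                      Error(subject / (treatment * method)), data = df)
  s <- summary(fit)
  f_aov <- c(s[["Error: subject:treatment"]][[1]]["treatment", "F value"],
             s[["Error: subject:method"]][[1]]["method", "F value"],
             s[["Error: subject:treatment:method"]][[1]][
               "treatment:method", "F value"])
  expect_equal(tab$F, unname(f_aov), tolerance = 1e-8)
  # per-subject constants change nothing
  arr2 <- arr + rnorm(ns, sd = 5)   # recycled over the 4 cells
  expect_equal(rm_anova_2x2(arr2)$F, tab$F, tolerance = 1e-8)
  # identical methods kill method and interaction effects
  arr3 <- arr
  arr3[, , 2] <- arr3[, , 1]
  tab3 <- rm_anova_2x2(arr3)
  expect_equal(tab3$F[tab3$effect == "method"], 0, tolerance = 1e-20)
  expect_equal(tab3$F[tab3$effect == "interaction"], 0,
               tolerance = 1e-20)
})

test_that("ANOVA accepts long data frames and rejects incomplete designs", {
  set.seed(25)
  arr <- array(rnorm(12), dim = c(3, 2, 2),
               dimnames = list(c("a", "b", "c"),
                               c("anticipation", "baseline"),
                               c("auc", "conv")))
  long <- expand.grid(subject = c("a", "b", "c"),
                      treatment = c("anticipation", "baseline"),
                      method = c("auc", "conv"),
                      stringsAsFactors = FALSE)
  long$value <- as.vector(arr)
  expect_equal(rm_anova_2x2(long)$F, rm_anova_2x2(arr)$F)
  expect_error(rm_anova_2x2(long[-1, ]), "missing cells")
})

test_that("point-biserial correlation is the Pearson correlation on 0/1", {
  labels <- c(0, 0, 1, 1, 0, 1)
  expect_equal(pointbiserial(labels, labels), 1)
  set.seed(26)
  x <- rnorm(6)
  expect_equal(pointbiserial(x, labels), cor(x, labels))
  expect_equal(pointbiserial(x, c("b", "b", "a", "a", "b", "a")),
               cor(x, 1 - labels))
  expect_error(pointbiserial(x, rep(1, 6)), "both classes")
  # independence null: |r| small at large n
  set.seed(27)
  xo <- rnorm(10000); lo <- rbinom(10000, 1, 0.5)
  expect_lt(abs(pointbiserial(xo, lo)), 0.05)
})

test_that("explained-variance F test follows its closed form", {
  eq <- compare_explained_variance(0.4, 0.4, 100)
  expect_equal(eq$F, 0)
  expect_equal(eq$p, 1)
  expect_identical(compare_explained_variance(1, 0.3, 100)$flag,
                   "degenerate")
  got <- compare_explained_variance(0.38, 0.30, 159)
  expect_equal(got$F, (0.38^2 - 0.30^2) / ((1 - 0.38^2) / 159))
  expect_equal(got$p, pf(got$F, 1, 159, lower.tail = FALSE))
  neg <- compare_explained_variance(0.1, 0.5, 50)
  expect_identical(neg$flag, "negative")
  expect_lt(neg$F, 0)
  # invariant to common affine rescaling of both predictors: r is, so F is
  set.seed(28)
  x <- rnorm(40); y <- rnorm(40); l <- rbinom(40, 1, 0.5)
  r1 <- pointbiserial(x, l); r2 <- pointbiserial(y, l)
  r1b <- pointbiserial(3 * x + 7, l); r2b <- pointbiserial(3 * y + 7, l)
  expect_equal(compare_explained_variance(r1, r2, 39)$F,
               compare_explained_variance(r1b, r2b, 39)$F,
               tolerance = 1e-12)
})

test_that("run_validation produces a coherent report on an easy study", {
  cfg <- sim_config(n_subjects = 6, noise_sd = 0.002, drift_slope = 0,
                    seed = 30)
  st <- simulate_study(cfg)
  rep <- run_validation(st)
  expect_s3_class(rep, "validation_report")
  expect_gte(rep$r2_auc_vs_na, 0.9)
  expect_true(all(abs(c(rep$r_classification_auc,
                        rep$r_classification_conventional)) <= 1))
  expect_equal(nrow(rep$epochs), 24)
  expect_equal(rep$anova$df2, rep(5L, 3))
  # treatment effect present by construction
  expect_lt(rep$anova$p[rep$anova$effect == "treatment"], 0.05)
  # report round-trips through JSON
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$slope, rep$slope)
  expect_equal(back$delta_r2_F$F, rep$delta_r2_F$F)
  expect_equal(back$anova$F, rep$anova$F)
})

test_that("run_validation requires both conditions and flags stages", {
  cfg <- sim_config(n_subjects = 2, seed = 31,
                    epoch_labels = c("BL1", "BL2"),
                    epoch_conditions = c("baseline", "baseline"))
  st <- simulate_study(cfg)
  expect_error(run_validation(st), "both baseline and anticipation")
})
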