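test_that("the signed-rank test reproduces closed-form and reference p-values", {
  ## five positive differences with distinct magnitudes: exact p = 2/32
  t5 <- wilcoxon_signed_rank(c(1.2, 0.8, 2.1, 1.4, 0.6))
  expect_equal(t5$p_value, 0.0625)
  expect_equal(t5$statistic, 15)
  ## identical samples: degenerate with p = 1
  td <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(td$degenerate)
  expect_equal(td$p_value, 1)
  expect_false(td$significant)
  ## tie-free random cases agree with stats::wilcox.test exact p-values
  set.seed(10)
  for (i in 1:50) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- wilcoxon_signed_rank(x, y)
    ref <- wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value)
    expect_equal(unname(mine$statistic), unname(ref$statistic))
  }
  expect_error(wilcoxon_signed_rank(1:3, 1:4), "equal length")
})

test_that("exact p-values with ties and zeros match full enumeration", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(2:11, 1)
    d <- round(rnorm(n), sample(0:1, 1))   # coarse rounding forces ties/zeros
    if (all(d == 0)) next
    expect_equal(wilcoxon_signed_rank(d)$p_value, brute_signed_rank_p(d))
  }
})

test_that("the large-sample path approximates the exact tail", {
  set.seed(12)
  d <- rnorm(40, 0.3)
  mine <- wilcoxon_signed_rank(d)
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("type-I error of the exact test stays near its nominal level", {
  set.seed(13)
  rej <- mean(vapply(1:2000, function(i) {
    wilcoxon_signed_rank(rnorm(9))$p_value < 0.05
  }, logical(1)))
  ## exact-test conservatism: attainable level at n = 9 is 0.039
  expect_gte(rej, 0.01)
  expect_lte(rej, 0.09)
})

test_that("the cold sBAT-FF effect size yields mostly significant cohorts", {
  set.seed(14)
  ps <- vapply(1:199, function(i) {
    wilcoxon_signed_rank(rnorm(9, -1.94, 1.83))$p_value
  }, numeric(1))
  expect_lt(median(ps), 0.05)
})

test_that("protocol summaries aggregate states, transitions and contrasts", {
  spec <- cohort_spec(seed = 3)
  m <- simulate_measurements(spec)
  s <- summarize_protocol(m)
  expect_equal(nrow(s$state_summary), 2 * 2 * 3)
  expect_equal(nrow(s$changes), 2 * 2 * 3)
  expect_equal(sort(unique(s$changes$transition)),
               sort(c("Cold-Baseline", "Reheated-Baseline", "Reheated-Cold")))
  expect_equal(nrow(s$baseline_contrast), 2)
  ## procedure mode has exactly two states and one transition
  sq <- summarize_protocol(simulate_measurements(
    cohort_spec(mode = "procedure_study", seed = 3)))
  expect_equal(unique(as.character(sq$state_summary$state)), c("Scan1", "Scan2"))
  expect_equal(unique(sq$changes$transition), "Scan2-Scan1")
  ## two identical states give change 0 and p = 1
  m2 <- m[m$state %in% c("Baseline", "Cold"), ]
  m2$mean_ff_pct[m2$state == "Cold"] <- m2$mean_ff_pct[m2$state == "Baseline"]
  m2$mean_r2s[m2$state == "Cold"] <- m2$mean_r2s[m2$state == "Baseline"]
  m2$state <- factor(as.character(m2$state), levels = c("Baseline", "Cold"))
  s2 <- summarize_protocol(m2)
  expect_true(all(s2$changes$mean_change == 0))
  expect_true(all(s2$changes$p_value == 1))
  ## a subject missing one state is excluded pairwise with a warning
  m3 <- m[!(m$subject == 1 & m$state == "Cold"), ]
  w <- capture_warnings(s3 <- summarize_protocol(m3))
  expect_true(any(grepl("excluded pairwise", w)))
  expect_equal(unique(s3$changes$n[s3$changes$transition == "Cold-Baseline"]), 8)
})

ptest <- function(p, mean = -1, voi = "sbat", quantity = "ff") {
  coolbat:::new_paired_test(mean_change = mean, sd_change = 1, statistic = 5,
                            p = p, alpha = 0.05, degenerate = FALSE, n = 9,
                            n_eff = 9, voi = voi, quantity = quantity)
}

test_that("the attribution rule maps significance patterns to mechanisms", {
  sig <- 0.01; ns <- 0.5
  expect_equal(attribute_mechanism(ptest(sig), ptest(sig), ptest(ns))$mechanism,
               "lipid")
  expect_equal(attribute_mechanism(ptest(sig), ptest(ns), ptest(sig))$mechanism,
               "perfusion")
  expect_equal(attribute_mechanism(ptest(sig), ptest(sig), ptest(sig))$mechanism,
               "mixed")
  expect_equal(attribute_mechanism(ptest(ns), ptest(sig), ptest(sig))$mechanism,
               "none")
  expect_equal(attribute_mechanism(ptest(sig), ptest(ns), ptest(ns))$mechanism,
               "indeterminate")
  ## direction is read from the cold change
  expect_equal(attribute_mechanism(ptest(sig, mean = 2), ptest(sig),
                                   ptest(ns))$direction, "increase")
  ## tests from different VOIs are rejected
  expect_error(attribute_mechanism(ptest(sig), ptest(sig, voi = "sat"),
                                   ptest(ns)), "different")
})

test_that("attribution depends only on the significance flags", {
  set.seed(15)
  base <- attribute_mechanism(ptest(0.01), ptest(0.02), ptest(0.6))$mechanism
  for (i in 1:20) {
    ## jitter p-values without crossing alpha, and scramble irrelevant fields
    a <- ptest(runif(1, 0.001, 0.049), mean = rnorm(1, -2))
    b <- ptest(runif(1, 0.001, 0.049), mean = rnorm(1))
    c <- ptest(runif(1, 0.051, 0.99), mean = rnorm(1))
    a$sd_change <- runif(1, 0.1, 5); a$statistic <- sample(0:45, 1)
    expect_equal(attribute_mechanism(a, b, c)$mechanism, base)
  }
})

test_that("a reversible perfusion-type effect is attributed to perfusion", {
  mech <- vapply(1:100, function(i) {
    spec <- cohort_spec(seed = i, sbat_lipid_ff_change = c(0, 0),
                        sbat_perfusion_ff_change = c(-3, 1))
    s <- summarize_protocol(simulate_measurements(spec))
    attribute_mechanism(s$tests[["sbat.ff.Cold-Baseline"]],
                        s$tests[["sbat.ff.Reheated-Baseline"]],
                        s$tests[["sbat.ff.Reheated-Cold"]])$mechanism
  }, character(1))
  expect_gte(mean(mech == "perfusion"), 0.9)
  ## and a null cohort is attributed to nothing
  mech0 <- vapply(1:50, function(i) {
    spec <- cohort_spec(seed = 1000 + i, sbat_lipid_ff_change = c(0, 0))
    s <- summarize_protocol(simulate_measurements(spec))
    attribute_mechanism(s$tests[["sbat.ff.Cold-Baseline"]],
                        s$tests[["sbat.ff.Reheated-Baseline"]],
                        s$tests[["sbat.ff.Reheated-Cold"]])$mechanism
  }, character(1))
  expect_gte(mean(mech0 == "none"), 0.9)
})
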