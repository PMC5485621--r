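test_that("the paired t statistic matches its closed form", {
  r <- paired_t_test(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  z <- paired_t_test(c(0, 0, 0))
  expect_true(z$degenerate)
  expect_true(is.na(z$t))
  expect_equal(z$mean, 0)
  # two-sided symmetry: mirrored differences give the identical p
  set.seed(4)
  x <- rnorm(9)
  expect_equal(paired_t_test(x)$p, paired_t_test(-x)$p, tolerance = 1e-12)
})

test_that("the 95% CI uses t quantiles", {
  ci <- mean_ci95(c(0, 0, 0, 4))
  expect_equal(ci$mean, 1)
  expect_equal(ci$half_width, qt(0.975, 3) * 1, tolerance = 1e-12)  # SE = 1
  expect_equal(mean_ci95(rep(2, 5))$half_width, 0)
})

test_that("the rank-sum U statistic and exact p match enumeration", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$U, 0)
  expect_equal(wilcoxon_rank_sum(c(1, 4), c(2, 3))$p, 1)
  far <- wilcoxon_rank_sum(c(10, 11, 12), c(1, 2, 3))
  expect_equal(far$U, 9)
  expect_equal(far$p, 2 / choose(6, 3), tolerance = 1e-12)

  # full permutation enumeration oracle for small untied samples
  perm_p <- function(a, b) {
    pooled <- c(a, b)
    n <- length(a)
    U <- function(aa, bb) sum(outer(aa, bb, ">"))
    obs <- U(a, b)
    combs <- utils::combn(length(pooled), n)
    us <- apply(combs, 2, function(ix) U(pooled[ix], pooled[-ix]))
    centre <- length(a) * length(b) / 2
    mean(abs(us - centre) >= abs(obs - centre) - 1e-12)
  }
  set.seed(6)
  for (i in 1:5) {
    a <- round(rnorm(4), 4); b <- round(rnorm(5) + 0.5, 4)
    got <- wilcoxon_rank_sum(a, b)$p
    expect_equal(got, perm_p(a, b), tolerance = 1e-10)
  }
})

test_that("group difference tables carry means, CIs and degeneracy flags", {
  metrics <- rbind(
    paired_metric_table(1, "small", "apex",
                        c(D95 = 100, lung_V20 = 30),
                        c(D95 = 99.5, lung_V20 = 30)),
    paired_metric_table(2, "small", "ribs",
                        c(D95 = 100.4, lung_V20 = 31),
                        c(D95 = 100, lung_V20 = 31)),
    paired_metric_table(3, "large", "apex",
                        c(D95 = 99.8, lung_V20 = 28),
                        c(D95 = 100, lung_V20 = 28)))
  expect_equal(metrics$difference, metrics$synCT - metrics$planCT)
  tab <- synctdose:::group_difference_table(metrics)
  all_d95 <- tab[tab$group == "All" & tab$metric == "D95", ]
  expect_equal(all_d95$n, 3)
  expect_equal(all_d95$mean_diff, mean(c(0.5, 0.4, -0.2)), tolerance = 1e-9)
  v20 <- tab[tab$group == "All" & tab$metric == "lung_V20", ]
  expect_equal(v20$flag, "degenerate")
})

test_that("the report bundle writes its tables and figure", {
  metrics <- rbind(
    paired_metric_table(1, "small", "apex", c(D95 = 100), c(D95 = 99.6)),
    paired_metric_table(2, "large", "ribs", c(D95 = 99.9), c(D95 = 100)))
  gam <- data.frame(plan_id = 1:2, size_class = c("small", "large"),
                    location = c("apex", "ribs"), criterion = "2%/2mm",
                    pass_rate = c(99, 100))
  out <- withr::local_tempdir()
  paths <- build_report(metrics, gam, organ_hu = NULL, out_dir = out)
  expect_true(file.exists(file.path(out, "plan_metrics.csv")))
  expect_true(file.exists(file.path(out, "gamma_pass_rates_by_group.csv")))
  expect_true(file.exists(file.path(out, "metric_differences_whisker.png")))
  # empty gamma set: table omitted with a notice, report still produced
  out2 <- withr::local_tempdir()
  expect_message(build_report(metrics, NULL, NULL, out2), "omitted")
  expect_true(file.exists(file.path(out2, "plan_metrics.csv")))
  expect_false(file.exists(file.path(out2, "gamma_pass_rates_by_group.csv")))
})
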