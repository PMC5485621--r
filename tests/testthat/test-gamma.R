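test_that("identical dose grids give gamma zero and a 100% pass rate", {
  r <- smooth_field(12, seed = 3)
  g <- gamma_map(r, r, gamma_criteria(2, 2))
  expect_equal(g$max_gamma, 0)
  expect_equal(g$pass_rate, 100)
  gb <- brute_force_gamma(r, r, gamma_criteria(2, 2))
  expect_equal(gb$max_gamma, 0)
})

test_that("a uniform 3% offset at 2%/2mm is gamma 1.5 everywhere", {
  ref <- volume_grid(array(1, c(12, 12, 12)), 2)
  ev <- volume_grid(array(1.03, c(12, 12, 12)), 2)
  g <- gamma_map(ref, ev, gamma_criteria(2, 2))
  expect_equal(unique(round(as.numeric(g$gamma$values), 9)), 1.5)
  expect_equal(g$pass_rate, 0)
  gb <- brute_force_gamma(ref, ev, gamma_criteria(2, 2))
  expect_equal(unique(round(as.numeric(gb$gamma$values), 9)), 1.5)
})

test_that("a 1 mm shift of a 1%/mm ramp scores the closed-form interior gamma", {
  # continuous minimum of sqrt(d^2/dta^2 + g^2 (d - s)^2 / dd^2) for
  # g = 1%/mm, s = 1 mm at 2%/2mm is 1/sqrt(8) at d = 0.5 mm
  d <- c(48L, 8L, 8L)
  xw <- (seq_len(d[1]) - 0.5)
  mk <- function(shift) {
    v <- array(rep(0.5 + 0.01 * (xw - shift), times = d[2] * d[3]), d)
    volume_grid(v, 1, origin = c(0, 0, 0))
  }
  crit <- gamma_criteria(2, 2, threshold_pct = 0, norm = "prescription",
                         step_frac = 1 / 10)
  g <- gamma_map(mk(0), mk(1), crit, prescription = 1)
  interior <- as.numeric(g$gamma$values[10:39, 4:5, 4:5])
  expect_lt(max(abs(interior - 1 / sqrt(8))), 0.01)
  gb <- brute_force_gamma(mk(0), mk(1), crit, prescription = 1, max_dim = 48L)
  expect_equal(as.numeric(gb$gamma$values[10:39, 4:5, 4:5]), interior,
               tolerance = 1e-12)
})

test_that("gamma_map matches the brute-force oracle on random smooth pairs", {
  for (seed in 1:6) {
    pair <- smooth_dose_pair(seed)
    for (cr in list(c(1, 1), c(2, 2), c(3, 3))) {
      crit <- gamma_criteria(cr[1], cr[2], step_frac = 1 / 10)
      gm <- gamma_map(pair$reference, pair$evaluated, crit)
      gb <- brute_force_gamma(pair$reference, pair$evaluated, crit)
      expect_lt(max(abs(gm$gamma$values - gb$gamma$values), na.rm = TRUE),
                1e-3)
    }
  }
})

test_that("pass rates are monotone in the criteria and in the direction asymmetry", {
  pair <- smooth_dose_pair(11, mix = 0.05)
  rates <- vapply(list(c(1, 1), c(2, 2), c(3, 3)), function(cr)
    gamma_map(pair$reference, pair$evaluated,
              gamma_criteria(cr[1], cr[2]))$pass_rate, numeric(1))
  expect_true(all(diff(rates) >= 0))
  # swapping reference/evaluated changes the result in general
  fwd <- gamma_map(pair$reference, pair$evaluated, gamma_criteria(1, 1))
  rev <- gamma_map(pair$evaluated, pair$reference, gamma_criteria(1, 1))
  expect_false(isTRUE(all.equal(fwd$gamma$values, rev$gamma$values)))
})

test_that("voxels within the dose tolerance pass regardless of the search cap", {
  pair <- smooth_dose_pair(21, mix = 0.04)
  crit <- gamma_criteria(3, 3, search_cap = 0.01)
  g <- gamma_map(pair$reference, pair$evaluated, crit)
  dnorm <- max(pair$reference$values)
  close_enough <- abs(pair$evaluated$values - pair$reference$values) <=
    0.03 * dnorm
  ev <- g$evaluated
  expect_true(all(g$gamma$values[ev & close_enough] <= 1))
})

test_that("the low-dose threshold excludes voxels from map and pass rate", {
  r <- smooth_field(12, seed = 8)          # values span ~[0.01, 1.01]
  e <- r; e$values <- r$values * 1.5       # fails everywhere evaluated
  g <- gamma_map(r, e, gamma_criteria(2, 2, threshold_pct = 50))
  expect_true(all(is.na(g$gamma$values[r$values < 0.5 * max(r$values)])))
  expect_lt(g$pass_rate, 100)
  allbelow <- volume_grid(array(0.01, c(8, 8, 8)), 2)
  hot <- volume_grid(array(1, c(8, 8, 8)), 2)
  # normalisation from the reference max: everything below 10% => error
  allbelow$values[1, 1, 1] <- 1
  allbelow$values[-1, , ] <- 0.0
  expect_error(gamma_map(volume_grid(array(0, c(8, 8, 8)), 2), hot,
                         gamma_criteria(2, 2)), "zero")
})

test_that("pass-rate tables aggregate like the printed summary", {
  res <- data.frame(plan_id = 1:2, size_class = "small", location = "apex",
                    criterion = "2%/2mm", pass_rate = c(98, 100))
  tab <- pass_rate_table(res)
  tot <- tab[tab$group == "Total", ]
  expect_equal(tot$mean, 99)
  expect_equal(tot$sd, sd(c(98, 100)), tolerance = 1e-12)
  one <- pass_rate_table(res[1, ])
  expect_equal(one$sd[one$group == "Total"], 0)
  expect_match(one$flag[one$group == "Total"], "single")
  same <- data.frame(plan_id = 1:3, size_class = "m", location = "l",
                     criterion = "3%/3mm", pass_rate = rep(100, 3))
  tabs <- pass_rate_table(same)
  expect_true(all(tabs$mean == 100 & tabs$sd == 0))
})
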