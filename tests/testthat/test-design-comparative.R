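test_that("superiority sizing reproduces the worked 80% vs 90% comparison", {
  r <- size_superiority(0.80, 0.90, alpha = 0.05, power = 0.90)
  expect_equal(r$n_per_group, 263L)
  expect_equal(r$n_total, 263L)  # paired-diagnostic: one patient sample
  # formula is symmetric under swapping the proportions
  expect_equal(size_superiority(0.90, 0.80)$n_per_group, 263L)
})

test_that("superiority at 80% power matches full-precision formula evaluation", {
  expected <- ceiling((qnorm(0.975) + qnorm(0.80))^2 *
                        (0.8 * 0.2 + 0.9 * 0.1) / (0.90 - 0.80)^2)
  r <- size_superiority(0.80, 0.90, power = 0.80)
  expect_equal(r$n_per_group, as.integer(expected))
  # the returned size delivers at least the nominal asymptotic power
  expect_gte(asymptotic_power(0.80, 0.90, r$n_per_group, 0.05), 0.80)
  expect_lt(asymptotic_power(0.80, 0.90, r$n_per_group - 5L, 0.05), 0.80)
})

test_that("non-inferiority sizing reproduces the worked margins", {
  expect_equal(size_noninferiority(0.80, 0.80, margin = 0.05)$n_per_group,
               1097L)
  expect_equal(size_noninferiority(0.80, 0.80, margin = 0.07)$n_per_group,
               560L)
  expect_equal(size_noninferiority(0.80, 0.82, margin = 0.05)$n_per_group,
               538L)
})

test_that("two-arm framing doubles the total but not the per-group size", {
  r <- size_noninferiority(0.80, 0.80, margin = 0.05, framing = "two-arm-rct")
  expect_equal(r$n_per_group, 1097L)
  expect_equal(r$n_total, 2194L)
  s <- size_superiority(0.80, 0.90, framing = "two-arm-rct")
  expect_equal(s$n_total, 2L * s$n_per_group)
})

test_that("event-rate orientation is normalized to success rates", {
  # disease in 20% of controls vs 10% hoped-for = success rates 80% vs 90%
  r <- size_superiority(0.20, 0.10, rates = "event")
  expect_equal(r$n_per_group, 263L)
  expect_equal(r$p_control, 0.80)
  expect_equal(r$p_new, 0.90)
  rn <- size_noninferiority(0.20, 0.20, margin = 0.05, rates = "event")
  expect_equal(rn$n_per_group, 1097L)
})

test_that("sizes shrink with wider margins and larger effects", {
  margins <- c(0.03, 0.05, 0.07, 0.10)
  ns <- vapply(margins, function(m) {
    size_noninferiority(0.80, 0.80, margin = m)$n_per_group
  }, integer(1))
  expect_true(all(diff(ns) < 0))

  deltas <- c(0.05, 0.10, 0.15)
  ns <- vapply(deltas, function(d) {
    size_superiority(0.80, 0.80 + d)$n_per_group
  }, integer(1))
  expect_true(all(diff(ns) < 0))
})

test_that("sizes grow with power and shrink with alpha", {
  for (sizer in list(
    function(a, pw) size_superiority(0.80, 0.90, alpha = a, power = pw),
    function(a, pw) size_noninferiority(0.80, 0.80, margin = 0.05,
                                        alpha = a, power = pw))) {
    for (a in c(0.01, 0.05)) {
      ns <- vapply(c(0.80, 0.90, 0.95),
                   function(pw) sizer(a, pw)$n_per_group, integer(1))
      expect_true(all(diff(ns) > 0))
    }
    for (pw in c(0.80, 0.90)) {
      expect_gt(sizer(0.01, pw)$n_per_group, sizer(0.05, pw)$n_per_group)
    }
  }
})

test_that("non-inferiority needs more patients than superiority in the worked pairs", {
  # holds for these example pairs; not asserted as a universal law
  expect_gt(size_noninferiority(0.80, 0.80, margin = 0.05)$n_per_group,
            size_superiority(0.80, 0.90)$n_per_group)
  expect_gt(size_noninferiority(0.80, 0.80, margin = 0.05,
                                framing = "two-arm-rct")$n_total,
            size_superiority(0.80, 0.90, framing = "two-arm-rct")$n_total)
})

test_that("impossible or out-of-scope designs are rejected", {
  expect_error(size_superiority(0.80, 0.80), "p_new != p_control")
  expect_error(size_noninferiority(0.80, 0.70, margin = 0.05),
               "cannot be shown")
  expect_error(size_noninferiority(0.80, 0.80, margin = 0), "margin")
  expect_error(size_superiority(0.80, 0.90, ratio = 3), "allocation ratios")
  expect_error(size_noninferiority(0.80, 0.80, margin = 0.05, ratio = 3),
               "allocation ratios")
  expect_error(size_superiority(1.0, 0.9), "p_control")
})

test_that("dropout inflation rounds up and zero inflation is the identity", {
  r <- size_superiority(0.80, 0.90)
  expect_equal(inflate_for_dropout(r, 10)$n_inflated, 290L)  # ceil(289.3)
  expect_equal(inflate_for_dropout(size_noninferiority(0.8, 0.8,
                                                       margin = 0.05),
                                   0)$n_inflated, 1097L)
  r100 <- r; r100$n_total <- 100L
  expect_equal(inflate_for_dropout(r100, 5)$n_inflated, 105L)
  expect_error(inflate_for_dropout(r, 60), "\\[0, 50\\]")
  expect_error(inflate_for_dropout(list(), 10), "samplesize_result")
  # inflate_pct argument on the sizing functions gives the same answer
  expect_equal(size_superiority(0.80, 0.90, inflate_pct = 10)$n_inflated,
               290L)
})
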