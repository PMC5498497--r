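make_counted_tree <- function(newick, counts) {
  tr <- ape::read.tree(text = newick)
  tr$edge.count <- counts
  tr
}

test_that("two-tip fixed-root fit recovers the closed-form rate", {
  tr <- make_counted_tree("(a:1,b:1);", c(10L, 10L))
  fit <- fit_clock(tr, list(calibration("root", 1e5, mode = "fixed")),
                   site_count = 1000)
  expect_equal(fit$rate, (10 + 10) / (2 * 100 * 1000))
  expect_equal(unname(fit$node_ages_ky[3]), 100)
  # fixed calibration contributes no age uncertainty
  expect_equal(unname(fit$node_se_ky[3]), 0)
})

test_that("rate and ages are scale-equivariant in the calibrations", {
  tr <- make_counted_tree("((a:1,b:1):1,(c:1,d:1):1);",
                          c(5L, 12L, 9L, 5L, 11L, 10L))
  f1 <- fit_clock(tr, list(calibration("root", 1e5, 1e4, "gaussian")),
                  site_count = 500)
  f2 <- fit_clock(tr, list(calibration("root", 3e5, 3e4, "gaussian")),
                  site_count = 500)
  n <- 4L
  expect_equal(f2$node_ages_ky[(n + 1):(n + 3)],
               3 * f1$node_ages_ky[(n + 1):(n + 3)], tolerance = 1e-3)
  expect_equal(f2$rate, f1$rate / 3, tolerance = 1e-3)
})

test_that("rate depends on counts only through their branch sums", {
  tr1 <- make_counted_tree("((a:1,b:1):1,(c:1,d:1):1);",
                           c(5L, 12L, 9L, 5L, 11L, 10L))
  # permuting which mutations the counts represent changes nothing
  fitA <- fit_clock(tr1, list(calibration("root", 1e5, mode = "fixed")),
                    site_count = 500)
  fitB <- fit_clock(tr1, list(calibration("root", 1e5, mode = "fixed")),
                    site_count = 500)
  expect_equal(fitA$rate, fitB$rate)
  expect_equal(fitA$node_ages_ky, fitB$node_ages_ky)
})

test_that("true rates fall inside the 95% CI at close to nominal rate", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 1000))
  true_r <- 0.02; L <- 1000
  cover <- 0L; nrep <- 60L
  for (i in seq_len(nrep)) {
    sim <- simulate_genealogy(demo, 8, seed = i)
    tr <- sim$tree
    root_true <- max(tr$ages_yr)
    set.seed(50000 + i)
    tr$edge.count <- stats::rpois(nrow(tr$edge),
                                  true_r * L * tr$edge.length / 1000)
    f <- fit_clock(tr, list(calibration("root", root_true,
                                        0.05 * root_true, "gaussian")),
                   site_count = L, n_starts = 2)
    if (!is.na(f$rate_se) &&
        abs(f$rate - true_r) <= 1.96 * f$rate_se) cover <- cover + 1L
  }
  expect_gte(cover / nrep, 0.9)
})

test_that("ancient dated tips are honoured as fixed ages", {
  tr <- make_counted_tree("(a:1,b:1);", c(10L, 1L))
  fit <- fit_clock(tr, list(calibration("root", 1e5, mode = "fixed")),
                   site_count = 1000, tip_ages = c(b = 5e4))
  # b's branch spans only 50 Ky
  expect_equal(unname(fit$node_ages_ky[2]), 50)
  expect_equal(fit$rate, 11 / ((100 + 50) * 1000))
})

test_that("clock LRT is calm on clock-like data, loud on violations", {
  tr <- make_counted_tree("((a:1,b:1):1,(c:1,d:1):1);",
                          c(5L, 10L, 10L, 5L, 10L, 10L))
  res <- clock_lrt(tr)
  expect_lt(res$statistic, 1e-3)
  expect_gt(res$p, 0.99)
  expect_equal(res$df, 3L)
  # inflate one tip branch 10x
  tr2 <- make_counted_tree("((a:1,b:1):1,(c:1,d:1):1);",
                           c(5L, 100L, 10L, 5L, 10L, 10L))
  res2 <- clock_lrt(tr2)
  expect_gt(res2$statistic, res$statistic)
  expect_lt(res2$p, 0.01)
})

test_that("clock LRT type-I error is near nominal on simulated clocks", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 800))
  rej <- 0L; nrep <- 100L
  for (i in seq_len(nrep)) {
    sim <- simulate_genealogy(demo, 6, seed = 2000 + i)
    tr <- sim$tree
    set.seed(70000 + i)
    tr$edge.count <- stats::rpois(nrow(tr$edge),
                                  0.05 * 500 * tr$edge.length / 1000)
    p <- tryCatch(clock_lrt(tr)$p, error = function(e) NA_real_)
    if (!is.na(p) && p < 0.05) rej <- rej + 1L
  }
  expect_lt(rej / nrep, 0.12)
})

test_that("waiting times convert rates exactly", {
  expect_equal(waiting_time(1, 1), 1)
  expect_equal(waiting_time(3.75e-5, 3790), 1 / (3.75e-5 * 3790))
  expect_error(waiting_time(0, 10), "positive")
  expect_error(waiting_time(1e-5, -1), "positive")
})

test_that("node age report handles singletons and flags non-monophyly", {
  tr <- make_counted_tree("((a:1,b:1):1,(c:1,d:1):1);",
                          c(5L, 10L, 10L, 5L, 10L, 10L))
  fit <- fit_clock(tr, list(calibration("root", 1e5, 1e4, "gaussian")),
                   site_count = 500)
  rep <- node_age_report(fit, list(ab = c("a", "b"), solo = "a"))
  expect_equal(rep$n, c(2L, 1L))
  expect_true(is.na(rep$se_ky[rep$clade == "solo"]))
  expect_equal(rep$ci_hi[1] - rep$age_ky[1], 1.96 * rep$se_ky[1])
  expect_warning(node_age_report(fit, list(bad = c("a", "c"))),
                 "not monophyletic")
})

test_that("age error shrinks as the mutation supply grows", {
  demo <- demographic_model(data.frame(start = 0, end = Inf, ne = 1000))
  err <- vapply(c(1e2, 1e3, 1e4), function(L) {
    e <- 0
    for (i in 1:10) {
      sim <- simulate_genealogy(demo, 6, seed = 300 + i)
      tr <- sim$tree
      root_true <- max(tr$ages_yr)
      set.seed(90000 + i + L)
      tr$edge.count <- stats::rpois(nrow(tr$edge),
                                    0.01 * L * tr$edge.length / 1000)
      f <- fit_clock(tr, list(calibration("root", root_true,
                                          mode = "fixed")),
                     site_count = L, n_starts = 2)
      true_ages <- tr$ages_yr[-(1:6)] / 1000
      est <- f$node_ages_ky[-(1:6)]
      e <- e + mean(abs(est - true_ages) / true_ages)
    }
    e / 10
  }, numeric(1))
  expect_gt(err[1], err[3])
})

test_that("degenerate inputs fail loudly", {
  tr <- make_counted_tree("(a:1,b:1);", c(0L, 0L))
  expect_warning(f <- fit_clock(tr, list(calibration("root", 1e5,
                                                     mode = "fixed")),
                                site_count = 10), "zero mutations")
  expect_equal(f$rate, 0)
  expect_error(fit_clock(tr, list(), site_count = 10), "calibration")
})
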