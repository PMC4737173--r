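test_that("stop frequencies use cumulative reached-transcript denominators", {
  expect_equal(stop_frequencies(fc(c(10, 0, 0), 90))$freq, c(0.1, 0, 0))
  expect_equal(stop_frequencies(fc(c(0, 0), 100))$freq, c(0, 0))
  # RT reaches site 1 only through stops at site 1 or full extension
  expect_equal(stop_frequencies(fc(c(19, 9), 72))$freq, c(19 / 91, 9 / 100))
})

test_that("unreached sites are flagged unobserved with frequency zero", {
  sf <- stop_frequencies(fc(c(0, 5, 5), 0))
  # all 5 transcripts reaching site 2 stopped there; site 1 never reached
  expect_equal(sf$freq, c(0, 1, 0.5))
  expect_equal(sf$observed, c(FALSE, TRUE, TRUE))
})

test_that("theta estimation recovers a one-hot profile from a single signal site", {
  th <- estimate_theta(fc(c(10, 0, 0), 90), fc(c(0, 0, 0), 100, channel = "minus"))
  expect_equal(th$theta, c(1, 0, 0))
  expect_false(th$degenerate)
})

test_that("identical channels give a flagged degenerate profile", {
  th <- estimate_theta(fc(c(5, 3, 2), 90), fc(c(5, 3, 2), 90, channel = "minus"))
  expect_true(th$degenerate)
  expect_equal(th$theta, c(0, 0, 0))
})

test_that("the closed-form theta equals the grid-search likelihood maximizer", {
  plus <- fc(c(19, 9), 72)
  minus <- fc(c(10, 0), 90, channel = "minus")
  th <- estimate_theta(plus, minus)
  oracle <- grid_theta_oracle(plus, minus)
  expect_equal(th$theta, oracle, tolerance = 1e-3)
  # frozen value from the oracle run
  expect_equal(th$theta, c(0.5773542, 0.4226458), tolerance = 1e-6)
})

test_that("negative raw intensities are truncated to zero before normalization", {
  # site 1: more natural drop-off than (+) signal
  th <- estimate_theta(fc(c(1, 20), 79), fc(c(10, 0), 90, channel = "minus"))
  expect_equal(th$theta[1], 0)
  expect_equal(sum(th$theta), 1)
})

test_that("theta is invariant to common depth scaling", {
  plus <- fc(c(12, 4, 0, 7), 150)
  minus <- fc(c(3, 1, 0, 2), 180, channel = "minus")
  th1 <- estimate_theta(plus, minus)
  th2 <- estimate_theta(fc(plus$X * 7L, plus$X_full * 7L),
                        fc(minus$X * 7L, minus$X_full * 7L, channel = "minus"))
  expect_equal(th1$theta, th2$theta)
})

test_that("saturated sites (frequency 1) are clamped with a warning", {
  expect_warning(th <- estimate_theta(fc(c(0, 100), 0), fc(c(0, 0), 100, channel = "minus")),
                 "clamped")
  expect_equal(sum(th$theta), 1)
})

test_that("mismatched channel lengths are a hard error", {
  expect_error(estimate_theta(fc(c(1, 2), 10), fc(c(1, 2, 3), 10, channel = "minus")),
               "different numbers of sites")
})

test_that("rho is mean-1 scaled theta", {
  expect_equal(theta_to_rho(theta_profile("t", c(1, 0, 0)))$rho, c(3, 0, 0))
  expect_equal(theta_to_rho(theta_profile("t", rep(0.25, 4)))$rho, rep(1, 4))
  expect_equal(theta_to_rho(theta_profile("t", c(0.5, 0.3, 0.2)))$rho,
               c(1.5, 0.9, 0.6))
  degen <- theta_to_rho(theta_profile("t", c(0, 0), degenerate = TRUE))
  expect_true(degen$degenerate)
  expect_equal(degen$rho, c(0, 0))
})

test_that("normalization invariants hold over random non-degenerate profiles", {
  set.seed(2024)
  for (i in 1:200) {
    n <- sample(5:80, 1)
    tab <- random_count_table(n, sample(200:5000, 1), seed = i)
    th <- suppressWarnings(estimate_theta(tab$plus, tab$minus))
    if (th$degenerate) next
    expect_lt(abs(sum(th$theta) - 1), 1e-9)
    expect_lt(abs(mean(theta_to_rho(th)$rho) - 1), 1e-9)
    expect_true(all(th$theta >= 0))
  }
})

test_that("reactivity classes follow the 0.5 / 1.25 thresholds", {
  expect_equal(as.character(classify_reactivity(c(1.3, 0.5, 0.2, 1.25, 0))),
               c("high", "moderate", "weak", "moderate", "weak"))
  expect_true(is.na(classify_reactivity(NA_real_)))
  expect_error(classify_reactivity(-0.1), "non-negative")
})

test_that("replicate aggregation gives positionwise mean and sample SD", {
  p <- rho_profile("t", c(1.5, 0.5, 1))
  agg <- aggregate_replicates(list(p, p, p))
  expect_equal(agg$mean, p$rho)
  expect_equal(agg$sd, c(0, 0, 0))

  agg2 <- aggregate_replicates(list(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)))
  expect_equal(agg2$mean, c(2, 2, 2))
  expect_equal(agg2$sd, c(1, 1, 1))

  expect_error(aggregate_replicates(list(c(1, 2))), "at least two")
  expect_error(aggregate_replicates(list(c(1, 2), c(1, 2, 3))), "unequal")
})

test_that("one-sided Welch test matches the textbook formula", {
  a <- c(1.0, 1.1, 0.9); b <- c(2.0, 2.1, 1.9)
  expect_equal(welch_one_sided(b, a, "greater"), welch_manual(b, a, "greater")$p)
  expect_equal(welch_one_sided(a, b, "less"), welch_manual(a, b, "less")$p)
  # Satterthwaite df with unequal variances stays below n1 + n2 - 2
  a2 <- c(1, 1.1, 0.9); b2 <- c(2, 2.2, 1.8)
  expect_lt(welch_manual(a2, b2)$df, 4)
  expect_equal(welch_one_sided(a2, b2, "greater"),
               welch_manual(a2, b2, "greater")$p)
})

test_that("Welch test degenerate cases are handled", {
  expect_equal(welch_one_sided(c(1, 2, 3), c(1, 2, 3), "greater"), 0.5)
  expect_warning(p <- welch_one_sided(c(1, 1, 1), c(1, 1, 1), "greater"),
                 "zero variance")
  expect_equal(p, 0.5)
})

test_that("positionwise Welch compares replicate sets site by site", {
  set.seed(5)
  on <- aggregate_replicates(list(c(2, 0.5), c(2.1, 0.4), c(1.9, 0.6)))
  off <- aggregate_replicates(list(c(0.5, 0.5), c(0.6, 0.4), c(0.4, 0.6)))
  p <- positionwise_welch(on, off, "greater")
  expect_lt(p[1], 0.10)     # clear increase at site 1
  expect_equal(p[2], 0.5)   # identical distributions at site 2
})

test_that("base masking blanks positions outside keep_bases", {
  tg <- target_rna("t", "GACUAAAAAAAAAA", rt_primer_site = c(5, 14),
                   probed_region = c(1, 4))
  expect_equal(mask_by_base(c(1, 1, 1, 1), tg, c("A", "C")),
               c(NA, 1, 1, NA))
  expect_equal(mask_by_base(c(1, 1, 1, 1), tg, c("A", "C", "G", "U")),
               c(1, 1, 1, 1))
  gu <- target_rna("t", "GUGUAAAAAAAAAA", rt_primer_site = c(5, 14),
                   probed_region = c(1, 4))
  expect_true(all(is.na(mask_by_base(c(1, 1, 1, 1), gu, c("A", "C")))))
  expect_error(mask_by_base(c(1, 1, 1, 1), tg, character(0)), "non-empty")
})

test_that("reactivity tables round-trip with the -999 missing sentinel", {
  tg <- synthetic_target(n = 5, primer_length = 10, seed = 9)
  th <- theta_profile("synthRNA", c(0.4, 0.3, 0.2, 0.1, 0),
                      observed = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  rho <- theta_to_rho(th)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_reactivity_table(tg, th, rho, path)
  back <- read_reactivity_table(path)
  expect_equal(back$rho[1:4], rho$rho[1:4])
  expect_true(is.na(back$rho[5]))
  expect_true(is.na(back$theta[5]))
  expect_equal(back$class[1], "high")
})
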