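test_that("posterior PSI matches the Beta closed form", {
  grid <- expand.grid(n = c(0, 1, 2, 5, 10, 40), k = 0:40)
  grid <- grid[grid$k <= grid$n, ]
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; n <- grid$n[i]
    est <- estimate_psi(k, n - k)
    expect_equal(est$psi_mean, (k + 1) / (n + 2), tolerance = 1e-12)
    # credible bounds invert the Beta cdf
    expect_equal(pbeta(est$ci_low, k + 1, n - k + 1), 0.025,
                 tolerance = 1e-9)
    expect_equal(pbeta(est$ci_high, k + 1, n - k + 1), 0.975,
                 tolerance = 1e-9)
    expect_true(est$ci_low <= est$psi_mean && est$psi_mean <= est$ci_high)
  }
  # prior-only case and the documented strong-skew case
  e0 <- estimate_psi(0, 0)
  expect_equal(e0$psi_mean, 0.5)
  expect_equal(c(e0$ci_low, e0$ci_high), c(0.025, 0.975), tolerance = 1e-9)
  expect_equal(estimate_psi(30, 0)$psi_mean, 31 / 32)
  expect_error(estimate_psi(-1, 5), "nonnegative")
})

test_that("pooling sums counts, is order-invariant and guards conditions", {
  reps <- data.frame(event_id = "ev1", condition = "16C",
                     replicate = 1:2, n_incl = c(12L, 20L),
                     n_excl = c(8L, 10L), stringsAsFactors = FALSE)
  pooled <- pool_counts(reps)
  expect_equal(pooled$n_incl, 32L)
  expect_equal(pooled$n_excl, 18L)
  expect_equal(pooled$replicate, "pooled")
  expect_equal(pool_counts(reps[1, ])$n_incl, 12L)
  set.seed(3)
  shuffled <- reps[sample(nrow(reps)), ]
  expect_equal(pool_counts(shuffled)[c("n_incl", "n_excl")],
               pooled[c("n_incl", "n_excl")])
  reps$condition <- c("16C", "25C")
  expect_error(pool_counts(reps), "mixed conditions")
})

test_that("isoform-specific read counting follows the compatibility rule", {
  ev <- enumerate_events(canonical_event_gene("IR"))  # alt (100, 200)
  reads <- list(
    rbind(c(90, 130)),                 # crosses into the retained intron
    rbind(c(80, 100), c(200, 220)),    # spans the exact splice junction
    rbind(c(50, 90)),                  # within the shared flank: ambiguous
    rbind(c(80, 110), c(190, 220))     # junction matching neither form
  )
  cts <- count_event_reads(ev, reads)
  expect_equal(cts$n_incl, 1L)
  expect_equal(cts$n_excl, 1L)
  expect_equal(count_event_reads(ev, list())[c("n_incl", "n_excl")],
               data.frame(n_incl = 0L, n_excl = 0L))
})

test_that("simulated alignments recover the inclusion fraction", {
  for (type in c("IR", "ES", "MXE")) {
    ev <- enumerate_events(canonical_event_gene(type))
    pure_incl <- count_event_reads(
      ev, gen_read_alignments(ev, 200, psi = 1, seed = 4))
    expect_equal(pure_incl$n_excl, 0L, info = type)
    expect_gt(pure_incl$n_incl, 0)
    pure_excl <- count_event_reads(
      ev, gen_read_alignments(ev, 200, psi = 0, seed = 5))
    expect_equal(pure_excl$n_incl, 0L, info = type)
    mixed <- count_event_reads(
      ev, gen_read_alignments(ev, 600, psi = 0.5, seed = 6))
    psi_hat <- estimate_psi(mixed$n_incl, mixed$n_excl)$psi_mean
    expect_lt(abs(psi_hat - 0.5), 0.15)
  }
})

test_that("Bayes factor behaves as evidence for a PSI difference", {
  cts <- function(i, e) data.frame(n_incl = i, n_excl = e)
  # identical pooled counts: posterior mass piles at delta = 0
  expect_lt(bayes_factor_delta(cts(50, 50), cts(50, 50), seed = 1), 1)
  # opposite extremes: overwhelming evidence
  expect_gt(bayes_factor_delta(cts(90, 10), cts(10, 90), seed = 1), 5)
  # symmetric under condition swap (Monte-Carlo tolerance)
  b1 <- bayes_factor_delta(cts(70, 30), cts(45, 55), seed = 2)
  b2 <- bayes_factor_delta(cts(45, 55), cts(70, 30), seed = 2)
  expect_lt(abs(log(b1 / b2)), 0.2)
  # agrees with the exact overlap-integral oracle in the moderate regime
  for (case in list(c(50, 50, 50, 50), c(60, 40, 40, 60), c(5, 5, 8, 2))) {
    impl <- bayes_factor_delta(cts(case[1], case[2]), cts(case[3], case[4]),
                               seed = 3)
    oracle <- bf_quadrature(case[1], case[2], case[3], case[4])
    expect_lt(abs(log(impl / oracle)), 0.35,
              label = paste("BF vs quadrature,", paste(case, collapse = ",")))
  }
  expect_error(bayes_factor_delta(cts(1, 1), cts(1, 1), n_draws = 10), "1000")
})

test_that("support filter requires enough reads in enough replicates", {
  reps <- function(totals) data.frame(event_id = "e", condition = "c",
                                      n_incl = totals, n_excl = 0L)
  expect_true(support_filter(reps(c(25, 18, 30)), reps(c(21, 22, 5))))
  expect_false(support_filter(reps(c(25, 18, 19)), reps(c(21, 22, 30))))
  expect_true(support_filter(reps(c(1, 1)), reps(c(0, 0)),
                             min_reads = 0, min_reps = 2))
})

test_that("consistency filter compares within spread to between difference", {
  expect_true(consistency_filter(c(0.20, 0.25, 0.22), c(0.60, 0.55, 0.65)))
  expect_false(consistency_filter(c(0.1, 0.6), c(0.35, 0.40)))
  # single replicates: zero within-spread, any mean difference passes
  expect_true(consistency_filter(0.3, 0.5))
  # ties fail the strict inequality
  expect_false(consistency_filter(c(0.5, 0.5), c(0.5, 0.5)))
})
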