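test_that("stimulus is the normalized payoff-aspiration mismatch, clamped", {
  expect_equal(compute_stimulus(0.75, 0.5, 1), 0.5)
  # aspiration at the endowment: defined as zero whatever the payoff
  expect_equal(compute_stimulus(c(0, 0.3, 1), 1, 1), c(0, 0, 0))
  # raw value (0 - 0.8) / 0.2 = -4 is clamped to -1
  expect_equal(compute_stimulus(0, 0.8, 1), -1)
  # sign tracks payoff - aspiration
  expect_gt(compute_stimulus(0.6, 0.5), 0)
  expect_lt(compute_stimulus(0.4, 0.5), 0)
  expect_error(compute_stimulus(1.2, 0.5), "payoff")
  expect_error(compute_stimulus(0.5, -0.1), "aspiration")
})

test_that("aspiration update moves towards the endowment or zero by branch", {
  expect_equal(update_aspiration(0.5, 1, 1), 1)
  expect_equal(update_aspiration(0.5, -1, 1), 0)
  expect_equal(update_aspiration(0.4, 0.5, 0.2), 0.46)
  # zero stimulus or zero learning rate leaves the aspiration alone
  expect_equal(update_aspiration(0.3, 0, 0.7), 0.3)
  expect_equal(update_aspiration(0.3, 0.9, 0), 0.3)
})

test_that("habituation is a convex combination of own donation and payoff", {
  expect_equal(update_donation_habituation(0.3, 0.3, 0.42), 0.3)
  expect_equal(update_donation_habituation(0.2, 0.6, 0.5), 0.4)
  expect_equal(update_donation_habituation(0.9, 0.1, 1), 0.1)
  expect_equal(update_donation_habituation(0.9, 0.1, 0), 0.9)
})

test_that("aspiration bound caps donations at endowment minus aspiration", {
  expect_equal(apply_aspiration_bound(0.6, 0.7, 1), 0.3)
  expect_equal(apply_aspiration_bound(0.2, 0.5, 1), 0.2)
  expect_equal(apply_aspiration_bound(-0.1, 0.5, 1), 0)
})

test_that("trembling hand is unbiased multiplicative noise, clipped", {
  expect_identical(apply_trembling_hand(0.3, 0), 0.3)
  set.seed(1)
  expect_equal(apply_trembling_hand(rep(0, 10), 0.1), rep(0, 10))
  set.seed(42)
  draws <- apply_trembling_hand(rep(0.3, 1e5), 0.1)
  # E[(1+eps) D] = D; clipping is negligible at these values
  se <- 0.3 * 0.1 / sqrt(1e5)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
  expect_true(all(draws >= 0 & draws <= 1))
})

test_that("envy cap limits donations to half the pie", {
  expect_equal(apply_envy_cap(0.7, 1), 0.5)
  expect_equal(apply_envy_cap(0.3, 1), 0.3)
  expect_equal(apply_envy_cap(0.5, 1), 0.5)
  expect_equal(apply_envy_cap(1.4, 2), 1)
})

test_that("recipient update composes the rules; frozen agents never move", {
  p <- dg_params(0.5, 0.5, n_agents = 2)
  frozen <- recipient_update(0.8, 0.1, 0.9, p, frozen = TRUE)
  expect_identical(frozen, list(aspiration = 0.8, donation = 0.1))
  # fair-split fixed point
  fp <- recipient_update(0.5, 0.5, 0.5, p)
  expect_equal(fp, list(aspiration = 0.5, donation = 0.5))
  # hand-checkable case: s = (0.2 - 0.6)/0.4 = -1, negative branch
  upd <- recipient_update(0.6, 0.4, 0.2, p)
  expect_equal(upd$aspiration, 0.3)
  expect_equal(upd$donation, 0.3)
  expect_equal(unname(oracle_recipient_update(0.6, 0.4, 0.2, 0.5, 0.5)),
               c(upd$aspiration, upd$donation))
})

test_that("recipient update keeps aspirations and donations in [0, endowment]", {
  set.seed(101)
  for (rep in 1:40) {
    p <- dg_params(runif(1), runif(1),
                   noise_scale = sample(c(0, 0.1, 0.5), 1),
                   n_agents = 50)
    n <- 50
    a <- runif(n)
    d <- runif(n)
    upd <- recipient_update(a, d, runif(n), p,
                            envious = runif(n) < 0.3,
                            frozen = runif(n) < 0.2)
    expect_true(all(upd$aspiration >= 0 & upd$aspiration <= 1))
    expect_true(all(upd$donation >= 0 & upd$donation <= 1))
  }
})

test_that("without noise the updated donation never exceeds endowment minus aspiration", {
  set.seed(202)
  for (rep in 1:40) {
    p <- dg_params(runif(1), runif(1), n_agents = 50)
    n <- 50
    upd <- recipient_update(runif(n), runif(n), runif(n), p,
                            envious = runif(n) < 0.3)
    expect_true(all(upd$donation <= 1 - upd$aspiration + 1e-12))
  }
})

test_that("a larger payoff never yields a smaller updated aspiration", {
  set.seed(303)
  for (rep in 1:200) {
    p <- dg_params(runif(1), runif(1), n_agents = 2)
    a <- runif(1)
    d <- runif(1)
    pis <- sort(runif(2))
    lo <- recipient_update(a, d, pis[1], p)
    hi <- recipient_update(a, d, pis[2], p)
    expect_gte(hi$aspiration, lo$aspiration)
  }
})

test_that("vectorized recipient update matches the straight-line scalar oracle", {
  set.seed(404)
  n <- 1e4
  a <- runif(n)
  d <- runif(n)
  pi <- runif(n)
  l <- runif(1)
  h <- runif(1)
  p <- dg_params(l, h, n_agents = 2)
  upd <- recipient_update(a, d, pi, p)
  expected <- vapply(seq_len(n),
                     function(i) oracle_recipient_update(a[i], d[i], pi[i], l, h),
                     numeric(2))
  expect_equal(upd$aspiration, unname(expected[1, ]), tolerance = 1e-12)
  expect_equal(upd$donation, unname(expected[2, ]), tolerance = 1e-12)
})
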