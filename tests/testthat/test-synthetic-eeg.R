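test_that("item patterns realise the requested within-group correlation", {
  design <- std_design(seed = 1)
  # rho = 0: independent patterns, mean pairwise correlation near 0
  p0 <- sim_params(rho_animate = 0, rho_inanimate = 0)
  # rho = 0.99: almost perfectly shared patterns
  p99 <- sim_params(rho_animate = 0.99, rho_inanimate = 0.99)
  mean_pair_cor <- function(pat, ids) {
    cc <- cor(pat[, ids])
    mean(cc[upper.tri(cc)])
  }
  nouns <- attr(design, "nouns")
  anim6 <- head(nouns$id[nouns$animacy == "animate"], 6)
  set.seed(11)
  r0 <- replicate(200, mean_pair_cor(generate_item_patterns(design, p0),
                                     anim6))
  r99 <- replicate(200, mean_pair_cor(generate_item_patterns(design, p99),
                                      anim6))
  expect_lt(abs(mean(r0)), 0.02)
  expect_lt(abs(mean(r99) - 0.99), 0.005)
})

test_that("unequal rho makes animate patterns reliably more similar", {
  design <- std_design(seed = 1)
  p <- sim_params(rho_animate = 0.5, rho_inanimate = 0.1)
  nouns <- attr(design, "nouns")
  gmean <- function(pat, g) {
    ids <- head(nouns$id[nouns$animacy == g], 6)
    cc <- cor(pat[, ids])
    mean(cc[upper.tri(cc)])
  }
  set.seed(12)
  wins <- replicate(100, {
    pat <- generate_item_patterns(design, p)
    gmean(pat, "animate") > gmean(pat, "inanimate")
  })
  expect_gte(mean(wins), 0.95)
})

test_that("rho outside [0, 1) is rejected", {
  expect_error(sim_params(rho_animate = 1), "rho")
  expect_error(sim_params(rho_inanimate = -0.1), "rho")
})

test_that("noiseless epochs follow the generative closed form", {
  design <- small_design(seed = 2)
  p <- sim_params(n_subjects = 1, n_channels = 10, fs = 100,
                  epoch_span = c(-500, 600), noise_sd = 0,
                  artifact_prob = 0)
  pat <- generate_item_patterns(design, p, seed = 3)
  ep <- simulate_epochs(design, p, patterns = pat, seed = 4)
  cong <- which(design$congruency == "congruent")[1]
  # outside the prediction window, the pre-noun signal is exactly zero
  out_idx <- which(ep$times < -240)
  expect_true(all(ep$data[1, cong, , out_idx] == 0))
  # at the Hann peak (-120 ms), signal equals pred_amplitude * pattern
  pk <- which(ep$times == -120)
  expect_equal(ep$data[1, cong, , pk],
               p$pred_amplitude * pat[, design$noun_id[cong]])
})

test_that("injected N400 is negative at Cz for incongruent trials", {
  design <- small_design(seed = 2)
  p <- sim_params(n_subjects = 1, n_channels = 10, fs = 100,
                  epoch_span = c(-500, 600), noise_sd = 0,
                  artifact_prob = 0)
  ep <- simulate_epochs(design, p, seed = 5)
  cz <- which(ep$channels == "CZ")
  n4 <- ep$times >= 300 & ep$times < 500
  g <- function(cond) {
    j <- which(design$congruency != "congruent") # all incongruent
    if (cond == "congruent") j <- which(design$congruency == "congruent")
    mean(ep$data[1, j, cz, n4])
  }
  expect_lt(g("incongruent") - g("congruent"), 0)
  # recompute from the generative equation: weight * amplitude * topography
  # * mean Hann over the window, averaged over incongruent trials
  w <- p$n400_weights[cbind(design$animacy_constraint, design$congruency)]
  hann <- function(t) 0.5 * (1 - cos(2 * pi * (t - 300) / 200))
  topo_cz <- n400_topography(ep$channels)[cz]
  exp_diff <- -mean(w[design$congruency != "congruent"]) *
    p$n400_amplitude * topo_cz * mean(hann(ep$times[n4]))
  expect_equal(g("incongruent") - g("congruent"), exp_diff, tolerance = 1e-10)
})

test_that("simulation is bit-identical under a fixed seed", {
  design <- small_design(seed = 1)
  p <- sim_params(n_subjects = 2, n_channels = 8, fs = 100,
                  epoch_span = c(-400, 600))
  a <- simulate_epochs(design, p, seed = 99)
  b <- simulate_epochs(design, p, seed = 99)
  expect_identical(a$data, b$data)
  ba <- simulate_behavior(design, p, n_subjects = 2, seed = 7)
  bb <- simulate_behavior(design, p, n_subjects = 2, seed = 7)
  expect_identical(ba, bb)
})

test_that("behaviour carries responses only for incongruent trials", {
  design <- std_design(seed = 1)
  p <- sim_params(n_subjects = 3)
  beh <- simulate_behavior(design, p, seed = 8)
  expect_true(all(beh$congruency != "congruent"))
  expect_equal(nrow(beh), 3 * 120)
  expect_true(all(beh$rt_ms > 0))
})

test_that("deterministic latency model yields the exact mismatch advantage", {
  design <- std_design(seed = 1)
  p0 <- sim_params(n_subjects = 2, rt_sd = 0)
  beh <- simulate_behavior(design, p0, seed = 1)
  m <- tapply(beh$rt_ms, beh$congruency, mean)
  expect_equal(unname(m["incongruent_animacy_match"] -
                        m["incongruent_animacy_mismatch"]), 22)
  pn <- sim_params(n_subjects = 2, rt_sd = 0, rt_mismatch_advantage = 0)
  behn <- simulate_behavior(design, pn, seed = 1)
  mn <- tapply(behn$rt_ms, behn$congruency, mean)
  expect_equal(unname(diff(mn)), 0)
})

test_that("estimated advantage approaches 22 ms at large n", {
  design <- std_design(seed = 1)
  p <- sim_params(n_subjects = 150)
  beh <- simulate_behavior(design, p, seed = 10)
  rc <- rt_contrast(beh, mode = "pooled")
  expect_equal(rc$difference_ms, 22, tolerance = 0.25) # +-5 ms absolute
})

test_that("epoch container enforces its axis invariants", {
  design <- toy_design(2)
  arr <- array(0, c(1, 2, 3, 4))
  expect_error(epoch_set(arr, c(0, 10, 20, 31), 100, montage_62(3), design),
               "spacing")
  expect_error(epoch_set(arr, c(0, 10, 20, 30), 100, montage_62(3),
                         toy_design(5)), "trial dimension")
  ep <- epoch_set(arr, c(0, 10, 20, 30), 100, montage_62(3), design)
  expect_s3_class(ep, "epoch_set")
})
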