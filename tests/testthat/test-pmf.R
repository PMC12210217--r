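test_that("softmin distance has the right limits and closed-form values", {
  expect_equal(softmin_distance(0.5), 0.5)
  expect_equal(softmin_distance(c(1, 1), beta = 100), 100 / (log(2) + 100),
               tolerance = 1e-12)
  expect_equal(softmin_distance(c(0.4, 4.0), beta = 100), 0.4,
               tolerance = 1e-6)
  # approaches the hard minimum monotonically from below as beta grows
  d <- c(0.7, 0.9, 1.4)
  betas <- c(5, 10, 20, 50, 100)
  vals <- vapply(betas, function(b) softmin_distance(d, b), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < min(d)))
  expect_equal(softmin_distance(d, 2000), min(d), tolerance = 1e-3)
  # numerically safe for very small distances (large exponents)
  expect_equal(softmin_distance(c(1e-3, 2), beta = 100), 1e-3,
               tolerance = 1e-6)
  expect_error(softmin_distance(c(0.5, -1)), "positive")
})

test_that("window schedules follow the half-open convention", {
  w <- build_windows(0.35, 4.4, 0.05)
  expect_length(w, 81)
  expect_equal(w[1], 0.35)
  expect_equal(w[81], 4.35)
  expect_equal(build_windows(0, 1, 0.25), c(0, 0.25, 0.5, 0.75))
  expect_length(build_windows(1.0, 1.0 + 1e-9, 0.5), 1)
  expect_error(build_windows(2, 1, 0.1), "stop > start")
  expect_error(build_windows(0, 1, -0.1), "step > 0")
})

test_that("in the unbiased single-window limit WHAM reduces to the histogram estimator", {
  set.seed(31)
  x <- rnorm(20000, 0.5, 0.08)
  win <- umbrella_window(0.5, x, force_constant = 1e-9)
  p <- wham(win, bin_width = 0.02)
  h <- hist(x, breaks = seq(min(p$bin) - 0.01, max(p$bin) + 0.011, by = 0.02),
            plot = FALSE)
  kt <- 0.0083144621 * 300
  ref <- -kt * log(h$counts)
  ok <- h$counts > 0
  diff_prof <- (p$free_energy - min(p$free_energy, na.rm = TRUE))[ok] -
    (ref - min(ref[ok]))[ok]
  expect_lt(max(abs(diff_prof)), 1e-6)
})

test_that("wham recovers a flat landscape from biased windows", {
  s <- sample_umbrella("flat", build_windows(0.05, 1.05, 0.1),
                       force_constant = 200, n_per_window = 5000, seed = 23)
  p <- wham(s, range = c(-0.3, 1.3))
  expect_true(attr(p, "converged"))
  kt <- attr(p, "kT")
  sel <- !is.na(p$free_energy) & p$bin >= 0.05 & p$bin <= 0.95
  expect_lt(diff(range(p$free_energy[sel])), 0.2 * kt)
})

test_that("wham warns on gapped windows and drops empty ones", {
  s1 <- umbrella_window(0.0, rnorm(500, 0, 0.02), 500)
  s2 <- umbrella_window(2.0, rnorm(500, 2, 0.02), 500)
  expect_warning(wham(dplyr::bind_rows(s1, s2)), "overlap")
})

test_that("replicate uncertainty removes the anchoring gauge", {
  s <- sample_umbrella("doublewell", build_windows(0.05, 1.05, 0.1),
                       force_constant = 200, n_per_window = 500, seed = 1)
  p1 <- wham(s, range = c(-0.3, 1.3))
  p2 <- p1
  p2$free_energy <- p2$free_energy + 3.7   # constant offset only
  u <- pmf_uncertainty(list(p1, p2))
  expect_true(all(u$sd_fe[!is.na(u$sd_fe)] < 1e-9))
  u_same <- pmf_uncertainty(list(p1, p1, p1))
  expect_true(all(u_same$sd_fe[!is.na(u_same$sd_fe)] == 0))
  p3 <- wham(s, range = c(-0.4, 1.3))
  expect_error(pmf_uncertainty(list(p1, p3)), "binned differently")
})

test_that("the std envelope of noisy replicates brackets the true profile", {
  reps <- lapply(1:3, function(sd) {
    s <- sample_umbrella("doublewell", build_windows(0.05, 1.05, 0.1),
                         force_constant = 200, n_per_window = 1500,
                         seed = 100 + sd)
    wham(s, range = c(-0.3, 1.3))
  })
  u <- pmf_uncertainty(reps)
  sel <- u$bin >= 0 & u$bin <= 1 & !is.na(u$mean_fe) & u$sd_fe > 0
  truth <- doublewell_potential(u$bin[sel])
  truth <- truth - min(truth)
  covered <- abs(u$mean_fe[sel] - truth) <= 2 * u$sd_fe[sel] + 0.25
  expect_gte(mean(covered), 0.9)
})

test_that("desorption cost is the plateau-minus-minimum and is gauge invariant", {
  kt <- 0.0083144621 * 300
  mk <- function(fe, bins) {
    out <- tibble::tibble(bin = bins, free_energy = fe,
                          n_samples = rep(100L, length(bins)))
    class(out) <- c("pmf_result", class(out))
    attr(out, "kT") <- kt
    attr(out, "anchor_width") <- 1
    out
  }
  bins <- seq(0.025, 3, by = 0.05)
  expect_equal(desorption_cost(mk(rep(0, length(bins)), bins)), 0)
  # planted single minimum of depth 3 relative to the plateau
  fe <- 3 * (1 - exp(-(bins - 0.325)^2 / 0.02)) - 3  # minimum on a bin centre
  fe <- fe - min(fe)
  expect_equal(desorption_cost(mk(fe, bins)), 3, tolerance = 1e-6)
  expect_equal(desorption_cost(mk(fe + 11.1, bins)),
               desorption_cost(mk(fe, bins)), tolerance = 1e-12)
  sloped <- mk(bins * 5, bins)
  expect_warning(desorption_cost(sloped), "plateau")
})
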