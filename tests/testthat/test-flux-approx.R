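# Analytic moments of the uniform distribution over the fixtures (see
# helper-oracles.R): chain fluxes are identical and uniform on [0,1];
# triangle outputs are uniform over the 2-simplex.

test_that("sampler reproduces the chain's analytic moments", {
  sp <- run_fva(flux_space(make_chain_model(3), "c")) |>
    (\(f) remove_blocked(flux_space(make_chain_model(3), "c"), f))()
  mom <- sample_moments(sp, n_samples = 20000L, seed = 4)
  expect_equal(unname(mom$mean), rep(chain_oracle$mean, 3), tolerance = 0.02)
  expect_equal(unname(mom$variance), rep(chain_oracle$var, 3), tolerance = 0.01)
  # all three fluxes are the same coordinate: correlation 1
  expect_equal(min(cov2cor(mom$covariance)), 1, tolerance = 1e-6)
})

test_that("sampler reproduces the triangle's analytic moments", {
  sp0 <- flux_space(make_triangle_model(), "t")
  sp <- remove_blocked(sp0, run_fva(sp0))
  mom <- sample_moments(sp, n_samples = 40000L, seed = 7)
  expect_equal(unname(mom$mean),
               c(triangle_oracle$mean_in, triangle_oracle$mean_out,
                 triangle_oracle$mean_out), tolerance = 0.02)
  expect_equal(unname(mom$variance[2]), triangle_oracle$var_out, tolerance = 0.02)
  expect_equal(mom$covariance["r2", "r3"], triangle_oracle$cov_out,
               tolerance = 0.02)
  # cross-check against an independent rejection sampler
  ref <- triangle_reference_sample(20000, seed = 99)
  expect_equal(unname(mom$mean), unname(colMeans(ref)), tolerance = 0.03)
})

test_that("EP matches sampling within module tolerances on the triangle", {
  sp0 <- flux_space(make_triangle_model(), "t")
  sp <- remove_blocked(sp0, run_fva(sp0))
  ep <- ep_moments(sp)
  smp <- sample_moments(sp, n_samples = 40000L, seed = 11)
  rng <- sp$model$ub - sp$model$lb
  expect_true(all(abs(ep$mean - smp$mean) <= 0.05 * rng))
  cep <- cov2cor(ep$covariance); csm <- cov2cor(smp$covariance)
  expect_gt(cor(cep[lower.tri(cep)], csm[lower.tri(csm)]), 0.9)
})

test_that("EP is bitwise deterministic", {
  sp0 <- flux_space(make_triangle_model(), "t")
  sp <- remove_blocked(sp0, run_fva(sp0))
  e1 <- ep_moments(sp); e2 <- ep_moments(sp)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$covariance, e2$covariance)
})

test_that("zero-width directions get (near-)zero variance", {
  m <- make_chain_model(2)
  m$lb[] <- c(0.25, 0.25); m$ub[] <- c(0.25, 0.25)
  sp <- flux_space(m, "fixed")
  ep <- ep_moments(sp)
  expect_equal(unname(ep$mean), c(0.25, 0.25), tolerance = 1e-4)
  expect_true(all(ep$variance <= 1e-10))
})

test_that("sampling is seed-reproducible and leaves the global RNG alone", {
  sp0 <- flux_space(make_triangle_model(), "t")
  sp <- remove_blocked(sp0, run_fva(sp0))
  set.seed(123); before <- .Random.seed
  m1 <- sample_moments(sp, n_samples = 500L, seed = 5)
  expect_identical(.Random.seed, before)   # private RNG stream
  m2 <- sample_moments(sp, n_samples = 500L, seed = 5)
  expect_identical(m1$mean, m2$mean)
  expect_identical(m1$covariance, m2$covariance)
  m3 <- sample_moments(sp, n_samples = 500L, seed = 6)
  expect_false(identical(m1$mean, m3$mean))
})

test_that("moment tables round-trip through TSV", {
  sp0 <- flux_space(make_triangle_model(), "t")
  sp <- remove_blocked(sp0, run_fva(sp0))
  mom <- sample_moments(sp, n_samples = 1000L, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_moments_tsv(mom, f)
  back <- read.delim(f)
  expect_equal(back$reaction_id, mom$reaction_ids)
  expect_equal(back$mean, unname(mom$mean))
  expect_equal(back$variance, unname(mom$variance))
})
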