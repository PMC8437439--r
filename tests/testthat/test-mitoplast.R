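test_that("ramp current law obeys its trivial limits", {
  m <- ramp_model()
  v <- seq(-160, 80, by = 5)
  # no charge carrier, no current
  expect_equal(ramp_current_law(m, v, ca_i = 0, permeant = "Ca"), rep(0, length(v)))
  # Hill midpoint of the magnesium block halves the current (calcium far
  # below its half-saturation so the competitive shift is negligible)
  m1 <- ramp_model(mg_block = list(ic50 = 150, n_h = 1, competitive = FALSE))
  i0 <- ramp_current_law(m1, -160, ca_i = 30, mg_i = 0)
  i1 <- ramp_current_law(m1, -160, ca_i = 30, mg_i = 150)
  expect_equal(i1 / i0, 0.5, tolerance = 1e-12)
  expect_error(ramp_current_law(m, -160, ca_i = -1), "non-negative")
})

test_that("sodium-mode sweeps are genotype independent", {
  m <- ramp_model()
  wt <- simulate_ramp(m, ca_i = 0, permeant = "Na", genotype = "WT", seed = 4)
  ko <- simulate_ramp(m, ca_i = 0, permeant = "Na", genotype = "MICU1KO", seed = 4)
  expect_identical(wt$current, ko$current)
  # nanomolar calcium blocks the sodium current identically in both
  blocked <- ramp_current_law(m, -80, ca_i = 0.002, permeant = "Na")
  open <- ramp_current_law(m, -80, ca_i = 0, permeant = "Na")
  expect_equal(blocked / open, 0.5, tolerance = 1e-12)  # 2 nM at Kd = 2 nM
})

test_that("WT inward limb is micu_factor times the knockout limb at saturating calcium", {
  m <- ramp_model(noise_sd = 0)
  wt <- ramp_current_law(m, -160, ca_i = 5e4, genotype = "WT")
  ko <- ramp_current_law(m, -160, ca_i = 5e4, genotype = "MICU1KO")
  expect_equal(wt / ko, m$micu_factor, tolerance = 1e-4)
})

test_that("voltage readout interpolates the generating law and scales with capacitance", {
  m <- ramp_model(noise_sd = 0)
  sw <- simulate_ramp(m, ca_i = 1000, seed = 1)
  for (v in c(-160, -120, -80, -33.3)) {
    got <- current_at_voltage(sw, v)$current_pA
    want <- ramp_current_law(m, v, ca_i = 1000)
    expect_equal(got, want, tolerance = 0.005 * abs(want) + 1e-9)
  }
  expect_equal(current_at_voltage(sw, -80)$density_pA_pF,
               current_at_voltage(sw, -80)$current_pA / sw$capacitance)
  expect_error(current_at_voltage(sw, -200), "outside")

  # constant current: density is current over capacitance at any voltage
  flat <- ramp_sweep(seq(0, 0.1, length.out = 1000),
                     seq(-160, 80, length.out = 1000), rep(-50, 1000), 0.5)
  expect_equal(current_at_voltage(flat, -100)$density_pA_pF, -100)
})

test_that("control subtraction removes programmed leak", {
  m <- ramp_model(noise_sd = 0)
  sw <- simulate_ramp(m, ca_i = 1000, seed = 2)
  zero <- sw
  zero$current <- rep(0, length(sw$current))
  expect_equal(subtract_control(sw, zero)$current, sw$current)
  expect_equal(subtract_control(sw, sw)$current, rep(0, length(sw$current)))
  leak <- sw
  leak$current <- sw$current + 0.05 * sw$voltage
  leak_only <- sw
  leak_only$current <- 0.05 * sw$voltage
  expect_equal(subtract_control(leak, leak_only)$current, sw$current)
  short <- ramp_sweep(sw$time[1:10], sw$voltage[1:10], sw$current[1:10], 0.4)
  expect_error(subtract_control(sw, short), "protocols")
})

test_that("paired ratios are gain invariant", {
  expect_equal(paired_ratio(-200, -100), 2)
  expect_equal(paired_ratio(-50, -50), 1)
  expect_equal(paired_ratio(3 * -200, 3 * -100), paired_ratio(-200, -100))
  expect_error(paired_ratio(1:3, 1:2), "equal-length")
})

test_that("Hill inhibition fit recovers noiseless parameters to machine tolerance", {
  conc <- c(0, 20, 60, 150, 400, 1200)
  resp <- 1 / (1 + (conc / 150)^0.9)
  fit <- fit_hill_inhibition(conc, resp)
  expect_equal(fit$ic50, 150, tolerance = 1e-6)
  expect_equal(fit$n_h, 0.9, tolerance = 1e-6)
  # defining identities of the fixed-asymptote Hill form
  f <- function(c_) 1 / (1 + (c_ / fit$ic50)^fit$n_h)
  expect_equal(f(fit$ic50), 0.5)
  expect_equal(f(0), 1)
  expect_error(fit_hill_inhibition(c(0, 10, 20), c(1, 0.8, 0.6)), "at least 4")
  expect_warning(fit_hill_inhibition(c(0, 10, 100, 1000), c(1, 0.3, 0.9, 0.1)),
                 "non-monotone")
})

test_that("Hill IC50 bias stays below 10 percent under 5 percent noise", {
  conc <- c(0, 20, 60, 150, 400, 1200)
  clean <- 1 / (1 + (conc / 150)^1)
  set.seed(7)
  est <- replicate(100, {
    fit_hill_inhibition(conc, clean + rnorm(length(conc), 0, 0.05))$ic50
  })
  expect_lt(abs(median(est) - 150) / 150, 0.10)
})

test_that("one-site calcium block fit recovers a 2 nM Kd exactly", {
  ca <- c(0, 0.5, 1, 2, 5, 20)
  resp <- 1 / (1 + ca / 2)
  fit <- fit_ca_block_of_ina(ca, resp)
  expect_equal(fit$kd_nM, 2, tolerance = 1e-8)
  expect_equal(1 / (1 + fit$kd_nM / fit$kd_nM), 0.5)
})

test_that("exponential kinetics fits recover the solution-exchange time constant", {
  tr <- simulate_fast_application(tau_ms = 0.4, amplitude_pA = -50, noise_sd = 0)
  fit <- fit_exponential_kinetics(tr$time_s, tr$current_pA, "activation")
  expect_equal(fit$tau_ms, 0.4, tolerance = 1e-6)
  # deactivation mirror has the same tau
  tr2 <- simulate_fast_application(tau_ms = 0.4, amplitude_pA = -50,
                                   direction = "deactivation", noise_sd = 0)
  fit2 <- fit_exponential_kinetics(tr2$time_s, tr2$current_pA, "deactivation")
  expect_equal(fit2$tau_ms, fit$tau_ms, tolerance = 1e-6)
  # normalization changes the amplitude but not tau
  fit3 <- fit_exponential_kinetics(tr$time_s, tr$current_pA, "activation",
                                   normalize = TRUE)
  expect_equal(fit3$tau_ms, 0.4, tolerance = 1e-6)
  expect_error(fit_exponential_kinetics(tr$time_s, rep(-5, nrow(tr)), "activation"),
               "amplitude")
  expect_error(fit_exponential_kinetics(tr$time_s, tr$current_pA, "activation",
                                        window = c(0, 2e-5)), "window")
})

test_that("rectification index matches hand values and the generative constraint", {
  tm <- seq(0, 0.12, length.out = 1200)
  v <- seq(-160, 80, length.out = 1200)
  # readout voltages inside the edge-trimmed span of the hand-built sweep
  lin <- ramp_sweep(tm, v, 0.5 * v, 0.4)       # symmetric linear I-V
  ri <- rectification_index(lin, v_out = 70, v_in = -150)
  expect_equal(ri$index, abs(0.5 * 70) / abs(0.5 * -150), tolerance = 0.05)
  none <- ramp_sweep(tm, v, ifelse(v < 0, 0.5 * v, 0), 0.4)
  expect_equal(rectification_index(none, v_out = 70, v_in = -150)$index, 0,
               tolerance = 1e-12)
  m <- ramp_model()
  sw <- simulate_ramp(m, ca_i = 1000, ca_matrix_mM = 2, seed = 9)
  expect_lt(rectification_index(sw)$index, 0.01)
})
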