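fura_cal <- indicator_calibration(kd = 224, r_min = 0.3, r_max = 3, beta = 1)

test_that("ratiometric calibration obeys its algebra", {
  expect_equal(calibrate_fura(0.3, fura_cal), 0)
  # midpoint ratio: (R - Rmin) = (Rmax - R), so [Ca] = Kd * beta
  expect_equal(calibrate_fura((0.3 + 3) / 2, fura_cal), 224)
  ca <- c(10, 224, 800, 2500)
  cal2 <- indicator_calibration(kd = 224, r_min = 0.3, r_max = 3, beta = 4)
  expect_equal(calibrate_fura(fura_ratio(ca, cal2), cal2), ca, tolerance = 1e-12)
  expect_error(calibrate_fura(3.2, fura_cal), "saturated")
  expect_warning(out <- calibrate_fura(0.2, fura_cal), "clamping")
  expect_equal(out, 0)
})

test_that("single-wavelength calibration obeys its algebra", {
  cal <- indicator_calibration(kd = 0.35, f_min = 10, f_max = 110)
  expect_equal(calibrate_single_wavelength(10, cal), 0)
  expect_equal(calibrate_single_wavelength(60, cal), 0.35)  # midpoint -> Kd
  ca <- c(0.05, 0.35, 2)
  expect_equal(calibrate_single_wavelength(single_wavelength_f(ca, cal), cal),
               ca, tolerance = 1e-12)
})

test_that("free calcium solver matches the closed form and the bisection oracle", {
  expect_equal(solve_free_ca(5, NULL)$free, 5)
  expect_equal(solve_free_ca(0, protocol_buffers(1))$free, 0)
  # one buffer with total equal to total calcium: positive quadratic root
  kd <- 0.5
  B <- 10
  tot <- 10
  root <- (-(B - tot + kd) + sqrt((B - tot + kd)^2 + 4 * kd * tot)) / 2
  got <- solve_free_ca(tot, list(list(name = "b", total = B, kd = kd)))
  expect_equal(got$free, root, tolerance = 1e-9)
  expect_equal(got$free + got$bound[["b"]], tot, tolerance = 1e-9 * tot)

  set.seed(11)
  for (i in 1:100) {
    nb <- sample(1:3, 1)
    totals <- runif(nb, 0.5, 100)
    kds <- exp(runif(nb, log(0.01), log(20)))
    total_ca <- runif(1, 0.01, 150)
    bufs <- lapply(seq_len(nb), function(j)
      list(name = paste0("b", j), total = totals[j], kd = kds[j]))
    res <- solve_free_ca(total_ca, bufs)
    oracle <- bisect_free_ca(total_ca, totals, kds)
    expect_equal(res$free, oracle, tolerance = 1e-9 * max(total_ca, 1))
    expect_equal(res$free + sum(res$bound), total_ca,
                 tolerance = 1e-9 * total_ca)
  }
})

test_that("flux estimation reads exact slopes and rejects short windows", {
  tm <- seq(0, 20, by = 0.2)
  tr <- 10 - 0.2 * tm
  fl <- estimate_flux(tm, tr, protein_mg_ml = 0.5)
  expect_equal(fl$slope_uM_s, -0.2, tolerance = 1e-12)
  expect_equal(fl$J, 0.2 * 1e-6 / 500, tolerance = 1e-12)  # positive into mitochondria
  expect_equal(estimate_flux(tm, rep(4, length(tm)), 0.5)$J, 0)
  expect_error(estimate_flux(tm, tr, 0.5, window = c(0, 0.3)), "fewer than 4")
})

test_that("Nernst potential has the right zeros, decades and signs", {
  expect_equal(nernst_eca(5, 5), 0)
  expect_equal(nernst_eca(10, 1), 29.58, tolerance = 1e-3)          # per decade
  expect_equal(nernst_eca(1, 2), -8.904, tolerance = 1e-3)          # RT/2F ln(1/2)
  expect_equal(nernst_eca(1, 10), -nernst_eca(10, 1))
  expect_error(nernst_eca(0, 1), "positive")
})

test_that("chord conductance follows Faraday arithmetic", {
  expect_equal(chord_conductance(0, -160, 20)$G, 0)
  cc <- chord_conductance(1e-9, -160, 33)
  expect_equal(abs(cc$I), 2 * 96485 * 1e-9, tolerance = 1e-12)
  expect_lt(cc$I, 0)                                   # influx is inward current
  expect_gt(cc$G, 0)
  expect_equal(cc$G, cc$I / ((-160 - 33) / 1000), tolerance = 1e-9)
  expect_error(chord_conductance(1e-9, -20, -20.5), "driving force")
})

test_that("conductance is invariant to consistent unit round trips", {
  # express J in nmol/s/mg instead of mol/s/mg and convert I back
  J <- 2.3e-10
  a <- chord_conductance(J, -160, 25)
  J_nmol <- J * 1e9
  I_nmol <- -2 * 96485 * J_nmol * 1e-9
  expect_equal(a$I, I_nmol, tolerance = 1e-15)
  expect_equal(a$G, I_nmol / ((-160 - 25) / 1000), tolerance = 1e-12)
})

test_that("zero conductance and zero driving force give flat assays", {
  m0 <- flux_model(true_G = 0, noise_frac = 0)
  rec <- simulate_flux_assay(m0, ca_added = 2)
  expect_equal(diff(range(attr(rec, "truth")$total_uM)), 0)
  # set matrix calcium so the Nernst potential equals psi_m
  free0 <- solve_free_ca(2, protocol_buffers(1))$free
  ca_m <- free0 / exp(-160 / (1000 * 8.31446 * 298.15 / (2 * 96485)))
  mz <- flux_model(ca_matrix_nM = ca_m * 1000, psi_m = -160, noise_frac = 0)
  expect_warning(rec2 <- simulate_flux_assay(mz, ca_added = 2), "zero driving force")
  expect_equal(diff(range(attr(rec2, "truth")$total_uM)), 0)
})

test_that("closed-loop conductance recovery and conservation hold", {
  fm <- flux_model(noise_frac = 0)
  rec <- simulate_flux_assay(fm, ca_added = 2, seed = 3)
  tt <- attr(rec, "truth")
  cons <- max(abs(tt$free_uM + rowSums(tt$bound_uM) + tt$uptake_uM -
                    rec$ca_added_uM)) / rec$ca_added_uM
  expect_lt(cons, 1e-9)
  cp <- recover_conductance(rec, fm$indicator, fm$buffers, fm$matrix_fura,
                            fm$protein_mg_ml,
                            tmrm_table = tmrm_calibration_table(fm))
  expect_equal(cp$G_nS, fm$true_G, tolerance = 0.05)
  expect_equal(cp$G, cp$I / ((cp$psi_m - cp$e_ca) / 1000), tolerance = 1e-9)
  # direct psi input instead of the TMRM table gives the same answer
  cp2 <- recover_conductance(rec, fm$indicator, fm$buffers, fm$matrix_fura,
                             fm$protein_mg_ml, psi_m = fm$psi_m)
  expect_equal(cp2$G_nS, cp$G_nS, tolerance = 0.01)
})

test_that("conductance-versus-calcium curves locate a programmed crossover", {
  single <- data.frame(ca_i_uM = 2, G_nS = 5, genotype = "WT")
  out1 <- g_vs_ca_curve(single, breaks = c(1, 4))
  expect_equal(out1$curve$G_mean, 5)

  set.seed(5)
  ca <- rep(exp(seq(log(0.5), log(25), length.out = 8)), each = 6)
  mk <- function(gt) {
    g <- if (gt == "WT") 10 * 2 * ca / (ca + 8) else rep(10, length(ca))
    data.frame(ca_i_uM = ca, G_nS = g * (1 + rnorm(length(ca), 0, 0.03)),
               genotype = gt)
  }
  pts <- rbind(mk("WT"), mk("MICU1KO"))
  out <- g_vs_ca_curve(pts)
  expect_false(is.na(out$crossover_uM))
  expect_gt(out$crossover_uM, 3)
  expect_lt(out$crossover_uM, 20)

  same <- rbind(mk("MICU1KO"),
                transform(mk("MICU1KO"), genotype = "WT"))
  out2 <- g_vs_ca_curve(same)
  curves <- split(out2$curve$G_mean, out2$curve$genotype)
  expect_equal(length(curves), 2)
})

test_that("depolarization index normalizes to the FCCP response", {
  tm <- seq(0, 1500, by = 1)
  step <- function(t0, amp) ifelse(tm >= t0, amp, 0)
  ratio <- 2 + step(100, 0.3) + step(700, 0.3)   # event then FCCP
  out <- depolarization_index(tm, ratio, event_time = 100, fccp_time = 700)
  expect_equal(out$percent_of_fccp, 100)
  ratio2 <- 2 + step(700, 0.6)
  out2 <- depolarization_index(tm, ratio2, event_time = 100, fccp_time = 700)
  expect_equal(out2$percent_of_fccp, 0)
  ratio3 <- 2 + step(100, 0.3) + step(700, 0.6)
  out3 <- depolarization_index(tm, ratio3, event_time = 100, fccp_time = 700)
  expect_equal(out3$percent_of_fccp, 50)
})
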