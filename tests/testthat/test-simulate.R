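test_that("identical seeds give bit-identical screens, different seeds differ", {
  cfg <- screen_sim_config(n_compounds = 40, seed = 11)
  a <- simulate_screen(cfg)
  b <- simulate_screen(cfg)
  expect_identical(a$wells, b$wells)
  expect_identical(a$truth$compounds, b$truth$compounds)
  c <- simulate_screen(screen_sim_config(n_compounds = 40, seed = 12))
  expect_false(identical(a$wells$signal, c$wells$signal))
  # truth structure (dimensions, planted set) is seed-invariant
  expect_identical(dim(a$truth$compounds), dim(c$truth$compounds))
  expect_identical(a$truth$compounds$is_planted, c$truth$compounds$is_planted)
})

test_that("with no Bliss excess the true SI is 1 - fa_cpd to machine precision", {
  sim <- simulate_screen(screen_sim_config(
    n_compounds = 60, hit_indices = integer(0), bliss_excess = 0,
    noise_sd = 0, seed = 3
  ))
  tr <- sim$truth$compounds
  expect_equal(tr$si_E, 1 - tr$fa_cpd, tolerance = 1e-14)
  expect_equal(tr$si_R, 1 - tr$fa_cpd, tolerance = 1e-14)
  expect_false(any(tr$is_hit))
})

test_that("compounds with zero single-agent effect give fa_comb = fa_inducer and SI = 1", {
  sim <- simulate_screen(screen_sim_config(
    n_compounds = 5, hit_indices = integer(0), bliss_excess = 0,
    fa_cpd_range = c(0, 0), noise_sd = 0, seed = 1
  ))
  tr <- sim$truth$compounds
  expect_equal(tr$fa_comb_E, rep(0.3, 5))
  expect_equal(tr$si_E, rep(1, 5))
  expect_equal(tr$si_R, rep(1, 5))
})

test_that("reference config plants exactly 10 truth hits and emits full well plan", {
  cfg <- screen_sim_config(seed = 1)  # 303 compounds, 10 hits, 3 replicates
  sim <- simulate_screen(cfg)
  expect_identical(sum(sim$truth$compounds$is_hit), 10L)
  expect_identical(
    sim$truth$compounds$compound_id[sim$truth$compounds$is_hit],
    sprintf("CPD_%03d", cfg$hit_indices)
  )
  # wells: (3 arms x 303 compounds + 2 inducers) x 3 reps + 16 controls/plate
  n_cond <- (3 * 303 + 2) * 3
  n_plates <- ceiling(n_cond / 80)
  expect_equal(nrow(sim$wells), n_cond + 16 * n_plates)
  expect_setequal(unique(sim$wells$arm),
                  c("vehicle", "blank", "cpd", "inducer_E", "inducer_R",
                    "combo_E", "combo_R"))
  # every plate carries its own controls
  ctrl <- table(sim$wells$plate[sim$wells$arm %in% c("vehicle", "blank")])
  expect_true(all(ctrl == 16L))
})

test_that("configs whose planted hits cannot reach SI > 1 are rejected", {
  expect_error(
    simulate_screen(screen_sim_config(n_compounds = 20, hit_indices = 1:3,
                                      bliss_excess = 0, noise_sd = 0, seed = 1)),
    class = "unusable_ground_truth"
  )
})

test_that("noiseless emitted signals equal the model values exactly", {
  cfg <- screen_sim_config(n_compounds = 15, noise_sd = 0, seed = 4)
  sim <- simulate_screen(cfg)
  w <- sim$wells
  expect_equal(w$signal[w$arm == "vehicle"], rep(cfg$vehicle_signal, 16))
  expect_equal(w$signal[w$arm == "blank"], rep(cfg$blank_signal, 16))
  tr <- sim$truth$compounds
  span <- cfg$vehicle_signal - cfg$blank_signal
  cpd1 <- w$signal[!is.na(w$compound_id) & w$compound_id == "CPD_001" & w$arm == "cpd"]
  expect_equal(cpd1, rep((1 - tr$fa_cpd[1]) * span + cfg$blank_signal, 3))
})

test_that("dose-response simulation follows the median-effect curve", {
  p <- median_effect_params(Dm = 2, m = 1)
  expect_equal(simulate_dose_response(p, 2)$fa, 0.5)
  expect_equal(simulate_dose_response(p, 8)$fa, 0.8)
  expect_equal(simulate_dose_response(median_effect_params(1, 2), 3)$fa, 0.9)
  expect_error(simulate_dose_response(p, c(1, -2)), class = "invalid_dose")
  expect_error(simulate_dose_response(p, 0), class = "invalid_dose")
  # noise is seed-reproducible and clipped to [0, 1]
  s1 <- simulate_dose_response(p, rep(2, 200), noise_sd = 0.4, seed = 9)
  s2 <- simulate_dose_response(p, rep(2, 200), noise_sd = 0.4, seed = 9)
  expect_identical(s1, s2)
  expect_true(all(s1$fa >= 0 & s1$fa <= 1))
})

test_that("combo matrix encodes the potency shift against the Loewe reference", {
  p <- median_effect_params(2, 1.5)
  sham <- simulate_combo_matrix(p, p, potency_shift = 1)
  expect_equal(sham$truth$Dm_combo, 2)       # self-combination reference = Dm
  half <- simulate_combo_matrix(p, p, potency_shift = 0.5)
  expect_equal(half$truth$Dm_combo, 1)
  uneq <- simulate_combo_matrix(median_effect_params(2, 1.5),
                                median_effect_params(8, 1.5))
  expect_equal(uneq$truth$Dm_ref, 1 / (0.5 / 2 + 0.5 / 8))
  expect_error(simulate_combo_matrix(p, p, potency_shift = 0),
               class = "invalid_argument")
  expect_error(simulate_combo_matrix(p, p, ratio = c(0.7, 0.6)),
               class = "invalid_argument")
})

test_that("xenograft trajectories reproduce exponential growth and truth TGI", {
  cfg <- xeno_sim_config(groups = c(vehicle = 0.1, treated = 0.04),
                         caliper_noise_sd = 0, seed = 2)
  sim <- simulate_xenograft(cfg)
  tr <- sim$trajectories
  expect_true(all(tr$L_mm >= tr$S_mm))
  expect_true(all(tr$S_mm > 0))
  # noiseless volumes follow V(t) = v0 exp(g t) under the fixed aspect ratio
  v <- tumor_volume(tr$L_mm, tr$S_mm)
  expect_equal(v[tr$group == "vehicle"],
               100 * exp(0.1 * tr$day[tr$group == "vehicle"]), tolerance = 1e-10)
  expect_equal(sim$truth$groups$tgi_percent, true_tgi(0.1, 0.04, 28))
  # identical growth rates: true TGI 0; stasis: true TGI 100
  same <- simulate_xenograft(xeno_sim_config(groups = c(a = 0.1, b = 0.1), seed = 1))
  expect_equal(same$truth$groups$tgi_percent, 0)
  stasis <- simulate_xenograft(xeno_sim_config(groups = c(a = 0.1, b = 0), seed = 1))
  expect_equal(stasis$truth$groups$tgi_percent, 100)
})
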