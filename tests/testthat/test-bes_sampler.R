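small_config <- function(...) {
  excursion_config(n_chains = 2L, blocks_per_chain = 2L,
                   sa_max_temperatures = c(700, 500),
                   sa_duration_steps = 40L, relax_duration_steps = 30L,
                   representative_window_steps = 24L, seed = 7L, ...)
}

test_that("energy model gradients agree with finite differences", {
  xyz <- coords(make_toy_peptide(8, "random", seed = 3))
  expect_lt(check_gradient(bead_chain_model(8), xyz), 1e-4)
  expect_lt(check_gradient(harmonic_well_model(2, c(1, -1, 0)), xyz), 1e-4)
  # and at a second, compact configuration
  xyz2 <- coords(make_toy_peptide(8, "collapsed", seed = 5))
  expect_lt(check_gradient(bead_chain_model(8), xyz2), 1e-4)
})

test_that("annealing a harmonic well to ~0 K lands at the minimum", {
  model <- harmonic_well_model(k = 5, center = c(2, -1, 3))
  start <- random_structure(4, seed = 1, spread = 6)
  cfg <- excursion_config(n_chains = 1L, blocks_per_chain = 1L,
                          sa_max_temperatures = 500,
                          sa_duration_steps = 800L,
                          relax_duration_steps = 10L,
                          representative_window_steps = 5L,
                          base_temperature = 1e-4, seed = 1L)
  out <- run_sa_block(start, model, t_max = 500, cfg, seed = 3L)
  expect_lt(max(abs(sweep(coords(out), 2, c(2, -1, 3)))), 0.5)
  expect_lt(model$energy(coords(out)), model$energy(coords(start)))
})

test_that("SA and relaxation blocks are deterministic given the seed", {
  model <- bead_chain_model(5)
  start <- make_toy_peptide(5, "extended")
  cfg <- small_config()
  a <- run_sa_block(start, model, 700, cfg, seed = 42L)
  b <- run_sa_block(start, model, 700, cfg, seed = 42L)
  expect_identical(coords(a), coords(b))
  c <- run_sa_block(start, model, 700, cfg, seed = 43L)
  expect_gt(max(abs(coords(a) - coords(c))), 0)
  ta <- run_relaxation_block(start, model, cfg, seed = 1L)
  tb <- run_relaxation_block(start, model, cfg, seed = 1L)
  expect_identical(ta$xyz, tb$xyz)
})

test_that("annealing lowers the energy for most seeds on the toy chain", {
  model <- bead_chain_model(5)
  start <- make_toy_peptide(5, "random", seed = 99)
  cfg <- excursion_config(n_chains = 1L, blocks_per_chain = 1L,
                          sa_max_temperatures = 700,
                          sa_duration_steps = 1000L,
                          relax_duration_steps = 10L,
                          representative_window_steps = 5L,
                          base_temperature = 5, seed = 1L)
  e0 <- model$energy(coords(start))
  lowered <- vapply(1:50, function(s) {
    model$energy(coords(run_sa_block(start, model, 700, cfg, seed = s))) < e0
  }, logical(1))
  expect_gt(mean(lowered), 0.9)
})

test_that("relaxation records floor(duration/stride) frames", {
  model <- bead_chain_model(5)
  start <- make_toy_peptide(5, "extended")
  cfg <- excursion_config(n_chains = 1L, blocks_per_chain = 1L,
                          sa_max_temperatures = 700,
                          relax_duration_steps = 25L, stride = 4L,
                          representative_window_steps = 6L, seed = 1L)
  traj <- run_relaxation_block(start, model, cfg, seed = 2L)
  expect_equal(n_frames(traj), 6L)  # floor(25/4)
  expect_length(attr(traj, "energies"), 6L)
})

test_that("relaxation energy variance grows with temperature", {
  model <- harmonic_well_model(k = 2)
  start <- random_structure(3, seed = 2, spread = 1)
  var_at <- function(temp) {
    cfg <- excursion_config(n_chains = 1L, blocks_per_chain = 1L,
                            sa_max_temperatures = temp + 1,
                            relax_duration_steps = 150L,
                            representative_window_steps = 100L,
                            base_temperature = temp, seed = 1L)
    mean(vapply(1:20, function(s)
      stats::var(attr(run_relaxation_block(start, model, cfg, seed = s),
                      "energies")), numeric(1)))
  }
  v <- vapply(c(50, 300, 900), var_at, numeric(1))
  expect_true(v[1] < v[2] && v[2] < v[3])
})

test_that("representative selection matches a brute-force argmin scan", {
  model <- bead_chain_model(6)
  start <- make_toy_peptide(6, "extended")
  cfg <- small_config()
  traj <- run_relaxation_block(start, model, cfg, seed = 5L)
  window <- 24L
  rec <- select_representative(traj, window, model)
  # oracle: superpose window frames on the first window frame, scan all
  nf <- n_frames(traj)
  idx <- (nf - window + 1L):nf
  ref <- traj$xyz[[idx[1]]]
  fitted <- lapply(idx, function(i) kabsch_fit(traj$xyz[[i]], ref)$xyz)
  mean_xyz <- Reduce(`+`, fitted) / length(fitted)
  or <- vapply(fitted, function(f) sqrt(mean(rowSums((f - mean_xyz)^2))),
               numeric(1))
  expect_equal(rec$frame_index, idx[which.min(or)])
  expect_equal(rec$rmsd_to_mean, min(or))
  # minimiser contract
  expect_lte(rec$minimized_energy,
             model$energy(traj$xyz[[rec$frame_index]]) + 1e-9)
})

test_that("identical frames give rmsd 0 and the first window frame", {
  start <- make_toy_peptide(5, "extended")
  traj <- ens_trajectory(start, replicate(10, coords(start),
                                          simplify = FALSE))
  rec <- select_representative(traj, 6L, bead_chain_model(5))
  expect_equal(rec$frame_index, 5L)
  expect_equal(rec$rmsd_to_mean, 0)
  expect_error(select_representative(traj, 0L, bead_chain_model(5)), "window")
})

test_that("conjugate-gradient minimisation solves a quadratic exactly", {
  model <- harmonic_well_model(k = 3, center = c(1, 2, 3))
  start <- random_structure(5, seed = 8, spread = 4)
  traj <- ens_trajectory(start, list(coords(start)))
  rec <- select_representative(traj, 1L, model, minimize_maxit = 200L)
  expect_lt(rec$minimized_energy, 1e-6)
})

test_that("an excursion chain yields one representative per block", {
  model <- bead_chain_model(5)
  start <- make_toy_peptide(5, "extended")
  recs <- run_excursion_chain(start, model, small_config(), 1L)
  expect_length(recs, 2L)
  expect_equal(vapply(recs, `[[`, integer(1), "block_index"), 1:2)
  one <- excursion_config(n_chains = 1L, blocks_per_chain = 1L,
                          sa_max_temperatures = 700,
                          sa_duration_steps = 20L,
                          relax_duration_steps = 12L,
                          representative_window_steps = 10L, seed = 2L)
  expect_length(run_excursion_chain(start, model, one, 1L), 1L)
})

test_that("different chains explore distinct conformations", {
  model <- bead_chain_model(6)
  start <- make_toy_peptide(6, "extended")
  cfg <- small_config()
  r1 <- run_excursion_chain(start, model, cfg, 1L)
  r2 <- run_excursion_chain(start, model, cfg, 2L)
  rms <- kabsch_rmsd(coords(r1[[1]]$structure), coords(r2[[1]]$structure))
  expect_gt(rms, 0)
})

test_that("library size is n_chains x blocks_per_chain with unique ids", {
  model <- bead_chain_model(5)
  start <- make_toy_peptide(5, "extended")
  cfg <- excursion_config(n_chains = 4L, blocks_per_chain = 5L,
                          sa_duration_steps = 15L, relax_duration_steps = 12L,
                          representative_window_steps = 10L, seed = 3L)
  lib <- build_library(model, cfg, start)
  expect_equal(nrow(lib$manifest), 20L)
  expect_equal(anyDuplicated(lib$manifest[, c("chain", "block")]), 0L)
  expect_equal(sort(unique(lib$manifest$chain)), 1:4)
})

test_that("library manifests are byte-identical across repeated runs", {
  model <- bead_chain_model(5)
  start <- make_toy_peptide(5, "extended")
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_library(build_library(model, cfg, start), d1,
                      write_structures = FALSE)
  m2 <- write_library(build_library(model, cfg, start), d2,
                      write_structures = FALSE)
  expect_identical(readLines(m1), readLines(m2))
})

test_that("config validation rejects inconsistent block settings", {
  expect_error(excursion_config(blocks_per_chain = 3L,
                                sa_max_temperatures = c(700, 600)),
               "temperature")
  expect_error(excursion_config(relax_duration_steps = 10L,
                                representative_window_steps = 20L),
               "window")
  expect_error(excursion_config(sa_max_temperatures =
                                  c(700, 600, 500, 400, 200)),
               "base temperature")
})

test_that("non-finite energies abort with a diagnostic", {
  bad <- list(energy = function(xyz) Inf,
              gradient = function(xyz) matrix(Inf, nrow(xyz), 3),
              label = "bad")
  start <- make_toy_peptide(4, "extended")
  expect_error(run_sa_block(start, bad, 700, small_config(), seed = 1L),
               "non-finite")
})
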