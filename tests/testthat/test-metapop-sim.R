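test_that("season growth follows the public-good growth law", {
  # no public good, no growth
  p0 <- patch_state(1, tibble::tibble(strain = "cheat", x = 0, density = 1e6))
  expect_equal(season_growth(p0)$strains$density, 1e6)

  # a cheat sharing a patch with a producer always gains frequency
  p <- default_pair_patch(R = 3.75)
  out <- season_growth(p)$strains
  f_cheat <- out$density[2] / sum(out$density)
  expect_gt(f_cheat, 0.5)

  # pure producer densities increase strictly with resource level
  dens <- vapply(c(1.5, 3.75, 6), function(R) {
    p <- patch_state(R, tibble::tibble(strain = "cooperator", x = 0.19,
                                       density = 1e6))
    sum(season_growth(p)$strains$density)
  }, numeric(1))
  expect_true(all(diff(dens) > 0))

  expect_error(
    season_growth(patch_state(1, tibble::tibble(strain = "a", x = 0,
                                                density = 0))),
    "inoculum")
})

test_that("lower investment never loses frequency within a shared patch", {
  withr::with_seed(41, {
    for (i in 1:10) {
      R <- runif(1, 1, 8)
      x <- sort(runif(2, 0, 0.4))         # x[1] < x[2]
      f <- runif(1, 0.1, 0.9)
      p <- patch_state(R, tibble::tibble(
        strain = c("low", "high"), x = x, density = 1e6 * c(f, 1 - f)))
      out <- season_growth(p)$strains
      expect_gte(out$density[1] / sum(out$density), f - 1e-12)
    }
  })
})

test_that("halving the integration step barely moves end-of-season frequencies", {
  p <- default_pair_patch(R = 3.75)
  f_end <- function(steps) {
    out <- season_growth(p, season_params(steps = steps))$strains
    out$density[1] / sum(out$density)
  }
  expect_lt(abs(f_end(480L) - f_end(960L)), 1e-4)
})

test_that("pooled transfer mixes by density under hard and equalizes under soft", {
  mk <- function(R, coop, cheat) {
    p <- patch_state(R, tibble::tibble(strain = c("cooperator", "cheat"),
                                       x = c(0.19, 0),
                                       density = c(coop, cheat)))
    p$season_time <- 1
    p
  }
  plan <- transfer_plan("hard", bottleneck = 0.01)
  a <- mk(6, 9e9, 0); b <- mk(1.5, 0, 1e9)

  fresh <- pooled_transfer(list(a, b), plan)
  f <- fresh[[1]]$strains$density
  expect_equal(f[1] / sum(f), 0.9)
  expect_equal(sum(f), 5e9 * 0.01)
  expect_identical(fresh[[1]]$strains$density, fresh[[2]]$strains$density)
  expect_equal(fresh[[1]]$R, 6)
  expect_equal(fresh[[2]]$R, 1.5)

  soft <- pooled_transfer(list(a, b), transfer_plan("soft"))
  fs <- soft[[1]]$strains$density
  expect_equal(fs[1] / sum(fs), 0.5)

  # two identical patches: pooling mode cannot matter
  c1 <- mk(3, 2e9, 1e9); c2 <- mk(3, 2e9, 1e9)
  h <- pooled_transfer(list(c1, c2), transfer_plan("hard"))
  s <- pooled_transfer(list(c1, c2), transfer_plan("soft"))
  expect_identical(h[[1]]$strains$density, s[[1]]$strains$density)

  # composition of the pool is conserved exactly (deterministic mode)
  mixed <- pooled_transfer(list(mk(6, 7e8, 3e8), mk(1.5, 1e8, 4e8)), plan)
  pool <- (c(7e8, 3e8) + c(1e8, 4e8)) / 2
  expect_equal(mixed[[1]]$strains$density / sum(mixed[[1]]$strains$density),
               pool / sum(pool))

  z1 <- mk(6, 0, 0); z2 <- mk(1.5, 0, 0)
  expect_error(pooled_transfer(list(z1, z2), plan), "Zero pool")
})

test_that("multinomial founder sampling is reproducible and conserves totals", {
  mk <- function(R, coop, cheat) {
    p <- patch_state(R, tibble::tibble(strain = c("cooperator", "cheat"),
                                       x = c(0.19, 0),
                                       density = c(coop, cheat)))
    p$season_time <- 1
    p
  }
  pair <- list(mk(6, 5e8, 5e8), mk(1.5, 2e8, 8e8))
  plan <- transfer_plan("hard")
  d1 <- withr::with_seed(5, pooled_transfer(pair, plan, rng = TRUE))
  d2 <- withr::with_seed(5, pooled_transfer(pair, plan, rng = TRUE))
  expect_identical(d1[[1]]$strains$density, d2[[1]]$strains$density)
  # sampled founder total matches the deterministic bottleneck count
  det <- pooled_transfer(pair, plan)
  expect_equal(sum(d1[[1]]$strains$density), sum(det[[1]]$strains$density),
               tolerance = 1e-6)
})

test_that("experiment trajectories are deterministic given the seed", {
  des <- synthetic_design(replicates = 2L)
  cfg <- gen_metapop_config(des, "heterogeneous", n_transfers = 2L,
                            stochastic = TRUE, n_replicates = 2L)
  t1 <- run_metapopulation_experiment(cfg, seed = 42)
  t2 <- run_metapopulation_experiment(cfg, seed = 42)
  t3 <- run_metapopulation_experiment(cfg, seed = 43)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
  expect_error(run_metapopulation_experiment(cfg), "seed")
})

test_that("hard and soft pooling coincide exactly when all patches share one R", {
  des <- synthetic_design(replicates = 3L)
  runs <- lapply(c("hard", "soft"), function(p) {
    cfg <- gen_metapop_config(des, "homogeneous", pooling = p,
                              n_transfers = 3L)
    run_metapopulation_experiment(cfg)
  })
  expect_identical(runs[[1]]$density, runs[[2]]$density)
})

test_that("a lone strain with no mutation stays at frequency one", {
  des <- synthetic_design(replicates = 1L)
  cfg <- gen_metapop_config(des, "heterogeneous", n_transfers = 3L,
                            evolution = TRUE, mu = 0)
  traj <- run_metapopulation_experiment(cfg)
  fr <- metapop_frequency(traj)
  expect_true(all(fr$frequency == 1))
})

test_that("heterogeneous pairs show the productivity-cooperation covariance", {
  des <- synthetic_design(replicates = 1L)
  cfg <- gen_metapop_config(des, "heterogeneous", n_transfers = 1L)
  traj <- run_metapopulation_experiment(cfg)
  season1 <- traj |>
    dplyr::filter(.data$transfer == 1) |>
    dplyr::group_by(.data$patch_id, .data$R) |>
    dplyr::summarise(
      total = sum(.data$density),
      W = malthusian(5e5, .data$density[.data$strain == "cooperator"]) /
        malthusian(5e5, .data$density[.data$strain == "cheat"]),
      .groups = "drop") |>
    dplyr::arrange(.data$R)
  # the high-R patch ends both denser and with relatively fitter cooperators
  expect_gt(season1$total[2], season1$total[1])
  expect_gt(season1$W[2], season1$W[1])
  expect_true(all(season1$W < 1))
})

test_that("trait substitution walks to the analytic ESS", {
  d1 <- resource_atoms(1)
  run <- trait_substitution_run(d1, trait_model(1), "soft", z0 = 0,
                                step = 0.01)
  expect_lt(abs(run$z_final - 0.5), 0.01 + 1e-12)
  expect_identical(run$trajectory$z[1], 0)
  expect_identical(run$trajectory$z[nrow(run$trajectory)], run$z_final)

  d <- resource_atoms(c(0.5, 1.5))
  hard <- trait_substitution_run(d, trait_model(1), "hard", step = 0.005)
  expect_lt(abs(hard$z_final - ess_solve(d, trait_model(1), "hard")$z_star),
            0.005 + 1e-12)

  # no relatedness: cooperation collapses to zero from any start
  none <- trait_substitution_run(d, trait_model(0), "hard", z0 = 0.4,
                                 step = 0.01)
  expect_equal(none$z_final, 0, tolerance = 1e-12)

  err <- tryCatch(
    trait_substitution_run(d1, trait_model(1), "soft", z0 = 0, step = 0.001,
                           max_iter = 5L),
    coopscape_nonconvergence = function(e) e
  )
  expect_s3_class(err, "coopscape_nonconvergence")
  expect_identical(nrow(err$trajectory), 6L)
})
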