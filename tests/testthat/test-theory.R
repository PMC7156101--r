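test_that("growth rate, fitness and gradient follow the model's closed forms", {
  expect_identical(growth_rate(R = 1, y = 0, x = 0), 0)
  expect_identical(growth_rate(R = 2, y = 1, x = 1), 1)
  expect_equal(growth_rate(R = 4, y = 1, x = 0, a = 0.5), 2)

  expect_identical(fitness(R = 1, y = 0, x = 0), 1)
  expect_identical(fitness(R = 1, y = 1, x = 1), 1)
  expect_equal(fitness(R = 3, y = 1, x = 1), exp(2))
  expect_equal(mean_fitness(R = 2, z = 0.3), exp(2 * 0.3 - 0.09))

  expect_identical(selection_gradient(R = 1, r = 1, z = 0.5), 0)
  expect_identical(selection_gradient(R = 2, r = 0.5, z = 0), 1)
  expect_equal(selection_gradient(R = 4, r = 1, z = 1, a = 0.5), 0)

  expect_error(growth_rate(R = -1, y = 0, x = 0), "positive")
  expect_error(growth_rate(R = 1, y = 0, x = 0, a = 0), "positive")
  expect_error(selection_gradient(R = 1, r = 1.2, z = 0), "\\[0, 1\\]")
  expect_error(trait_model(r = -0.1), "\\[0, 1\\]")
})

test_that("the single-patch gradient vanishes exactly at z* = r R^a / 2", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      R <- runif(1, 0.01, 50)
      r <- runif(1)
      a <- sample(c(1, runif(1, 0.2, 3)), 1)
      fit <- single_patch_ess(R, r, a)
      expect_identical(selection_gradient(R, r, fit$z_star, a), 0)
      expect_identical(fit$method, "closed_form")
    }
  })
  expect_equal(single_patch_ess(1, 1)$z_star, 0.5)
  expect_equal(single_patch_ess(2, 0)$z_star, 0)
  expect_equal(single_patch_ess(9, 0.4, a = 0.5)$z_star, 0.6)
})

test_that("resource distributions validate support and report exact moments", {
  d <- resource_atoms(c(1, 2, 4), c(0.5, 0.3, 0.2))
  expect_equal(d$mean, 0.5 + 0.6 + 0.8)
  expect_equal(d$variance, sum(c(0.5, 0.3, 0.2) * (c(1, 2, 4) - d$mean)^2))

  u <- resource_uniform(0.5, 1.5)
  expect_equal(u$mean, 1, tolerance = 1e-9)
  expect_equal(u$variance, 1 / 12, tolerance = 1e-9)

  expect_error(resource_atoms(c(-1, 2)), "positive")
  expect_error(resource_atoms(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(resource_density(function(R) rep(2, length(R)), 1, 2),
               "integrate to 1")
})

test_that("metapopulation gradient matches a literal weighted-sum oracle", {
  d1 <- resource_atoms(1)
  m <- trait_model(r = 1)
  # degenerate metapopulation reduces to the single patch in both regimes
  expect_equal(metapop_gradient(d1, m, 0.5, "soft"), 0)
  expect_equal(metapop_gradient(d1, m, 0.5, "hard"), 0)

  d <- resource_atoms(c(0.5, 1.5))
  expect_equal(metapop_gradient(d, m, 0, "soft"), 1)
  expect_gt(metapop_gradient(d, m, 0.5, "hard"), 0)

  withr::with_seed(21, {
    for (i in 1:20) {
      ra <- random_atoms()
      r <- runif(1); a <- runif(1, 0.3, 2.5); z <- runif(1, 0, 1.5)
      for (regime in c("soft", "hard")) {
        expect_equal(
          metapop_gradient(ra$dist, trait_model(r, a), z, regime),
          brute_gradient(ra$R, ra$w, r, a, z, regime),
          tolerance = 1e-12
        )
      }
    }
  })
})

test_that("quadrature over a continuous density agrees with a fine discretisation", {
  m <- trait_model(r = 0.8)
  u <- resource_uniform(0.5, 1.5)
  R <- seq(0.5 + 0.5e-4, 1.5 - 0.5e-4, length.out = 1e4)
  approx <- resource_atoms(R, rep(1 / length(R), length(R)))
  for (z in c(0, 0.3, 0.6)) {
    expect_equal(metapop_gradient(u, m, z, "hard"),
                 metapop_gradient(approx, m, z, "hard"), tolerance = 1e-6)
  }
})

test_that("soft-selection ESS equals mean-resource closed form; hard exceeds it", {
  m <- trait_model(r = 1)
  d <- resource_atoms(c(0.5, 1.5))
  soft <- ess_solve(d, m, "soft")
  hard <- ess_solve(d, m, "hard")
  expect_equal(soft$z_star, 0.5, tolerance = 1e-10)
  expect_gt(hard$z_star, 0.5)
  expect_lte(abs(hard$residual_gradient), 1e-10)
  expect_identical(hard$method, "numeric_root")
  # grid-scan oracle for the hard root
  expect_equal(hard$z_star, brute_ess(c(0.5, 1.5), c(0.5, 0.5), 1, 1, "hard"),
               tolerance = 1e-4)
  # degenerate distribution reduces to the single-patch closed form
  expect_equal(ess_solve(resource_atoms(2), trait_model(0.5), "hard")$z_star,
               0.5, tolerance = 1e-10)
  # r = 0: no relatedness, no cooperation
  expect_equal(ess_solve(d, trait_model(0), "hard")$z_star, 0)
})

test_that("first-order approximations reproduce the printed expansions", {
  m <- trait_model(r = 1)
  expect_equal(ess_approx(1, 0, m, "hard")$z_star, 0.5)
  expect_equal(ess_approx(1, 0.25, m, "hard")$z_star, 0.5625)
  # heterogeneity has no first-order impact under soft selection when a = 1
  expect_equal(ess_approx(1, 0.25, m, "soft")$z_star, 0.5)
  withr::with_seed(31, {
    for (i in 1:50) {
      Rm <- runif(1, 0.5, 3); Rv <- runif(1, 0, 0.5); r <- runif(1)
      a <- runif(1, 0.3, 2.5)
      mod <- trait_model(r, a)
      expect_equal(ess_approx(Rm, Rv, mod, "soft")$z_star,
                   (r * Rm^a / 2) * (1 + 0.5 * a * (a - 1) * Rv / Rm^2))
      expect_equal(ess_approx(Rm, Rv, mod, "hard")$z_star,
                   (r * Rm^a / 2) *
                     (1 + a * (a - 1 + a * r * Rm^(2 * a)) * Rv / (2 * Rm^2)))
      # a = 1 reductions
      expect_equal(ess_approx(Rm, Rv, trait_model(r), "hard")$z_star,
                   (Rm * r / 2) * (1 + r * Rv / 2))
      expect_equal(ess_approx(Rm, Rv, trait_model(r), "soft")$z_star,
                   Rm * r / 2)
    }
  })
})

test_that("numeric-vs-approximate ESS error shrinks at fourth order in sigma", {
  m <- trait_model(r = 0.8)
  err <- function(s) {
    d <- resource_atoms(c(1 - s, 1 + s))
    abs(ess_solve(d, m, "hard")$z_star - ess_approx(1, s^2, m, "hard")$z_star)
  }
  ratio <- err(0.2) / err(0.1)
  expect_gte(ratio, 4)
  expect_lte(ratio, 64)
})

test_that("soft ESS under nonlinearity follows Jensen's direction", {
  d <- resource_atoms(c(0.5, 1.5))
  r <- 0.9
  conc <- ess_solve(d, trait_model(r, a = 0.5), "soft")$z_star
  conv <- ess_solve(d, trait_model(r, a = 2), "soft")$z_star
  expect_lt(conc, single_patch_ess(1, r, a = 0.5)$z_star)
  expect_gt(conv, single_patch_ess(1, r, a = 2)$z_star)
})

test_that("ess fits tidy into one-row tibbles", {
  fit <- ess_solve(resource_atoms(c(0.5, 1.5)), trait_model(1), "hard")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_identical(nrow(td), 1L)
  expect_named(td, c("z_star", "method", "regime", "residual_gradient",
                     "r", "a", "R_mean", "R_var"))
  expect_identical(glance(fit), td)
})

test_that("solver rejects brackets without a sign change", {
  d <- resource_atoms(c(0.5, 1.5))
  expect_error(ess_solve(d, trait_model(1), "hard", bracket = c(0, 0.1)),
               "sign")
  expect_error(metapop_gradient(d, trait_model(1), 0.5, "medium"), "soft")
})
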