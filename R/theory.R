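#' Trait model for siderophore investment
#'
#' Bundles the two exogenous parameters of the kin-selection model: the
#' relatedness coefficient `r` (the regression slope of neighbours'
#' siderophore availability on the focal cell's own investment, `dy/dx`) and
#' the resource exponent `a` governing how growth scales with resources
#' (`a < 1` diminishing returns, `a = 1` linear, `a > 1` accelerating).
#'
#' @param r Relatedness, in `[0, 1]`.
#' @param a Resource exponent, `> 0`. Default 1 (linear returns).
#' @return A `trait_model` object (list with `r`, `a`).
#' @examples
#' trait_model(r = 0.5)
#' trait_model(r = 1, a = 0.5)
#' @export
trait_model <- function(r, a = 1) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < 0 || r > 1) {
    abort("Relatedness `r` must be a single number in [0, 1].")
  }
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0) {
    abort("Resource exponent `a` must be a single positive number.")
  }
  structure(list(r = r, a = a), class = "trait_model")
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf("<trait_model: r = %g, a = %g>\n", x$r, x$a))
  invisible(x)
}

.check_regime <- function(regime) {
  if (!is.character(regime) || length(regime) != 1 ||
      !regime %in% c("soft", "hard")) {
    abort('`regime` must be exactly one of "soft" or "hard".')
  }
  regime
}

.check_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be strictly positive.", name))
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be non-negative.", name))
  }
  invisible(x)
}

#' Basic growth rate of a focal cell
#'
#' The model's growth law: a cell growing in a patch with resource level `R`,
#' experiencing siderophore availability `y` (the average production of its
#' neighbours) and itself investing `x`, has basic rate
#' `gamma = R^a * y - x^2`. Benefit is proportional to both resources and
#' public-good availability; cost of production accelerates quadratically.
#'
#' @param R Resource level, `> 0`. Vectorised.
#' @param y Siderophore availability, `>= 0`.
#' @param x Focal investment, `>= 0`.
#' @param a Resource exponent, `> 0`.
#' @return `R^a * y - x^2` (may be negative).
#' @examples
#' growth_rate(R = 2, y = 1, x = 1)      # 1
#' growth_rate(R = 4, y = 1, x = 0, a = 0.5)  # 2
#' @export
growth_rate <- function(R, y, x, a = 1) {
  .check_pos(R, "R"); .check_pos(a, "a")
  .check_nonneg(y, "y"); .check_nonneg(x, "x")
  R^a * y - x^2
}

#' Absolute fitness of a focal cell
#'
#' `w_R = exp(growth_rate(R, y, x, a))`: always strictly positive.
#'
#' @inheritParams growth_rate
#' @return `exp(R^a * y - x^2)`.
#' @examples
#' fitness(R = 3, y = 1, x = 1)  # exp(2)
#' @export
fitness <- function(R, y, x, a = 1) {
  exp(growth_rate(R, y, x, a))
}

#' Mean fitness of a monomorphic patch
#'
#' With all residents investing `z` (so `y = z`, `x = z`):
#' `wbar_R = exp(R^a * z - z^2)`.
#'
#' @inheritParams growth_rate
#' @param z Resident investment, `>= 0`.
#' @export
mean_fitness <- function(R, z, a = 1) {
  fitness(R, y = z, x = z, a = a)
}

#' Marginal relative-fitness (selection) gradient in a single patch
#'
#' The kin-selection gradient of relative fitness with respect to investment,
#' evaluated at a monomorphic resident `z`:
#' `dW_R/dx |_(x=y=z) = R^a * r - 2z`. A positive value means selection
#' favours more siderophore production.
#'
#' @inheritParams growth_rate
#' @param r Relatedness in `[0, 1]`.
#' @param z Resident investment, `>= 0`.
#' @return `R^a * r - 2 * z`.
#' @examples
#' selection_gradient(R = 1, r = 1, z = 0.5)  # 0 at the ESS
#' @export
selection_gradient <- function(R, r, z, a = 1) {
  .check_pos(R, "R"); .check_pos(a, "a"); .check_nonneg(z, "z")
  if (any(r < 0) || any(r > 1)) abort("`r` must lie in [0, 1].")
  R^a * r - 2 * z
}

.new_ess_fit <- function(z_star, method, residual, regime = NA_character_,
                         r = NA_real_, a = NA_real_,
                         R_mean = NA_real_, R_var = NA_real_) {
  structure(
    list(z_star = z_star, method = method, residual_gradient = residual,
         regime = regime, r = r, a = a, R_mean = R_mean, R_var = R_var),
    class = "ess_fit"
  )
}

#' Closed-form ESS investment in a single patch
#'
#' The selection gradient `R^a r - 2z` vanishes at `z* = r R^a / 2`, the
#' evolutionarily stable siderophore investment for an isolated population.
#'
#' @inheritParams selection_gradient
#' @return An `ess_fit` object with `method = "closed_form"`.
#' @examples
#' single_patch_ess(R = 1, r = 1)$z_star  # 0.5
#' @export
single_patch_ess <- function(R, r, a = 1) {
  .check_pos(R, "R"); .check_pos(a, "a")
  if (r < 0 || r > 1) abort("`r` must lie in [0, 1].")
  z <- r * R^a / 2
  .new_ess_fit(z, "closed_form", selection_gradient(R, r, z, a),
               r = r, a = a, R_mean = R, R_var = 0)
}

#' Ancestry-weighted selection gradient across a metapopulation
#'
#' Integrates the single-patch gradient over the resource distribution with
#' ancestry weights `c_R` set by the selection regime. Under soft selection
#' every patch contributes equal ancestry (`c_R = p_R`), giving
#' `E_p[R^a] r - 2z`. Under hard selection patches contribute in proportion
#' to their productivity (`c_R = p_R wbar_R / wbar`), giving the normalized
#' integral `E_p[wbar_R (R^a r - 2z)] / E_p[wbar_R]`. Normalizing by `wbar`
#' rescales but never moves the root, and makes the returned value a
#' per-capita quantity.
#'
#' Atomic distributions are summed exactly; continuous densities use adaptive
#' quadrature.
#'
#' @param dist A [resource_atoms()] / [resource_density()] object.
#' @param model A [trait_model()].
#' @param z Resident investment, `>= 0`. Vectorised.
#' @param regime `"soft"` or `"hard"`.
#' @return The gradient value(s); positive favours more investment.
#' @examples
#' d <- resource_atoms(c(0.5, 1.5))
#' metapop_gradient(d, trait_model(r = 1), z = 0,   regime = "soft")  # 1
#' metapop_gradient(d, trait_model(r = 1), z = 0.5, regime = "hard") # > 0
#' @export
metapop_gradient <- function(dist, model, z, regime) {
  stopifnot(inherits(dist, "resource_dist"), inherits(model, "trait_model"))
  .check_regime(regime)
  .check_nonneg(z, "z")
  r <- model$r; a <- model$a
  one <- function(zz) {
    if (regime == "soft") {
      dist_expect(dist, function(R) R^a) * r - 2 * zz
    } else {
      num <- dist_expect(dist, function(R) mean_fitness(R, zz, a) * (R^a * r - 2 * zz))
      den <- dist_expect(dist, function(R) mean_fitness(R, zz, a))
      if (!is.finite(num) || !is.finite(den) || den <= 0) {
        abort(sprintf(
          "Non-finite hard-selection gradient at z = %g (numerator %g, mean fitness %g).",
          zz, num, den))
      }
      num / den
    }
  }
  vapply(z, one, numeric(1))
}

#' Numeric ESS for a metapopulation under hard or soft selection
#'
#' Finds the root of [metapop_gradient()] in `z` by Brent's method on the
#' bracket `[0, r * Rmax^a]`: the gradient is positive at 0 whenever `r > 0`
#' and negative at the upper end, where `2z` exceeds the largest possible
#' benefit term. With `r = 0` (or a non-positive gradient at the origin) the
#' boundary ESS `z* = 0` is returned directly.
#'
#' @inheritParams metapop_gradient
#' @param bracket Optional length-2 search interval; defaults to
#'   `c(0, r * Rmax^a)`.
#' @param tol Absolute tolerance on the root. Default `1e-10`.
#' @return An `ess_fit` with `method = "numeric_root"` and the residual
#'   gradient at the root.
#' @examples
#' d <- resource_atoms(c(0.5, 1.5))
#' ess_solve(d, trait_model(r = 1), "soft")$z_star   # 0.5 = mean(R) * r / 2
#' ess_solve(d, trait_model(r = 1), "hard")$z_star   # > 0.5
#' @export
ess_solve <- function(dist, model, regime, bracket = NULL, tol = 1e-10) {
  stopifnot(inherits(dist, "resource_dist"), inherits(model, "trait_model"))
  .check_regime(regime)
  .check_pos(tol, "tol")
  g <- function(z) metapop_gradient(dist, model, z, regime)
  if (is.null(bracket)) bracket <- c(0, max(model$r * dist$Rmax^model$a, tol))
  g0 <- g(bracket[1])
  if (g0 <= 0) {
    # selection never favours investment above the lower end (e.g. r = 0)
    z <- bracket[1]
    return(.new_ess_fit(z, "numeric_root", g0, regime, model$r, model$a,
                        dist$mean, dist$variance))
  }
  g1 <- g(bracket[2])
  if (g1 > 0) {
    abort(sprintf(
      "Gradient does not change sign on [%g, %g] (values %g, %g); widen `bracket`.",
      bracket[1], bracket[2], g0, g1))
  }
  root <- uniroot(g, interval = bracket, tol = tol / 2)
  res <- g(root$root)
  if (abs(res) > tol) {
    # polish by bisection if uniroot's interpolation stopped short
    lo <- bracket[1]; hi <- bracket[2]
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) lo <- mid else hi <- mid
      if (hi - lo < tol / 4) break
    }
    root$root <- (lo + hi) / 2
    res <- g(root$root)
  }
  .new_ess_fit(root$root, "numeric_root", res, regime, model$r, model$a,
               dist$mean, dist$variance)
}

#' First-order ESS approximations in the resource variance
#'
#' Closed-form small-variance expansions of the metapopulation ESS about the
#' mean resource level. Under soft selection
#' `z* ~ (r Rbar^a / 2) (1 + a(a-1) Rbar^-2 sigma^2 / 2)` — for `a = 1` the
#' variance term vanishes: heterogeneity has no effect. Under hard selection
#' `z* ~ (r Rbar^a / 2) (1 + a(a - 1 + a r Rbar^(2a)) sigma^2 / (2 Rbar^2))`,
#' which for `a = 1` reduces to `(Rbar r / 2)(1 + r sigma^2 / 2)`: patch
#' productivity differences favour extra cooperation.
#'
#' @param R_mean Mean resource level `Rbar`, `> 0`.
#' @param R_var Resource variance `sigma^2`, `>= 0`.
#' @param model A [trait_model()].
#' @param regime `"soft"` or `"hard"`.
#' @return An `ess_fit` with `method = "first_order_approx"`.
#' @examples
#' ess_approx(1, 0.25, trait_model(r = 1), "hard")$z_star  # 0.5625
#' ess_approx(1, 0.25, trait_model(r = 1), "soft")$z_star  # 0.5
#' @export
ess_approx <- function(R_mean, R_var, model, regime) {
  stopifnot(inherits(model, "trait_model"))
  .check_regime(regime)
  .check_pos(R_mean, "R_mean"); .check_nonneg(R_var, "R_var")
  r <- model$r; a <- model$a
  base <- r * R_mean^a / 2
  corr <- if (regime == "soft") {
    0.5 * a * (a - 1) * R_mean^-2 * R_var
  } else {
    (a * (a - 1 + a * r * R_mean^(2 * a)) / (2 * R_mean^2)) * R_var
  }
  .new_ess_fit(base * (1 + corr), "first_order_approx", NA_real_,
               regime, r, a, R_mean, R_var)
}

#' @export
print.ess_fit <- function(x, ...) {
  cat(sprintf("<ess_fit: z* = %.8g  [%s%s]>\n", x$z_star, x$method,
              if (!is.na(x$regime)) paste0(", ", x$regime, " selection") else ""))
  if (!is.na(x$residual_gradient)) {
    cat(sprintf("  residual gradient = %.3g\n", x$residual_gradient))
  }
  invisible(x)
}

#' @rdname tidy.ess_fit
#' @export
glance.ess_fit <- function(x, ...) {
  tibble::tibble(
    z_star = x$z_star, method = x$method, regime = x$regime,
    residual_gradient = x$residual_gradient,
    r = x$r, a = x$a, R_mean = x$R_mean, R_var = x$R_var
  )
}

#' Tidy an ESS fit
#'
#' `tidy()` and `glance()` return the fitted equilibrium investment and its
#' provenance (method, selection regime, model parameters) as a one-row
#' tibble, for binding across scenarios.
#'
#' @param x An `ess_fit` object.
#' @param ... Unused.
#' @export
tidy.ess_fit <- function(x, ...) glance.ess_fit(x, ...)
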