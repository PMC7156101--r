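#' Ancestry-weighted invasion exponent of a rare mutant
#'
#' Log relative fitness of a rare mutant investing `z_mut` in a
#' metapopulation monomorphic for `z_res`, averaged over patches with the
#' ancestry weights of the selection regime. The mutant's neighbourhood
#' siderophore availability is `y = r * z_mut + (1 - r) * z_res` — the
#' defining property of relatedness as the slope `dy/dx`. A positive value
#' means the mutant invades. The log (geometric-mean) form is used so that
#' the measure's derivative at `z_mut = z_res` equals [metapop_gradient()]
#' exactly, without the second-order convexity bias an arithmetic mean of
#' relative fitness across patches would add.
#'
#' @inheritParams metapop_gradient
#' @param z_res Resident investment, `>= 0`.
#' @param z_mut Mutant investment, `>= 0`.
#' @return Scalar invasion measure.
#' @export
invasion_measure <- function(dist, model, z_res, z_mut, regime) {
  stopifnot(inherits(dist, "resource_dist"), inherits(model, "trait_model"))
  .check_regime(regime)
  .check_nonneg(z_res, "z_res"); .check_nonneg(z_mut, "z_mut")
  r <- model$r; a <- model$a
  y_mut <- r * z_mut + (1 - r) * z_res
  # log w(mutant) - log wbar(resident) = R^a (y_mut - z_res) - z_mut^2 + z_res^2
  log_rel_w <- function(R) {
    growth_rate(R, y = y_mut, x = z_mut, a = a) -
      growth_rate(R, y = z_res, x = z_res, a = a)
  }
  if (regime == "soft") {
    dist_expect(dist, log_rel_w)
  } else {
    num <- dist_expect(dist, function(R) mean_fitness(R, z_res, a) * log_rel_w(R))
    den <- dist_expect(dist, function(R) mean_fitness(R, z_res, a))
    num / den
  }
}

#' Adaptive trait-substitution walk to the ESS
#'
#' Iterated invasion analysis: from the resident value, propose mutants one
#' `step` up and one `step` down; substitute the direction with the larger
#' positive [invasion_measure()]; stop when neither direction invades. The
#' walk converges to within one mutation step of the [ess_solve()] root for
#' both selection regimes.
#'
#' @inheritParams metapop_gradient
#' @param z0 Starting investment, `>= 0`. Default 0.
#' @param step Mutation step size, `> 0`. Default 0.01.
#' @param max_iter Iteration cap; exceeding it raises a non-convergence
#'   error carrying the trajectory so far (in the condition's `trajectory`
#'   field). Default 10000.
#' @param seed Optional integer; when given, each substitution proposes the
#'   up/down mutants in random order, which does not change the fixed point.
#' @return List with `trajectory` (tibble `iteration`, `z`), `z_final`, and
#'   `iterations`.
#' @examples
#' d <- resource_atoms(c(0.5, 1.5))
#' trait_substitution_run(d, trait_model(r = 1), "hard", step = 0.005)$z_final
#' @export
trait_substitution_run <- function(dist, model, regime, z0 = 0, step = 0.01,
                                   max_iter = 10000L, seed = NULL) {
  stopifnot(inherits(dist, "resource_dist"), inherits(model, "trait_model"))
  .check_regime(regime)
  .check_nonneg(z0, "z0"); .check_pos(step, "step")
  if (!is.null(seed)) set.seed(seed)
  z <- z0
  zs <- numeric(max_iter + 1L)
  zs[1L] <- z
  it <- 0L
  repeat {
    if (it >= max_iter) {
      traj <- tibble::tibble(iteration = 0:it, z = zs[1:(it + 1L)])
      cnd <- rlang::error_cnd(
        "coopscape_nonconvergence",
        message = sprintf("No fixed point within %d substitutions (z = %g).",
                          max_iter, z),
        trajectory = traj
      )
      rlang::cnd_signal(cnd)
    }
    cands <- c(z + step, max(z - step, 0))
    if (!is.null(seed)) cands <- sample(cands)
    gains <- vapply(cands, function(zm) {
      if (zm == z) -Inf else invasion_measure(dist, model, z, zm, regime)
    }, numeric(1))
    if (all(gains <= 0)) break
    z <- cands[which.max(gains)]
    it <- it + 1L
    zs[it + 1L] <- z
  }
  list(
    trajectory = tibble::tibble(iteration = 0:it, z = zs[1:(it + 1L)]),
    z_final = z,
    iterations = it
  )
}
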