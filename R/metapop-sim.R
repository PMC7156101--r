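#' Season and transfer parameters for the serial-transfer simulator
#'
#' `season_params()` sets the within-season growth law: strains grow
#' exponentially at Malthusian rates `gamma_i = R^a * y - x_i^2` (per hour),
#' with `y` the density-weighted mean investment of the patch (the public
#' good is fully shared in a well-mixed microcosm), until the patch total
#' reaches the carrying ceiling `K * R` — carrying capacity proportional to
#' resource level — after which growth stops for the rest of the season.
#' Integration is a fixed-step exponential-midpoint scheme on log
#' densities, `steps` steps per season; `y` is recomputed every half-step
#' as strain frequencies shift.
#'
#' `transfer_plan()` sets the between-season pooling: paired microcosms are
#' mixed either volumetrically (`"hard"`, contribution proportional to final
#' density) or after equalizing each patch's total density (`"soft"`), and a
#' `bottleneck` fraction (default 1%) of the pooled mixture seeds two fresh
#' patches.
#'
#' @param K Carrying coefficient, cells/mL per unit resource. Default `1e9`.
#' @param duration Season length in hours. Default 48.
#' @param steps Euler steps per season. Default 480 (halving the step size
#'   changes end-of-season frequencies by < 1e-4 at the default scales).
#' @param a Resource exponent of the growth law. Default 1.
#' @param mu Per-division probability that a producer's offspring is a
#'   non-producing mutant (`x = 0`). Default 0 (no de-novo cheats).
#' @param volume_ml Patch volume in mL, used to convert densities to founder
#'   cell counts when transfers are sampled. Default 6.
#' @return A `season_params` (resp. `transfer_plan`) list.
#' @export
season_params <- function(K = 1e9, duration = 48, steps = 480L, a = 1,
                          mu = 0, volume_ml = 6) {
  .check_pos(K, "K"); .check_pos(duration, "duration"); .check_pos(a, "a")
  .check_pos(volume_ml, "volume_ml")
  if (!is.numeric(mu) || mu < 0 || mu > 1) abort("`mu` must lie in [0, 1].")
  steps <- as.integer(steps)
  if (steps < 1L) abort("`steps` must be a positive integer.")
  structure(list(K = K, duration = duration, steps = steps, a = a,
                 mu = mu, volume_ml = volume_ml),
            class = "season_params")
}

#' @rdname season_params
#' @param pooling `"hard"` or `"soft"`.
#' @param bottleneck Transfer fraction in (0, 1). Default 0.01 (1% by
#'   volume, relative to the destination microcosm).
#' @param n_transfers Number of serial transfers. Default 20.
#' @export
transfer_plan <- function(pooling = "hard", bottleneck = 0.01,
                          n_transfers = 20L) {
  .check_regime(pooling)
  if (!is.numeric(bottleneck) || bottleneck <= 0 || bottleneck >= 1) {
    abort("`bottleneck` must lie strictly between 0 and 1.")
  }
  n_transfers <- as.integer(n_transfers)
  if (n_transfers < 1L) abort("`n_transfers` must be >= 1.")
  structure(list(pooling = pooling, bottleneck = bottleneck,
                 n_transfers = n_transfers),
            class = "transfer_plan")
}

#' Construct a patch (one microcosm)
#'
#' @param R Resource level of the patch, `> 0`.
#' @param strains A data frame with columns `strain` (label), `x`
#'   (investment, `>= 0`) and `density` (cells/mL, `>= 0`).
#' @return A `patch_state` list with fields `R`, `strains`, `season_time`.
#' @export
patch_state <- function(R, strains) {
  .check_pos(R, "R")
  strains <- tibble::as_tibble(strains)
  if (!all(c("strain", "x", "density") %in% names(strains))) {
    abort("`strains` needs columns strain, x, density.")
  }
  .check_nonneg(strains$x, "x"); .check_nonneg(strains$density, "density")
  structure(list(R = R, strains = strains, season_time = 0),
            class = "patch_state")
}

# Vectorised season integrator over a set of patches.
# D: patches x strains density matrix; R: per-patch resources; x: per-strain
# investments. Growth freezes per patch once total density reaches K*R.
# When mu > 0, a fraction mu of each producer's births is diverted to the
# strain column with x == 0 (which must exist).
.grow_season <- function(D, R, x, params) {
  dt <- params$duration / params$steps
  cap <- params$K * R
  a <- params$a
  mut_col <- if (params$mu > 0) which(x == 0)[1] else NA_integer_
  if (params$mu > 0 && is.na(mut_col)) {
    abort("Mutation requires a strain with investment x = 0 to receive mutants.")
  }
  rates <- function(D) {
    y <- as.vector(D %*% x) / rowSums(D)
    outer(R^a * y, x^2, "-")               # gamma[p, i] = R^a y - x_i^2
  }
  active <- rowSums(D) < cap
  for (s in seq_len(params$steps)) {
    if (!any(active)) break
    # exponential midpoint: evaluate rates again after half a step so the
    # frequency-dependent public good y is second-order accurate
    g1 <- rates(D)
    gamma <- rates(D * exp(g1 * (dt / 2)))
    Dn <- D
    idx <- which(active)
    Dn[idx, ] <- D[idx, , drop = FALSE] * exp(gamma[idx, , drop = FALSE] * dt)
    if (params$mu > 0) {
      births <- pmax(Dn[idx, , drop = FALSE] - D[idx, , drop = FALSE], 0)
      flux <- params$mu * births[, -mut_col, drop = FALSE]
      Dn[idx, -mut_col] <- Dn[idx, -mut_col, drop = FALSE] - flux
      Dn[idx, mut_col] <- Dn[idx, mut_col] + rowSums(flux)
    }
    totn <- rowSums(Dn)
    over <- idx[totn[idx] > cap[idx]]
    if (length(over)) {
      # land exactly on the ceiling, then freeze the patch
      Dn[over, ] <- Dn[over, , drop = FALSE] * (cap[over] / totn[over])
      active[over] <- FALSE
    }
    D <- Dn
  }
  D
}

#' Grow one patch for a season
#'
#' Integrates the within-patch dynamics for `duration` hours (see
#' [season_params()] for the growth law). With all strains sharing the patch
#' public good `y`, a lower-investment strain never loses frequency: cheats
#' gain within every mixed patch.
#'
#' @param patch A [patch_state()] with at least one positive density.
#' @param params A [season_params()].
#' @param duration Optional override of the season length (hours).
#' @return The patch with end-of-season densities and `season_time = 1`.
#' @export
season_growth <- function(patch, params = season_params(), duration = NULL) {
  stopifnot(inherits(patch, "patch_state"), inherits(params, "season_params"))
  if (!is.null(duration)) params$duration <- .check_pos(duration, "duration")
  if (all(patch$strains$density <= 0)) {
    abort("All-zero inoculum: at least one strain must have positive density.")
  }
  D <- matrix(patch$strains$density, nrow = 1)
  D <- .grow_season(D, patch$R, patch$strains$x, params)
  patch$strains$density <- as.vector(D)
  patch$season_time <- 1
  patch
}

#' Pool a pair of patches and seed two fresh ones
#'
#' Implements the between-season mixing of matched microcosm pairs. Under
#' hard pooling the two cultures are mixed in equal volumes, so each patch
#' contributes in proportion to its final density. Under soft pooling each
#' patch's total density is first rescaled to the pair average, equalizing
#' contributions regardless of productivity. A `bottleneck` fraction of the
#' pool then inoculates two fresh patches at the pair's original resource
#' levels. If `rng = TRUE`, founder cells are drawn multinomially from the
#' pool composition (cell counts via `volume_ml`); otherwise the transfer is
#' exact fractional densities.
#'
#' @param pair List of two completed [patch_state()]s with identical strain
#'   tables (same strains, same order).
#' @param plan A [transfer_plan()].
#' @param params A [season_params()] (for `volume_ml`).
#' @param rng Logical; sample founders multinomially? Default `FALSE`.
#' @return List of two fresh `patch_state`s.
#' @export
pooled_transfer <- function(pair, plan, params = season_params(), rng = FALSE) {
  stopifnot(length(pair) == 2, inherits(plan, "transfer_plan"))
  A <- pair[[1]]; B <- pair[[2]]
  if (!identical(A$strains$strain, B$strains$strain)) {
    abort("Paired patches must carry the same strains in the same order.")
  }
  da <- A$strains$density; db <- B$strains$density
  ta <- sum(da); tb <- sum(db)
  if (ta + tb <= 0) abort("Zero pool density: nothing to transfer.")
  if (plan$pooling == "hard") {
    pool <- (da + db) / 2
  } else {
    t0 <- (ta + tb) / 2
    if (ta <= 0 || tb <= 0) abort("Soft pooling requires both patches non-empty.")
    pool <- (da * t0 / ta + db * t0 / tb) / 2
  }
  inoc <- pool * plan$bottleneck
  if (isTRUE(rng)) {
    n_cells <- round(sum(inoc) * params$volume_ml)
    draw <- function() {
      if (n_cells > 0 && sum(pool) > 0) {
        as.vector(rmultinom(1, n_cells, pool / sum(pool))) / params$volume_ml
      } else {
        rep(0, length(pool))
      }
    }
    inoc_a <- draw(); inoc_b <- draw()
  } else {
    inoc_a <- inoc; inoc_b <- inoc
  }
  fresh <- function(template, dens) {
    s <- template$strains
    s$density <- dens
    patch_state(template$R, s)
  }
  list(fresh(A, inoc_a), fresh(B, inoc_b))
}

#' Configure a serial-transfer metapopulation experiment
#'
#' @param pairs Data frame with columns `pair_id`, `R_1`, `R_2`: one row per
#'   matched microcosm pair (heterogeneous pairs have `R_1 != R_2`).
#' @param strains Data frame with columns `strain`, `x`, `inoculum`
#'   (starting density, cells/mL, identical across patches).
#' @param season A [season_params()].
#' @param plan A [transfer_plan()].
#' @param n_replicates Independent replicate metapopulations. Default 1.
#' @param stochastic Sample transfer founders multinomially (and so make
#'   replicates/seeds differ)? Default `FALSE` (exact fractional transfer;
#'   the ~1e7-cell bottlenecks of the experimental design make drift
#'   negligible).
#' @return A validated `metapop_config` list.
#' @export
metapop_config <- function(pairs, strains, season = season_params(),
                           plan = transfer_plan(), n_replicates = 1L,
                           stochastic = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  strains <- tibble::as_tibble(strains)
  if (!all(c("pair_id", "R_1", "R_2") %in% names(pairs))) {
    abort("`pairs` needs columns pair_id, R_1, R_2.")
  }
  if (anyDuplicated(pairs$pair_id)) abort("`pair_id` must be unique.")
  if (!all(c("strain", "x", "inoculum") %in% names(strains))) {
    abort("`strains` needs columns strain, x, inoculum.")
  }
  .check_pos(c(pairs$R_1, pairs$R_2), "R")
  .check_nonneg(strains$x, "x")
  .check_nonneg(strains$inoculum, "inoculum")
  if (sum(strains$inoculum) <= 0) abort("Total inoculum must be positive.")
  stopifnot(inherits(season, "season_params"), inherits(plan, "transfer_plan"))
  structure(list(pairs = pairs, strains = strains, season = season,
                 plan = plan, n_replicates = as.integer(n_replicates),
                 stochastic = isTRUE(stochastic)),
            class = "metapop_config")
}

# one child seed per replicate, derived deterministically from the run seed
.child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(NA_integer_, n))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Run a serial-transfer metapopulation experiment
#'
#' Simulates `n_replicates` independent metapopulations of paired microcosms
#' through `n_transfers` 48-h seasons with pooling and 1% transfer between
#' seasons (see [season_params()], [transfer_plan()]). Deterministic given
#' `seed`: a single seed expands to one child seed per replicate.
#'
#' @param config A [metapop_config()].
#' @param seed Integer seed (required when `config$stochastic`).
#' @return A tibble with one row per replicate x transfer x patch x strain:
#'   `replicate`, `transfer` (0 = initial inoculum, t >= 1 = end of season
#'   t), `pair_id`, `patch_id`, `R`, `strain`, `x`, `density`.
#' @examples
#' cfg <- metapop_config(
#'   pairs = tibble::tibble(pair_id = 1, R_1 = 6, R_2 = 1.5),
#'   strains = tibble::tibble(strain = c("cooperator", "cheat"),
#'                            x = c(0.19, 0), inoculum = c(5e5, 5e5)),
#'   plan = transfer_plan("hard", n_transfers = 2))
#' run_metapopulation_experiment(cfg, seed = 1)
#' @export
run_metapopulation_experiment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "metapop_config"))
  if (config$stochastic && is.null(seed)) {
    abort("`seed` is required for a stochastic run.")
  }
  seeds <- .child_seeds(seed %||% 0L, config$n_replicates)
  x <- config$strains$x
  strain <- config$strains$strain
  n_pair <- nrow(config$pairs)
  R <- as.vector(rbind(config$pairs$R_1, config$pairs$R_2))
  pair_id <- rep(config$pairs$pair_id, each = 2)
  patch_id <- seq_along(R)
  P <- length(R); S <- length(x)

  record <- function(rep_i, transfer, D) {
    tibble::tibble(
      replicate = rep_i, transfer = transfer,
      pair_id = rep(pair_id, each = S), patch_id = rep(patch_id, each = S),
      R = rep(R, each = S), strain = rep(strain, times = P),
      x = rep(x, times = P), density = as.vector(t(D))
    )
  }

  run_one <- function(rep_i) {
    set.seed(seeds[rep_i])
    D <- matrix(rep(config$strains$inoculum, each = P), nrow = P)
    out <- list(record(rep_i, 0L, D))
    for (t in seq_len(config$plan$n_transfers)) {
      D <- .grow_season(D, R, x, config$season)
      out[[t + 1L]] <- record(rep_i, t, D)
      if (t < config$plan$n_transfers) {
        D <- .transfer_all(D, config$plan, config$season, config$stochastic)
      }
    }
    dplyr::bind_rows(out)
  }
  dplyr::bind_rows(lapply(seq_len(config$n_replicates), run_one))
}

# pool consecutive patch pairs (rows 2k-1, 2k) and reseed
.transfer_all <- function(D, plan, season, stochastic) {
  P <- nrow(D)
  Dn <- D
  for (k in seq_len(P / 2)) {
    i <- 2 * k - 1; j <- 2 * k
    da <- D[i, ]; db <- D[j, ]
    ta <- sum(da); tb <- sum(db)
    if (ta + tb <= 0) abort("Zero pool density during transfer.")
    if (plan$pooling == "hard") {
      pool <- (da + db) / 2
    } else {
      t0 <- (ta + tb) / 2
      pool <- (da * t0 / ta + db * t0 / tb) / 2
    }
    inoc <- pool * plan$bottleneck
    if (stochastic) {
      n_cells <- round(sum(inoc) * season$volume_ml)
      pr <- pool / sum(pool)
      Dn[i, ] <- as.vector(rmultinom(1, n_cells, pr)) / season$volume_ml
      Dn[j, ] <- as.vector(rmultinom(1, n_cells, pr)) / season$volume_ml
    } else {
      Dn[i, ] <- inoc; Dn[j, ] <- inoc
    }
  }
  Dn
}

#' Metapopulation-level strain frequency per transfer
#'
#' Density-weighted frequency of one strain across all patches, per
#' replicate and transfer — the quantity the pooled plating of a
#' metapopulation competition experiment estimates.
#'
#' @param trajectory Output of [run_metapopulation_experiment()].
#' @param strain Strain label to track. Default `"cooperator"`.
#' @return Tibble with `replicate`, `transfer`, `frequency`, `total_density`.
#' @export
metapop_frequency <- function(trajectory, strain = "cooperator") {
  trajectory |>
    dplyr::group_by(.data$replicate, .data$transfer) |>
    dplyr::summarise(
      frequency = sum(.data$density[.data$strain == !!strain]) /
        sum(.data$density),
      total_density = sum(.data$density),
      .groups = "drop"
    )
}
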