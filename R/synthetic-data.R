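#' Design of the synthetic assay experiments
#'
#' Describes the in-silico analogue of the wet-lab designs so that every
#' generator draws from one consistent parameterisation. The three media are
#' encoded by their casamino-acid dilution fractions relative to the
#' strongest medium — high = 1, low = 1/4, intermediate their mean (a 1:1
#' mix of high and low) — and scaled to model units by `resource_scale`.
#' The default scale (6) and cooperator investment (`coop_x = 0.19`) are set
#' so that (i) a pure producer culture saturates its carrying ceiling within
#' one 48-h season in every medium, making end-of-season density
#' proportional to resource level, and (ii) in co-culture the cooperator's
#' relative fitness `W ~ 1 - coop_x^2 / (R y)` lands below one in all media,
#' increases with resource level, and sits near 0.9 in the intermediate
#' medium — the regime the competition assays operate in.
#'
#' Measurement noise is multiplicative lognormal — colony counts and optical
#' densities are positive and right-skewed — with sd 0.1 (log scale) on
#' densities and 0.05 on absorbances.
#'
#' @param media Named resource levels (relative). Must be positive with
#'   `high > intermediate > low`.
#' @param resource_scale Multiplier mapping relative media levels to model
#'   resource units. Default 6.
#' @param replicates Replicates per group. Default 12.
#' @param coop_x Cooperator investment. Default 0.19.
#' @param inoculum Per-strain starting density, cells/mL. Default 5e5.
#' @param sigma_density Lognormal sd of density noise. Default 0.1.
#' @param sigma_absorbance Lognormal sd of absorbance noise. Default 0.05.
#' @param A_ref Reference CAS absorbance at 630 nm. Default 0.8.
#' @param season A [season_params()] for the growth core.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(media = c(high = 1, intermediate = 0.625,
                                       low = 0.25),
                             resource_scale = 6, replicates = 12L,
                             coop_x = 0.19, inoculum = 5e5,
                             sigma_density = 0.1, sigma_absorbance = 0.05,
                             A_ref = 0.8, season = season_params()) {
  if (!all(c("high", "intermediate", "low") %in% names(media))) {
    abort('`media` must name levels "high", "intermediate", "low".')
  }
  .check_pos(media, "media")
  if (!(media[["high"]] > media[["intermediate"]] &&
        media[["intermediate"]] > media[["low"]])) {
    abort("Require media high > intermediate > low.")
  }
  .check_pos(resource_scale, "resource_scale")
  .check_nonneg(coop_x, "coop_x"); .check_pos(inoculum, "inoculum")
  .check_nonneg(sigma_density, "sigma_density")
  .check_nonneg(sigma_absorbance, "sigma_absorbance")
  .check_pos(A_ref, "A_ref")
  stopifnot(inherits(season, "season_params"))
  structure(list(media = media, resource_scale = resource_scale,
                 replicates = as.integer(replicates), coop_x = coop_x,
                 inoculum = inoculum, sigma_density = sigma_density,
                 sigma_absorbance = sigma_absorbance, A_ref = A_ref,
                 season = season),
            class = "synthetic_design")
}

.media_R <- function(design) design$media * design$resource_scale

#' Synthetic single-population competition counts
#'
#' Emulates the co-inoculation competition experiment: a cooperator and a
#' cheat grown together for one season in each of the three media, with
#' `replicates` replicate microcosms per medium. The noise-free start and
#' end densities come from [season_growth()]; each recorded density is then
#' perturbed by multiplicative lognormal error. Ground truth (noise-free
#' Malthusian parameters and relative fitness per medium) is returned
#' alongside.
#'
#' @param design A [synthetic_design()].
#' @param seed Integer seed; the output is fully determined by it.
#' @return List with `counts` (tibble `replicate`, `media`, `strain`,
#'   `timepoint`, `density` — the input format of [competition_fitness()])
#'   and `truth` (tibble per medium: `media`, `R`, `m_cooperator`,
#'   `m_cheat`, `W`, `end_density`).
#' @export
gen_competition_counts <- function(design = synthetic_design(), seed = 1L) {
  stopifnot(inherits(design, "synthetic_design"))
  R <- .media_R(design)
  strains0 <- tibble::tibble(strain = c("cooperator", "cheat"),
                             x = c(design$coop_x, 0),
                             density = design$inoculum)
  truth <- purrr::map_dfr(names(R), function(m) {
    p <- season_growth(patch_state(R[[m]], strains0), design$season)
    endd <- p$strains$density
    mm <- malthusian(design$inoculum, endd)
    tibble::tibble(media = m, R = R[[m]],
                   m_cooperator = mm[1], m_cheat = mm[2],
                   W = relative_fitness(mm[1], mm[2]),
                   end_cooperator = endd[1], end_cheat = endd[2],
                   end_density = sum(endd))
  })
  set.seed(seed)
  grid <- tidyr::expand_grid(
    replicate = seq_len(design$replicates),
    media = names(R),
    strain = c("cooperator", "cheat"),
    timepoint = c("start", "end")
  )
  clean <- grid |>
    dplyr::left_join(truth, by = "media") |>
    dplyr::mutate(density = dplyr::case_when(
      .data$timepoint == "start" ~ design$inoculum,
      .data$strain == "cooperator" ~ .data$end_cooperator,
      TRUE ~ .data$end_cheat
    )) |>
    dplyr::select(dplyr::all_of(c("replicate", "media", "strain",
                                  "timepoint", "density")))
  noise <- exp(rnorm(nrow(clean), 0, design$sigma_density))
  counts <- dplyr::mutate(clean, density = .data$density * noise)
  list(counts = counts, truth = truth)
}

#' Synthetic metapopulation experiment configuration
#'
#' Builds the paired-microcosm design: the heterogeneous treatment pairs one
#' high- with one low-resource microcosm; the homogeneous treatment pairs
#' two intermediate microcosms. Because intermediate is the mean of high and
#' low, the two treatments have identical mean resource level by
#' construction.
#'
#' @param design A [synthetic_design()].
#' @param treatment `"heterogeneous"` or `"homogeneous"`.
#' @param pooling `"hard"` or `"soft"` transfer pooling. Default `"hard"`.
#' @param n_transfers Serial transfers. Default 20.
#' @param evolution If `TRUE`, start from the cooperator alone with de-novo
#'   cheat mutation (`mu`); if `FALSE` (default) co-inoculate cooperator and
#'   cheat equally with no mutation.
#' @param mu Mutation rate to non-producers for the evolution setup.
#'   Default `3e-4` per division (a large mutational target: complete
#'   siderophore loss only needs a regulatory knockout, and the rate is set
#'   so de-novo non-producers sweep to intermediate frequency on the
#'   20-transfer horizon, as observed experimentally).
#' @param n_replicates,stochastic Passed to [metapop_config()].
#' @return A [metapop_config()] ready for
#'   [run_metapopulation_experiment()].
#' @export
gen_metapop_config <- function(design = synthetic_design(),
                               treatment = c("heterogeneous", "homogeneous"),
                               pooling = "hard", n_transfers = 20L,
                               evolution = FALSE, mu = 3e-4,
                               n_replicates = 1L, stochastic = FALSE) {
  stopifnot(inherits(design, "synthetic_design"))
  treatment <- match.arg(treatment)
  R <- .media_R(design)
  n <- design$replicates
  pairs <- if (treatment == "heterogeneous") {
    tibble::tibble(pair_id = seq_len(n), R_1 = R[["high"]], R_2 = R[["low"]])
  } else {
    tibble::tibble(pair_id = seq_len(n), R_1 = R[["intermediate"]],
                   R_2 = R[["intermediate"]])
  }
  strains <- if (evolution) {
    tibble::tibble(strain = c("cooperator", "cheat"),
                   x = c(design$coop_x, 0),
                   inoculum = c(2 * design$inoculum, 0))
  } else {
    tibble::tibble(strain = c("cooperator", "cheat"),
                   x = c(design$coop_x, 0),
                   inoculum = c(design$inoculum, design$inoculum))
  }
  season <- design$season
  season$mu <- if (evolution) mu else 0
  metapop_config(pairs = pairs, strains = strains, season = season,
                 plan = transfer_plan(pooling, n_transfers = n_transfers),
                 n_replicates = n_replicates, stochastic = stochastic)
}

#' Synthetic CAS plate reads
#'
#' Simulates the chrome azurol S assay: each sample with true chelation
#' fraction `c` reads `A_i = A_ref * (1 - c)` at 630 nm, perturbed by
#' multiplicative lognormal noise, and an `OD600` of the 1:10-diluted sample
#' consistent with the stated culture density. With noise off,
#' [per_capita_cas()] recovers `c / density` exactly.
#'
#' @param production Numeric vector of chelation fractions in `[0, 1]`.
#' @param design A [synthetic_design()].
#' @param seed Integer seed.
#' @param density Undiluted culture densities (OD600 units), recycled along
#'   `production`. Default 1.
#' @param dilution OD measurement dilution factor. Default 10.
#' @param label Optional sample labels (e.g. treatment arms), recycled.
#' @return List with `plate` (tibble `sample`, `label`, `A_i`, `A_ref`,
#'   `OD600`, `dilution`) and `truth` (tibble with the noise-free chelation
#'   and per-capita activity).
#' @export
gen_cas_plate <- function(production, design = synthetic_design(), seed = 1L,
                          density = 1, dilution = 10, label = "sample") {
  stopifnot(inherits(design, "synthetic_design"))
  if (any(!is.finite(production)) || any(production < 0) || any(production > 1)) {
    abort("`production` must be chelation fractions in [0, 1].")
  }
  .check_pos(density, "density")
  n <- length(production)
  density <- rep_len(density, n)
  label <- rep_len(label, n)
  set.seed(seed)
  A_clean <- design$A_ref * (1 - production)
  OD_clean <- density / dilution
  plate <- tibble::tibble(
    sample = seq_len(n),
    label = label,
    A_i = A_clean * exp(rnorm(n, 0, design$sigma_absorbance)),
    A_ref = design$A_ref,
    OD600 = OD_clean * exp(rnorm(n, 0, design$sigma_absorbance)),
    dilution = dilution
  )
  truth <- tibble::tibble(
    sample = seq_len(n), label = label, chelation = production,
    density = density,
    activity = per_capita_cas(A_clean, design$A_ref, OD_clean, dilution)
  )
  list(plate = plate, truth = truth)
}
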