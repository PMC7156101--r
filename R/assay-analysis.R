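#' Malthusian parameter and relative fitness
#'
#' The Malthusian parameter of a strain over a growth period is
#' `m = ln(n_end / n_start)`; relative fitness of the cooperator against the
#' cheat is the ratio of their Malthusian parameters, `W = m_coop / m_cheat`.
#' `W < 1` (with both parameters positive) means the cheat outgrew the
#' cooperator.
#'
#' @param n_start,n_end Strictly positive densities (CFU/mL). Vectorised.
#' @return `malthusian()`: `ln(n_end/n_start)`; `relative_fitness()`: `W`.
#' @examples
#' malthusian(1e6, 1e8)          # log(100)
#' relative_fitness(4, 5)        # 0.8
#' @export
malthusian <- function(n_start, n_end) {
  .check_pos(n_start, "n_start"); .check_pos(n_end, "n_end")
  log(n_end / n_start)
}

#' @rdname malthusian
#' @param m_coop,m_cheat Malthusian parameters. `m_cheat` must be non-zero.
#' @export
relative_fitness <- function(m_coop, m_cheat) {
  if (any(!is.finite(m_coop)) || any(!is.finite(m_cheat))) {
    abort("Malthusian parameters must be finite.")
  }
  if (any(m_cheat == 0)) {
    abort("Relative fitness is undefined when the reference strain's m is 0.")
  }
  m_coop / m_cheat
}

#' Per-replicate relative fitness from a competition count table
#'
#' Takes the long table a plate-count competition experiment produces — one
#' row per replicate x media x strain x timepoint — and returns one row per
#' replicate x media with each strain's Malthusian parameter and the
#' cooperator's relative fitness `W`.
#'
#' @param data Data frame with columns `replicate`, `media`, `strain`,
#'   `timepoint` (`"start"`/`"end"`), `density`. Zero or missing densities
#'   are rejected: the assay cannot score extinct strains.
#' @param cooperator,cheat Strain labels. Defaults `"cooperator"`, `"cheat"`.
#' @return Tibble with `replicate`, `media`, `m_cooperator`, `m_cheat`, `W`.
#' @export
competition_fitness <- function(data, cooperator = "cooperator",
                                cheat = "cheat") {
  data <- tibble::as_tibble(data)
  need <- c("replicate", "media", "strain", "timepoint", "density")
  if (!all(need %in% names(data))) {
    abort(paste("`data` needs columns", paste(need, collapse = ", ")))
  }
  if (!all(data$strain %in% c(cooperator, cheat))) {
    abort("Unknown strain labels; set `cooperator`/`cheat`.")
  }
  if (!all(data$timepoint %in% c("start", "end"))) {
    abort('`timepoint` must be "start" or "end".')
  }
  .check_pos(data$density, "density")
  wide <- data |>
    tidyr::pivot_wider(id_cols = c("replicate", "media", "strain"),
                       names_from = "timepoint", values_from = "density")
  if (anyNA(wide$start) || anyNA(wide$end)) {
    abort("Every replicate x media x strain needs a start and an end count.")
  }
  wide |>
    dplyr::mutate(m = malthusian(.data$start, .data$end)) |>
    tidyr::pivot_wider(id_cols = c("replicate", "media"),
                       names_from = "strain", values_from = "m") |>
    dplyr::rename(m_cooperator = dplyr::all_of(cooperator),
                  m_cheat = dplyr::all_of(cheat)) |>
    dplyr::mutate(W = relative_fitness(.data$m_cooperator, .data$m_cheat))
}

#' Per-capita iron chelator activity (CAS assay)
#'
#' Chrome azurol S loses absorbance at 630 nm when iron is chelated; the
#' chelation fraction of a culture supernatant is `1 - A_i / A_ref`, with
#' `A_ref` the absorbance of a CAS reaction on sterile medium. Dividing by
#' culture density gives per-capita activity:
#' `(1 - A_i/A_ref) / (OD600 * dilution)`. `OD600` is measured on a diluted
#' sample (default 1:10) to stay in the linear range; multiplying by the
#' dilution factor back-calculates the undiluted density. Set `dilution = 1`
#' to normalise by the diluted reading instead.
#'
#' @param A_i Sample absorbance at 630 nm, `>= 0`.
#' @param A_ref Reference absorbance at 630 nm, `> 0`.
#' @param OD600 Optical density of the diluted sample, `> 0`.
#' @param dilution Dilution factor, `>= 1`. Default 10.
#' @return Per-capita activity (per OD unit). 0 when `A_i = A_ref`.
#' @examples
#' per_capita_cas(A_i = 0.4, A_ref = 0.8, OD600 = 0.05)  # 1
#' @export
per_capita_cas <- function(A_i, A_ref, OD600, dilution = 10) {
  .check_nonneg(A_i, "A_i"); .check_pos(A_ref, "A_ref")
  .check_pos(OD600, "OD600")
  if (any(dilution < 1)) abort("`dilution` must be >= 1.")
  (1 - A_i / A_ref) / (OD600 * dilution)
}

#' Per-sample CAS activity from a plate table
#'
#' @param data Data frame with columns `A_i`, `A_ref`, `OD600` and
#'   optionally `dilution` (default 10); any id columns are carried through.
#' @return The input tibble with an `activity` column appended.
#' @export
cas_activity <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("A_i", "A_ref", "OD600") %in% names(data))) {
    abort("`data` needs columns A_i, A_ref, OD600.")
  }
  if (!"dilution" %in% names(data)) data$dilution <- 10
  dplyr::mutate(data, activity = per_capita_cas(.data$A_i, .data$A_ref,
                                                .data$OD600, .data$dilution))
}

.check_groups <- function(values, group) {
  if (length(unique(group)) < 2) abort("Need at least 2 groups.")
  n <- table(group)
  if (any(n < 2)) abort("Every group needs at least 2 values.")
  ss_within <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  if (ss_within <= 0) abort("Zero within-group variance: F is undefined.")
  invisible(NULL)
}

#' One-way ANOVA over a tidy table
#'
#' Classical fixed-effects one-way analysis of variance (via [stats::aov()])
#' of a response across groups, returned as a one-row tibble.
#'
#' @param data Data frame.
#' @param value,group Column names (strings) of the response and the
#'   grouping factor.
#' @return Tibble with `F`, `df_between`, `df_within`, `p`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 6),
#'                  y = c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 6, 8,
#'                        13, 9, 11, 8, 7, 12))
#' one_way_anova(df, "y", "g")   # F about 9.59 on (2, 15) df
#' @export
one_way_anova <- function(data, value, group) {
  data <- as.data.frame(data)
  v <- data[[value]]; g <- factor(data[[group]])
  if (is.null(v) || is.null(g)) abort("`value`/`group` columns not found.")
  .check_groups(v, g)
  fit <- aov(v ~ g)
  s <- summary(fit)[[1]]
  tibble::tibble(
    F = s[["F value"]][1],
    df_between = s[["Df"]][1],
    df_within = s[["Df"]][2],
    p = s[["Pr(>F)"]][1]
  )
}

#' Tukey honest-significant-difference contrasts
#'
#' All pairwise group contrasts with studentized-range adjusted p-values
#' (via [stats::TukeyHSD()] on the one-way fit).
#'
#' @inheritParams one_way_anova
#' @param conf_level Family-wise confidence level. Default 0.95.
#' @return Tibble with `contrast`, `estimate`, `conf_low`, `conf_high`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(data, value, group, conf_level = 0.95) {
  data <- as.data.frame(data)
  v <- data[[value]]; g <- factor(data[[group]])
  if (is.null(v) || is.null(g)) abort("`value`/`group` columns not found.")
  .check_groups(v, g)
  tk <- TukeyHSD(aov(v ~ g), conf.level = conf_level)$g
  tibble::tibble(
    contrast = rownames(tk),
    estimate = tk[, "diff"],
    conf_low = tk[, "lwr"],
    conf_high = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
}

#' One-sample t-test against a hypothesized mean
#'
#' Two-sided one-sample t-test (via [stats::t.test()]), e.g. of relative
#' fitness against the neutral value `mu = 1`.
#'
#' @param x Numeric vector, length >= 2, with positive variance.
#' @param mu Hypothesized mean. Default 1.
#' @return Tibble with `estimate`, `t`, `df`, `p`.
#' @examples
#' one_sample_t(c(2, 2, 2, 4), mu = 2)  # t = 1 on 3 df
#' @export
one_sample_t <- function(x, mu = 1) {
  if (length(x) < 2) abort("Need at least 2 values.")
  if (stats::var(x) == 0) abort("Zero sample variance: t is undefined.")
  tt <- t.test(x, mu = mu)
  tibble::tibble(
    estimate = unname(tt$estimate),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value
  )
}
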