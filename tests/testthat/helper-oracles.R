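# Independent brute-force oracles and fixture builders shared across tests.
# These deliberately avoid the package's own code paths wherever they check
# one: literal sums, explicit sums of squares, permutation nulls.

`%||%` <- function(a, b) if (is.null(a)) b else a

# literal ancestry-weighted sum over atoms (checks metapop_gradient)
brute_gradient <- function(R, w, r, a, z, regime) {
  g <- R^a * r - 2 * z
  if (regime == "soft") {
    sum(w * g)
  } else {
    wbar <- exp(R^a * z - z^2)
    sum(w * wbar * g) / sum(w * wbar)
  }
}

# dense grid scan for the sign change of the gradient (checks ess_solve)
brute_ess <- function(R, w, r, a, regime, n = 2e5) {
  zs <- seq(0, max(r * max(R)^a, 1e-6), length.out = n)
  gs <- vapply(zs, function(z) brute_gradient(R, w, r, a, z, regime),
               numeric(1))
  i <- which(gs <= 0)[1]
  if (is.na(i) || i == 1) return(zs[1])
  # linear interpolation across the sign change
  z0 <- zs[i - 1]; z1 <- zs[i]
  g0 <- gs[i - 1]; g1 <- gs[i]
  z0 - g0 * (z1 - z0) / (g1 - g0)
}

# random atomic resource distribution, optionally rescaled to a fixed mean
random_atoms <- function(k = NULL, fixed_mean = NULL) {
  k <- k %||% sample(2:5, 1)
  R <- sort(runif(k, 0.2, 3))
  w <- runif(k); w <- w / sum(w)
  if (!is.null(fixed_mean)) R <- R * fixed_mean / sum(w * R)
  list(R = R, w = w, dist = resource_atoms(R, w))
}

# explicit one-way ANOVA table from sums of squares
oracle_anova <- function(values, group) {
  group <- factor(group)
  gm <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(group) - 1
  dfw <- length(values) - nlevels(group)
  F <- (ssb / dfb) / (ssw / dfw)
  list(F = F, df_between = dfb, df_within = dfw,
       p = stats::pf(F, dfb, dfw, lower.tail = FALSE))
}

# permutation null of the F statistic, vectorised over draws
perm_anova_p <- function(values, group, n_perm = 1e4) {
  obs <- oracle_anova(values, group)$F
  group <- factor(group)
  n <- length(values)
  counts <- table(group)
  total_ss <- sum(values^2)
  exceed <- 0L
  chunk <- 2000L
  done <- 0L
  while (done < n_perm) {
    m <- min(chunk, n_perm - done)
    # m permutations as columns; compute between-group SS for each
    perms <- replicate(m, sample.int(n))
    ssb <- numeric(m)
    for (lev in levels(group)) {
      idx_rows <- which(group == lev)
      sums <- colSums(matrix(values[perms[seq_along(values), , drop = FALSE]],
                             nrow = n)[idx_rows, , drop = FALSE])
      ssb <- ssb + sums^2 / length(idx_rows)
    }
    ssb <- ssb - sum(values)^2 / n
    ssw <- (total_ss - sum(values)^2 / n) - ssb
    dfb <- nlevels(group) - 1; dfw <- n - nlevels(group)
    Fs <- (ssb / dfb) / (ssw / dfw)
    exceed <- exceed + sum(Fs >= obs - 1e-12)
    done <- done + m
  }
  exceed / n_perm
}

# pairwise Tukey p-values straight from the studentized range distribution
oracle_tukey <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group)
  ns <- tapply(values, group, length)
  means <- tapply(values, group, mean)
  dfw <- length(values) - k
  mse <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / dfw
  pairs <- utils::combn(levels(group), 2)
  apply(pairs, 2, function(pr) {
    se <- sqrt(mse / 2 * (1 / ns[[pr[1]]] + 1 / ns[[pr[2]]]))
    q <- abs(means[[pr[2]]] - means[[pr[1]]]) / se
    stats::ptukey(q, k, dfw, lower.tail = FALSE)
  })
}

# textbook three-group example; F frozen from oracle_anova (SSB 84, SSW 68)
textbook_groups <- function() {
  data.frame(
    g = rep(c("a", "b", "c"), each = 6),
    y = c(6, 8, 4, 5, 3, 4, 8, 12, 9, 11, 6, 8, 13, 9, 11, 8, 7, 12)
  )
}
textbook_F <- 84 / 2 / (68 / 15)  # = 9.2647...

# two-strain competition patch at the generator's default operating point
default_pair_patch <- function(R, f_coop = 0.5, total = 1e6, x = 0.19) {
  patch_state(R, tibble::tibble(
    strain = c("cooperator", "cheat"), x = c(x, 0),
    density = total * c(f_coop, 1 - f_coop)
  ))
}
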