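#' Resource distributions over patches
#'
#' A metapopulation is described by the distribution `p_R` of resource
#' availability `R` across its constituent patches. `resource_atoms()` builds
#' a finite (atomic) distribution from explicit `(R, weight)` pairs — the
#' form the paired-microcosm experiments realise (e.g. two patches at high
#' and low resource levels). `resource_density()` wraps a continuous density
#' on `[Rmin, Rmax]`, and `resource_uniform()` is the uniform special case.
#'
#' All constructors validate that resource levels are strictly positive and
#' that weights (or the density) sum / integrate to one; the reported mean
#' and variance are always computed from the support itself.
#'
#' @param R Numeric vector of resource levels, all `> 0`.
#' @param weights Numeric vector of non-negative weights summing to 1.
#'   Defaults to equal weights.
#' @param density A vectorised function of `R` returning the probability
#'   density, non-negative on `[Rmin, Rmax]`.
#' @param Rmin,Rmax Support bounds, `0 < Rmin < Rmax`.
#'
#' @return An object of class `resource_dist` with fields `type`
#'   (`"atoms"` or `"density"`), the support, and moments `mean` and
#'   `variance`.
#'
#' @examples
#' resource_atoms(c(0.5, 1.5))                 # two equal patches
#' resource_atoms(c(1, 2, 4), c(0.5, 0.3, 0.2))
#' resource_uniform(0.5, 1.5)
#' @export
resource_atoms <- function(R, weights = NULL) {
  if (length(R) < 1 || !is.numeric(R) || any(!is.finite(R)) || any(R <= 0)) {
    abort("`R` must be a numeric vector of strictly positive resource levels.")
  }
  if (is.null(weights)) weights <- rep(1 / length(R), length(R))
  if (length(weights) != length(R) || any(!is.finite(weights)) || any(weights < 0)) {
    abort("`weights` must be non-negative and match `R` in length.")
  }
  s <- sum(weights)
  if (abs(s - 1) > 1e-9) {
    abort(sprintf("`weights` must sum to 1 (got %.12g).", s))
  }
  weights <- weights / s
  m <- sum(weights * R)
  v <- sum(weights * (R - m)^2)
  structure(
    list(type = "atoms", R = as.numeric(R), weights = as.numeric(weights),
         Rmin = min(R), Rmax = max(R), mean = m, variance = v),
    class = "resource_dist"
  )
}

#' @rdname resource_atoms
#' @export
resource_density <- function(density, Rmin, Rmax) {
  if (!is.function(density)) abort("`density` must be a function of R.")
  if (!is.numeric(Rmin) || !is.numeric(Rmax) || Rmin <= 0 || Rmax <= Rmin) {
    abort("Require 0 < Rmin < Rmax.")
  }
  total <- .quad(function(R) density(R), Rmin, Rmax)
  if (abs(total - 1) > 1e-9) {
    abort(sprintf("Density must integrate to 1 on [Rmin, Rmax] (got %.12g).", total))
  }
  m <- .quad(function(R) R * density(R), Rmin, Rmax)
  v <- .quad(function(R) (R - m)^2 * density(R), Rmin, Rmax)
  structure(
    list(type = "density", density = density, Rmin = Rmin, Rmax = Rmax,
         mean = m, variance = v),
    class = "resource_dist"
  )
}

#' @rdname resource_atoms
#' @export
resource_uniform <- function(Rmin, Rmax) {
  width <- Rmax - Rmin
  resource_density(function(R) rep(1 / width, length(R)), Rmin, Rmax)
}

# adaptive quadrature with the tolerance used throughout the theory layer
.quad <- function(f, lower, upper) {
  res <- integrate(f, lower, upper, rel.tol = 1e-10, abs.tol = 1e-10,
                   subdivisions = 500L, stop.on.error = FALSE)
  if (res$message != "OK" || !is.finite(res$value)) {
    abort(sprintf("Quadrature failed on [%g, %g]: %s", lower, upper, res$message))
  }
  res$value
}

#' Expectation of a function under a resource distribution
#'
#' Atomic supports are summed exactly; continuous densities are integrated by
#' adaptive quadrature (absolute tolerance 1e-10).
#'
#' @param dist A [resource_atoms()] / [resource_density()] object.
#' @param f Vectorised function of `R`.
#' @return The expectation `E_p[f(R)]` as a scalar.
#' @export
dist_expect <- function(dist, f) {
  stopifnot(inherits(dist, "resource_dist"))
  if (dist$type == "atoms") {
    sum(dist$weights * f(dist$R))
  } else {
    .quad(function(R) f(R) * dist$density(R), dist$Rmin, dist$Rmax)
  }
}

#' @export
print.resource_dist <- function(x, ...) {
  if (x$type == "atoms") {
    cat(sprintf("<resource_dist: %d atoms on [%g, %g]>\n",
                length(x$R), x$Rmin, x$Rmax))
  } else {
    cat(sprintf("<resource_dist: density on [%g, %g]>\n", x$Rmin, x$Rmax))
  }
  cat(sprintf("  mean R = %.6g, variance = %.6g\n", x$mean, x$variance))
  invisible(x)
}
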