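## Multigroup energy structure and the small quadrature/Legendre machinery
## shared by the feed-function integrals.

#' Build a multigroup energy structure
#'
#' Boundaries run from `E_max` down to the 1 keV transport cutoff, strictly
#' decreasing (group 1 is the highest-energy group, the transport
#' convention).  Midpoints are arithmetic means of the bounding boundaries;
#' the flux-weighted average energies are initialised to the midpoints
#' (flat within-group flux guess).
#'
#' @param E_max Top boundary in MeV (at most 20).
#' @param N Number of groups (at least 3).
#' @param spacing `"log"` (default) or `"linear"`.
#' @return An object of class `bfp_groups` with fields `boundaries` (length
#'   `N + 1`, decreasing), `mid`, `Eavg`, `dE`, `N`.
#' @examples
#' make_groups(1.0, 10)
#' @export
make_groups <- function(E_max, N, spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  lo <- bfp_constants$e_cutoff
  if (E_max <= lo) stop("E_max must exceed the 1 keV cutoff", call. = FALSE)
  if (E_max > 20) stop("E_max above the 20 MeV library range", call. = FALSE)
  if (N < 3) stop("at least 3 groups required", call. = FALSE)
  b <- switch(spacing,
    log = exp(seq(log(E_max), log(lo), length.out = N + 1)),
    linear = seq(E_max, lo, length.out = N + 1))
  b[1] <- E_max
  b[N + 1] <- lo
  mid <- (b[-1] + b[-(N + 1)]) / 2
  structure(list(boundaries = b, mid = mid, Eavg = mid,
                 dE = b[-(N + 1)] - b[-1], N = N, spacing = spacing),
            class = "bfp_groups")
}

#' @export
print.bfp_groups <- function(x, ...) {
  cat(sprintf("<bfp_groups> %d groups, %s spacing, %.4g MeV -> %.4g MeV\n",
              x$N, x$spacing, x$boundaries[1], x$boundaries[x$N + 1]))
  invisible(x)
}

## Soft/catastrophic threshold boundary for source group g: the boundary two
## below the group's top boundary (bottom of the adjacent group), so that
## "catastrophic" means down-scatter into non-adjacent groups.  For the two
## lowest groups the threshold saturates at the cutoff boundary.
.soft_threshold <- function(gs, g) {
  gs$boundaries[min(g + 2, gs$N + 1)]
}

## group index containing energy E (1 = highest); N+1 codes below-cutoff
.group_of <- function(gs, E) {
  b <- gs$boundaries
  ## boundaries decreasing; group g is (b[g+1], b[g]]
  idx <- findInterval(-E, -b, left.open = FALSE)
  pmin(pmax(idx, 1L), gs$N + 1L)
}

#' Gauss-Lobatto rule on [-1, 1]
#'
#' Nodes and weights of the n-point Gauss-Lobatto rule (endpoints included),
#' computed by Newton iteration on the derivative of the Legendre
#' polynomial.  Rules are provided up to order 10; higher orders fall back
#' to Gauss-Legendre with a warning.
#'
#' @param n Number of nodes (2..10).
#' @return List with `x` (nodes) and `w` (weights).
#' @export
gauss_lobatto <- function(n) {
  if (n > 10) {
    warning("Gauss-Lobatto panels stored up to order 10; ",
            "falling back to Gauss-Legendre", call. = FALSE)
    r <- .gl_cache(n)
    return(list(x = r$x, w = r$w))
  }
  stopifnot(n >= 2)
  if (n == 2) return(list(x = c(-1, 1), w = c(1, 1)))
  ## interior nodes: roots of P'_{n-1}; Chebyshev initial guess
  x <- cos(pi * (seq_len(n) - 1) / (n - 1))
  for (it in 1:100) {
    P <- .legendre_all(x, n - 1)
    Pm <- P[n, ]      # P_{n-1}
    Pm2 <- P[n - 1, ] # P_{n-2}
    ## Newton on q(x) = x*P_{n-1} - P_{n-2} (proportional to (1-x^2)P'_{n-1})
    xold <- x
    x <- xold - (x * Pm - Pm2) / (n * Pm)
    x[c(1, n)] <- c(1, -1)
    if (max(abs(x - xold)) < 1e-15) break
  }
  P <- .legendre_all(x, n - 1)
  w <- 2 / (n * (n - 1) * P[n, ]^2)
  o <- order(x)
  list(x = x[o], w = w[o])
}

## Legendre polynomials P_0..P_L at points x: matrix (L+1) x length(x)
.legendre_all <- function(x, L) {
  out <- matrix(0, L + 1, length(x))
  out[1, ] <- 1
  if (L >= 1) out[2, ] <- x
  if (L >= 2) {
    for (l in 2:L) {
      out[l + 1, ] <- ((2 * l - 1) * x * out[l, ] - (l - 1) * out[l - 1, ]) / l
    }
  }
  out
}

## composite Gauss-Legendre nodes/weights over the subintervals obtained by
## cutting [lo, hi] at the interior points of `cuts`; returns nodes, weights
## and the index of the subinterval each node belongs to
.panel_quad <- function(lo, hi, cuts, nq = 16) {
  edges <- sort(unique(c(lo, hi, cuts[cuts > lo & cuts < hi])))
  gl <- .gl_cache(nq)
  nodes <- weights <- numeric(0)
  panel <- integer(0)
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    nodes <- c(nodes, (gl$x + 1) / 2 * (b - a) + a)
    weights <- c(weights, gl$w / 2 * (b - a))
    panel <- c(panel, rep(i, nq))
  }
  list(x = nodes, w = weights, panel = panel, edges = edges)
}
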