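## Shared fixtures: small group structures and memoised libraries so the
## expensive generation steps run once per test session.

.fix_env <- new.env(parent = emptyenv())

fix_water <- function() nist_material("water")

## 30-group water library, P5 (cheap, used by several module tests)
fix_lib_small <- function() {
  if (is.null(.fix_env$lib_small)) {
    gs <- make_groups(1.0, 30)
    .fix_env$lib_small <- assemble_library("water", gs, L = 5)
  }
  .fix_env$lib_small
}

## coarse 3-group toy structure on [1 keV, 1 MeV]
fix_gs3 <- function(spacing = "log") make_groups(1.0, 3, spacing = spacing)

## brute-force trapezoid integration of f over [a, b]
trap <- function(f, a, b, n = 1e4) {
  x <- seq(a, b, length.out = n)
  sum((f(x)[-1] + f(x)[-n]) / 2 * diff(x))
}
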