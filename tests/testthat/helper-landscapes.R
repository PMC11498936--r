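## Shared fixtures: landscapes are expensive to build, so the heavy default
## ones are cached across test files.

.ef_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .ef_cache)) assign(key, builder(), envir = .ef_cache)
  get(key, envir = .ef_cache)
}

small_L <- function() {
  cached("small10", function() compute_landscape(mode = "small", A_p = 10))
}

large_L <- function(delta_p = 10) {
  L <- cached("large10", function()
    compute_landscape(mode = "large", A_p = 10,
                      phys = physical_params(delta_p_Pa = 10)))
  if (delta_p == 10) L else endofuse:::.with_delta_p(L, delta_p)
}

coarse_w <- function() seq(0, 0.6, by = 0.05)
coarse_a <- function() seq(0.02, 0.5, by = 0.04)

## analytic landscape object from a function f(w, a), for interpolation and
## gradient unit tests
synthetic_landscape <- function(f, w = seq(0, 0.6, by = 0.02),
                                a = seq(0.02, 0.5, by = 0.02)) {
  Fm <- outer(w, a, Vectorize(f))
  mask <- matrix(TRUE, length(w), length(a))
  L <- structure(list(w = w, a = a, F_kBT = Fm, E_kBT = Fm,
                      V_um3 = matrix(1, length(w), length(a)),
                      mask = mask, mode = "small",
                      phys = physical_params(), A_p = 10,
                      Gamma = neck_energy_scale(10)),
                 class = "fusion_landscape")
  L$F_fill <- endofuse:::.fill_masked(L$F_kBT, mask)
  L
}
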