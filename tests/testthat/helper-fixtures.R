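# Shared fixtures for the suite. The "standard" setup mirrors the package's
# reference conditions: a 60-residue helix target with a 10-member mixed
# helix/sheet library, potentials and profile derived from the library, and
# normalizers calibrated with 200 random sequences.

std <- local({
  lib <- make_library(10, seed = 1, n_res = 60)
  target <- make_helix(60, seed = 99)
  pot <- derive_potentials(lib)
  prof <- build_profile(target$structure, lib)
  model <- build_energy_model(target$structure, potentials = pot,
                              profile = prof, rng = mt_rng(1))
  list(lib = lib, target = target, pot = pot, prof = prof, model = model)
})

# A short cooling schedule for optimizer tests (109 levels x 100 iterations).
short_schedule <- function(iters = 100L) {
  sa_schedule(t_initial = 10, mu_t = 1.05, t_min = 0.05, iters_fixed_t = iters)
}

# Independent brute-force neighbour count (double loop, no dist()).
oracle_burial_counts <- function(st, radius = 14) {
  L <- st$L
  counts <- integer(L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      if (sqrt(sum((st$cb[i, ] - st$cb[j, ])^2)) < radius) {
        counts[i] <- counts[i] + 1L
      }
    }
  }
  counts
}
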