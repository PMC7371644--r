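# Shared small synthetic cohorts, built once per test run.

.cg_cache <- new.env(parent = emptyenv())

# Small default-effect cohort: 2 panels x 2 groups x 2 hemispheres x 3 animals.
tiny_cohort <- function() {
  if (is.null(.cg_cache$tiny)) {
    co <- simulate_cohort(
      cohort_design(n_events = 2000, beads_added = 1000),
      seed = 42)
    .cg_cache$tiny <- gate_cohort(prepare_cohort(co))
  }
  .cg_cache$tiny
}

# Zero-effect, exchangeable-event cohort (no animal intercepts), M1 only.
tiny_null_cohort <- function(seed = 7, n_events = 1500) {
  co <- simulate_cohort(
    cohort_design(n_events = n_events, beads_added = 500, panels = "M1"),
    effects = null_effects("M1"), seed = seed, animal_sigma = 0)
  suppressWarnings(gate_cohort(prepare_cohort(co)))
}

one_sample <- function(seed = 5, n_events = 4000, ...) {
  simulate_sample(n_events = n_events, beads_added = 1000, seed = seed, ...)
}
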