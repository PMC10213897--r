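# Shared, lazily computed simulation fixtures. The full five-food pipeline
# takes a few seconds; computing it once and reusing it keeps the suite fast.

.sim_cache <- new.env(parent = emptyenv())

full_sim <- function(n_steps = 200) {
  key <- paste0("sim", n_steps)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_chewing(n_steps = n_steps)
  }
  .sim_cache[[key]]
}

one_food_sim <- function(food = "d", n_steps = 100) {
  key <- paste0("one", food, n_steps)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_chewing(food, n_steps = n_steps)
  }
  .sim_cache[[key]]
}

default_anatomy <- function() {
  if (is.null(.sim_cache$anatomy)) .sim_cache$anatomy <- build_default_anatomy()
  .sim_cache$anatomy
}
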