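# shared fixtures: the two experimental growth conditions and small
# synthetic populations reused across test files (built once per run)

cond_slow <- function() growth_condition(122, 70, 40)
cond_fast <- function() growth_condition(29, 53, 25)

# cached populations so expensive generation runs once per test session
pop_cache <- new.env(parent = emptyenv())

slow_population <- function() {
  if (is.null(pop_cache$slow)) {
    pop_cache$slow <- generate_population(synth_config(seed = 421))
  }
  pop_cache$slow
}

fast_population <- function() {
  if (is.null(pop_cache$fast)) {
    pop_cache$fast <- generate_population(synth_config_fast(seed = 422))
  }
  pop_cache$fast
}

fast_profiles <- function() {
  if (is.null(pop_cache$fast_prof)) {
    pop_cache$fast_prof <- generate_profiles(fast_population())
  }
  pop_cache$fast_prof
}

# draw n values with exactly the requested mean and sd (moment matching)
moment_matched_sample <- function(n, mean, sd) {
  x <- rnorm(n)
  mean + sd * (x - mean(x)) / stats::sd(x)
}
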