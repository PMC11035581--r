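# Shared fixtures: cheap deterministic swings reused across test files.

ideal_spec <- function(...) {
  swing_spec(noise = c(0, 0), accel_bias = c(0, 0, 0),
             gyro_bias = c(0, 0, 0), clipping_enabled = FALSE, seed = 1L,
             ...)
}

# memoized default swings (generation ~0.1 s each, reused many times)
local_cache <- new.env(parent = emptyenv())

cached_swing <- function(name, spec_fun) {
  if (is.null(local_cache[[name]]))
    local_cache[[name]] <- generate_swing(spec_fun())
  local_cache[[name]]
}

ideal_swing <- function() cached_swing("ideal", ideal_spec)
planar_swing <- function()
  cached_swing("planar", function() ideal_spec(out_of_plane_amplitude = 0))
noisy_swing <- function()
  cached_swing("noisy", function() swing_spec(seed = 99L))

q_add_true <- function(sw)
  quaternion(sw$truth$orientation$q[sw$truth$events[["add"]], ],
             normalize = FALSE)

random_quat <- function() quaternion(stats::rnorm(4))

unit3_test <- function(v) v / sqrt(sum(v^2))
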