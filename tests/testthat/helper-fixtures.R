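# Lazily built, cached fixtures shared across test files (the canonical
# pose solve is the expensive step; build it once per test run).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

native_model <- function() fixture("native_model", function()
  make_model("CPS224Ac", "native"))

native_pose <- function() fixture("native_pose", function()
  generate_canonical_pose(native_model(), c(2, 3, 4)))

small_ensemble <- function() fixture("small_ensemble", function()
  generate_pose_ensemble(native_pose(), n = 120, seed = 11))
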