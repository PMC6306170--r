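# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# A medium-sized default-parameter session reused across test files.
cached_session <- function() {
  if (is.null(.fixture_env$session)) {
    .fixture_env$session <- simulate_session(seed = 7, n_wake = 10,
                                             n_nrem = 30, n_rem = 20)
  }
  .fixture_env$session
}

# Independent coordinate oracle for the point-source potential (volts).
oracle_potential <- function(current, sigma, source_pos, point) {
  current / (4 * pi * sigma * sqrt(sum((source_pos - point)^2)))
}

# Sample indices covered by the epochs of one state.
state_indices <- function(session, state) {
  fs <- session$fs
  ep <- epochize(session, state)
  unlist(lapply(seq_len(nrow(ep)), function(i) {
    (round(ep$start[i] * fs) + 1):(round(ep$start[i] * fs) +
                                     round(ep$duration[i] * fs))
  }))
}
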