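# Shared fixtures: simulations are cheap but several tests reuse the same
# runs, so cache them per test session.
.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .fixture_env))
    assign(name, force(expr), .fixture_env)
  get(name, .fixture_env)
}

# two-test-lung, normal chest wall: the reference arm
ref_config <- function() cached("ref_config", make_default_config(2, "normal"))

# steady ventilation at ZEEP then a 0 -> 8.4 cmH2O PEEP step (25 + 25 breaths)
ref_step_run <- function() cached("ref_step_run", {
  wf <- simulate_breaths(ref_config(), rep(c(0, 8.4), each = 25))
  list(wf = wf, breaths = segment_breaths(wf))
})

# full six-arm study at the bench's measured PEEP steps, noise-free
ref_study <- function() cached("ref_study", run_peep_step_study())

ref_incremental <- function() cached("ref_incremental", incremental_peep_study())
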