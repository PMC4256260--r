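# Simulated datasets shared across test files, built once per run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, maker) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, maker(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# default study conditions, moderate replicate noise
default_fixture <- function() {
  cached("default", function() simulate_dataset(sim_config(seed = 42L)))
}

# noise-free replicate FPKM (absent draws still sample the boundary)
noisefree_fixture <- function() {
  cached("noisefree", function() {
    simulate_dataset(sim_config(
      fpkm_lognormal_mu_sigma = c(log(20), 0), seed = 101L))
  })
}

# near-noise-free: for checks involving the t-test on both assay arms,
# where exactly constant replicates make the test undefined by design
tiny_noise_fixture <- function() {
  cached("tinynoise", function() {
    simulate_dataset(sim_config(
      fpkm_lognormal_mu_sigma = c(log(20), 1e-3), seed = 202L))
  })
}

# tiny quant table builder for threshold tests
quant_row <- function(tx, gene, cond, vals) {
  tibble::tibble(transcript_id = tx, gene_id = gene, condition = cond,
                 replicate = seq_along(vals), fpkm = vals)
}

run_event_pipeline <- function(sim, origin = "five_prime") {
  std <- select_standard_form(sim$quant, sim$config$conditions[1])
  uq <- call_unique_isoforms(sim$quant, sim$config$conditions[2],
                             sim$config$conditions[1])  # returns both directions
  ev <- call_splice_events(uq, std, sim$sequences, sim$models,
                           origin = origin)
  list(standards = std, unique_calls = uq, events = ev)
}
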