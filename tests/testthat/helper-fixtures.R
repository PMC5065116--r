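# Shared fixtures. The tiny config keeps module-level tests fast; the
# full-scale default run (used by the recovery checks) is generated once per
# session and memoized.

tiny_config <- function(seed = 42L, ...) {
  defaults <- list(seed = seed, reads_per_sample = 1500L,
                   n_common_compatible = 3L, n_common_incompatible = 2L,
                   n_unique_per_pair = 1L,
                   n_background = 10L, n_novel = 2L,
                   n_host_transcripts = 10L, n_host_novel = 2L,
                   n_mycelium = 2L, n_control = 1L,
                   n_rrna = 2L, rrna_len = 400L, n_16s = 2L, s16_len = 400L,
                   cds_len_aa = 100L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_panel <- function() cached("tiny_panel",
                                generate_reference_panel(tiny_config()))

# full study-condition run (default sim_config, seed 1): shared by the
# recovery tests so the pipeline executes once
default_run <- function() cached("default_run", {
  # one species has no incompatible pairing; the quantifier warning is
  # expected under the bundled design
  suppressWarnings(
    run_pipeline(pipeline_config(simulate = sim_config(seed = 1L),
                                 log_level = "quiet")))
})

table1_path <- function() system.file("extdata", "design_suillus_pinus.tsv",
                                      package = "symbiotrx", mustWork = TRUE)
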