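# Shared small fixtures and configurations. Everything is generated in code;
# graphs are tiny so the whole suite stays fast.

tiny_cfg <- function(hidden = 8L, ta = 2L) encoder_config(hidden, ta)

# A deterministic small covered fixture set shared across tests.
shared_fixtures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixtures(fixture_spec(
        n = 20L, seed = 7L, mix = c(BF = 0.5, BC = 0.2, A = 0.3, UNCOVERED = 0)))
    }
    cache
  }
})

shared_records <- function() lapply(shared_fixtures(), `[[`, "record")

shared_vocab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_vocabulary(shared_records())
    cache
  }
})

# Hand-built amide coupling reaction used in many examples.
amide_rxn <- paste0("[CH3:1][C:2](=[O:3])[OH:4].[NH2:5][CH3:6]",
                    ">>[CH3:1][C:2](=[O:3])[NH:5][CH3:6]")

zero_params <- function(params) lapply(params, function(p) p * 0)
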