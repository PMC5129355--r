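# Shared fixtures: model-term declarations for the generator's covariates
# (10 inner knots keep the test fits quick; the science is unchanged) and
# one cached geoadditive fit reused across test files.

sim_terms <- function(graph, inner_knots = 10L) {
  model_terms(
    fixed = list(fixed_term("sex", c("female", "male")),
                 fixed_term("iron", c("no", "yes")),
                 fixed_term("literate", c("no", "yes"))),
    smooth = list(pspline_term("mage", inner_knots = inner_knots),
                  pspline_term("mbmi", inner_knots = inner_knots),
                  pspline_term("mweight", inner_knots = inner_knots)),
    spatial = spatial_terms(graph))
}

.fixture_env <- new.env(parent = emptyenv())

cached_m3_fit <- function() {
  if (is.null(.fixture_env$m3)) {
    ds <- simulate_dataset(simulation_spec(n_obs = 2500, seed = 42))
    fit <- fit_cumulative(ds$data, sim_terms(ds$graph))
    .fixture_env$m3 <- list(ds = ds, fit = fit)
  }
  .fixture_env$m3
}
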