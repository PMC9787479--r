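# Shared reduced-scale preset runs, computed once per test session.
#
# Formose and pyruvic run at mass cap 100 AMU; glucose degradation and the
# Maillard network carry a 180 AMU seed (open-chain glucose) and therefore
# run at the full 200 AMU cap with fewer generations.
preset_run_scales <- list(
  formose = list(generations = 4L, mass_cap = 100L),
  pyruvic = list(generations = 4L, mass_cap = 100L),
  glucose_degradation = list(generations = 2L, mass_cap = 200L),
  maillard = list(generations = 2L, mass_cap = 200L)
)

.net_cache <- new.env(parent = emptyenv())

cached_net <- function(preset, iron) {
  key <- paste(preset, iron)
  if (is.null(.net_cache[[key]])) {
    sc <- preset_run_scales[[preset]]
    .net_cache[[key]] <- expand(preset_config(
      preset, with_iron = iron,
      generations = sc$generations, mass_cap = sc$mass_cap))
  }
  .net_cache[[key]]
}

cached_toy <- function(kind, ...) {
  key <- paste("toy", kind, ...)
  if (is.null(.net_cache[[key]]))
    .net_cache[[key]] <- make_toy_system(kind, ...)
  .net_cache[[key]]
}

event_generations <- function(net) {
  vapply(net$events, `[[`, 0L, "generation")
}

# cumulative event counts at generations 1..G
cumulative_events <- function(net, gmax) {
  cumsum(tabulate(event_generations(net), nbins = gmax))
}
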