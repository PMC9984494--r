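# Shared synthetic worlds, built once per test run and memoised. Sizes are
# chosen to keep the default suite fast while leaving enough data for the
# statistical checks.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# 20 cells x 30 years under generator defaults (10% penalty, stationary
# event probability with yearly clustering)
world_small <- function() {
  fixture("small", function() {
    cfg <- synth_config(n_cells = 20, n_years = 30, seed = 42)
    ds <- generate_dataset(cfg)
    ind <- compute_indicators(ds$weather, ds$calendar)
    fm <- standardize_features(ind, detrend_yield(ds$yields))
    list(cfg = cfg, ds = ds, ind = ind, fm = fm)
  })
}

# 200 cells x 30 years at the generator defaults; the scale used for the
# model-skill and impact-recovery checks. Because the latent flags and
# weather do not depend on the yield penalty, the indicator table is shared
# across penalty variants and only yields/features are rebuilt.
world_big <- function() {
  fixture("big", function() {
    cfg <- synth_config(n_cells = 200, n_years = 30, seed = 101)
    ds <- generate_dataset(cfg)
    ind <- compute_indicators(ds$weather, ds$calendar)
    fm <- standardize_features(ind, detrend_yield(ds$yields))
    list(cfg = cfg, ds = ds, ind = ind, fm = fm)
  })
}

world_big_penalty <- function(penalty) {
  w <- world_big()
  if (penalty == w$cfg$hotdry_penalty) return(w$fm)
  cfg <- w$cfg
  cfg$hotdry_penalty <- penalty
  yields <- generate_yields(w$ds$truth, cfg)
  standardize_features(w$ind, detrend_yield(yields))
}
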