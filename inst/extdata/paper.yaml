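# Reference analysis configuration: the four PGLS models of the package's
# worked example.  Edit or extend the roster without touching code; pass
# the file to read_config() or to the command-line tool via --config.
lambda: ML
# lift:            # uncomment and fill in to enable load-capacity output
#   a: 0.0         # intercept of log10(max liftable mass, g)
#   b: 1.0         # slope on log10(flight muscle mass, g)
models:
  - name: fmr_model
    response: fmr
    log10_response: false
    predictors: [manipulation, body_mass_g]
    log10_predictors: [body_mass_g]
  - name: wl_model
    response: wing_loading_g_cm2
    log10_response: true
    predictors: [manipulation, body_mass_g]
    log10_predictors: [body_mass_g]
  - name: wasp_fmr_model
    response: fmr
    log10_response: false
    predictors: [manipulation, body_mass_g]
    log10_predictors: [body_mass_g]
    subset: "diet == 'prey'"
    var_group: manipulation
  - name: covariation_model
    response: wing_loading_g_cm2
    log10_response: true
    predictors: [fmr, body_mass_g]
    log10_predictors: [body_mass_g]
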