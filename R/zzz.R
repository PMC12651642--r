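.onLoad <- function(libname, pkgname) {
  register_model_backend("random_forest", rf_backend)
  register_model_backend("extreme_gradient_boosting", xgb_backend)
}
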