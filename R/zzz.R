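.onLoad <- function(libname, pkgname) {
  register_backend("synthetic",
                   function(...) synthetic_provider(synthetic_spec(...)))
}
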