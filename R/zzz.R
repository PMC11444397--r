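.onLoad <- function(libname, pkgname) {
  registerFoldBackend("nussinov", function(s) {
    res <- cpp_nussinov(as.character(s))
    list(structure = res$structure, score = -res$weight)
  })
}
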