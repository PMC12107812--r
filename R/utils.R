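# Logging and load-time hooks.

.log_info <- function(...) {
  if (isTRUE(getOption("moldesirer.verbose", FALSE))) message(...)
  invisible(NULL)
}

#' @importFrom utils head read.delim write.table
#' @importFrom stats median prcomp density dist rnorm
NULL

.onLoad <- function(libname, pkgname) {
  registerScorerBackend("surrogate", .surrogate_backend)
  registerScorerBackend("vina", .vina_backend)
  invisible(NULL)
}
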