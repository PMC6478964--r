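# Session-level memoization. Fixation results are keyed by canonical graph6
# string together with (r, rule), so isomorphic graphs are never solved twice;
# enumeration results are keyed by size.
.evo_cache <- new.env(parent = emptyenv())

cache_env <- function(name) {
  e <- get0(name, envir = .evo_cache, inherits = FALSE)
  if (is.null(e)) {
    e <- new.env(parent = emptyenv())
    assign(name, e, envir = .evo_cache)
  }
  e
}

#' Clear evograph's in-session caches
#'
#' Drops memoized enumeration lists, canonical labels and solver results.
#' Mainly useful to bound memory in very long sessions; results are
#' deterministic, so clearing never changes any value.
#'
#' @return `NULL`, invisibly.
#' @export
evo_cache_clear <- function() {
  rm(list = ls(.evo_cache), envir = .evo_cache)
  invisible(NULL)
}
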