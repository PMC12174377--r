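#' @keywords internal
"_PACKAGE"

# Deterministic substream seeds: one master seed, per-block seeds derived by
# counter so any single block can be regenerated without replaying the study.
# Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1L, master >= 0)
  as.integer((as.double(master) * 48271 + as.double(counter) * 7919 + 1) %%
               2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

tb_log <- function(...) {
  if (isTRUE(getOption("tacsbeta.verbose", FALSE))) {
    message("[tacsbeta] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
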