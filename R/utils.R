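#' @importFrom rlang .data %||%
#' @importFrom generics tidy glance
#' @keywords internal
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

# evaluate `expr` with the RNG seeded by `seed`, restoring global RNG state
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
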