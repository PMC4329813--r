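# Internal helpers shared across modules.

clip01 <- function(x) pmin(pmax(x, 0), 1)

octaves_between <- function(f1, f2) log2(f1 / f2)

#' Derive reproducible child seeds from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the master
#' seed, so any stage can be regenerated in isolation from the manifest.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 1)`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)
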