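#' @keywords internal
"_PACKAGE"

#' @importFrom stats rpois runif rbinom rnbinom rnorm rgamma rmultinom
#'   median cor lm predict coef optimize setNames
#' @importFrom utils read.csv write.csv write.table packageVersion head tail
#' @importFrom graphics par
#' @importFrom grDevices n2mfrow
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` with a locally-set RNG seed, restoring the caller's RNG
## state afterwards so package functions do not clobber the user's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Derive a stage seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629L)
}

## FNV-1a 32-bit hash of a character scalar, as 8 hex digits.  Used for
## provenance headers (config fingerprint); not cryptographic.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low 8 bits; keep the value in double to stay
    ## within 32-bit unsigned range without integer overflow
    hi <- h - h %% 256
    h <- hi + bitwXor(as.integer(h %% 256), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

marker_name <- function(contig, pos) paste0(contig, "@", pos)

stop_arg <- function(...) stop(..., call. = FALSE)
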