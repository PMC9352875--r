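#' @importFrom stats pbinom runif setNames aggregate
#' @importFrom utils adist head tail read.table write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so package functions that
#' need reproducible draws do not disturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return Value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## derive a stream-specific seed below 2^31 from a master seed
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## half-open interval intersection test on 0-based coordinates
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

## empty variant rejection/removal log
empty_log <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), reason = character(), stringsAsFactors = FALSE)
}

log_entry <- function(vt, reason) {
  if (nrow(vt) == 0) return(empty_log())
  data.frame(contig = vt$contig, pos = vt$pos, ref = vt$ref, alt = vt$alt,
             reason = rep_len(reason, nrow(vt)), stringsAsFactors = FALSE)
}
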