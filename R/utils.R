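#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream index, staying in
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 1103L + as.double(stream) * 12289L) %% 2147483629)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Sum values sharing a name into one entry per name.
collapse_named <- function(x) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  tapply_res <- tapply(x, names(x), sum)
  stats::setNames(as.numeric(tapply_res), names(tapply_res))
}

abort_input <- function(...) stop(paste0(...), call. = FALSE)
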