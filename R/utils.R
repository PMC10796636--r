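# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Deterministic sub-seed derivation; keeps results invariant to unit ordering
# (keyed by id, not position) and within 32-bit integer range.
derive_seed <- function(root, ...) {
  ks <- c(root, ...)
  s <- 0
  for (k in ks) s <- (s * 69069 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# spikes falling in the half-open window [t0, t1)
count_in_window <- function(spikes, t0, t1) sum(spikes >= t0 & spikes < t1)

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

BRAIN_AREAS <- c("Hipp", "Amg", "dACC", "preSMA", "vmPFC", "other")
MTL_AREAS <- c("Hipp", "Amg")
MFC_AREAS <- c("dACC", "preSMA", "vmPFC")

STERNBERG_CODES <- c(61L, 11L, 1L, 2L, 3L, 5L, 6L, 7L, 8L, 60L)
SCREENING_CODES <- c(61L, 1L, 3L, 4L, 60L)
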