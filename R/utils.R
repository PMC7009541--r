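#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a base seed and an index, staying below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587L) + 1L
}

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten voxel coordinates (1-based) to linear index for a given grid.
vox_index <- function(coords, grid) {
  coords <- matrix(coords, ncol = 3)
  coords[, 1] + (coords[, 2] - 1) * grid[1] + (coords[, 3] - 1) * grid[1] * grid[2]
}
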