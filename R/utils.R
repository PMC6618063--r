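# Internal helpers shared across modules.

# Gyromagnetic ratio of 1H over 2*pi, expressed so that a gradient in mT/m
# advances k (cycles/mm) at GAMMA_BAR per ms: gamma/2pi = 42.577478518 MHz/T.
GAMMA_BAR <- 0.042577478518

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package funnel
# through this so that seeds given in configs are the only entropy source.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Voxel-center coordinates (mm) along one axis: n voxels of size delta,
# half-open convention, centers at (i + 0.5)*delta - FOV/2 for 0-based i.
axis_coords <- function(n, delta) {
  ((seq_len(n) - 1) + 0.5) * delta - n * delta / 2
}

# Centered 2D DFT helpers on the half-voxel-offset grid are implemented at
# the call sites (recon) where the phase bookkeeping lives; here only the
# generic fftshift.
fftshift <- function(x) {
  n <- length(x)
  c(x[(floor(n / 2) + 1):n], x[1:floor(n / 2)])
}

stop_ctx <- function(..., class) {
  stop(structure(class = c(class, "spiral4d_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(cond, msg, class = "spiral4d_invalid") {
  if (!isTRUE(cond)) stop_ctx(msg, class = class)
  invisible(TRUE)
}
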