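#' Derive a reproducible child seed from a master seed
#'
#' All stochastic operations in the package draw their randomness from seeds
#' derived deterministically from a single master seed, so that an entire run
#' is reproducible from one integer.
#'
#' @param master integer master seed.
#' @param k integer stream index (>= 0).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, k = 0L) {
  # Lehmer-style mixing in double precision; exact below 2^53 so the
  # modular arithmetic is reproducible across platforms.
  m <- 2147483647
  x <- (abs(as.double(master)) %% m) + 1
  for (i in seq_len(2 + (k %% 7))) {
    x <- (x * 48271 + as.double(k) * 16807 + 12345) %% m
  }
  as.integer(x %% (m - 2) + 1)
}

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library internals never perturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopifnot_finite <- function(x, what = "values") {
  if (!all(is.finite(x))) stop("non-finite ", what, " encountered", call. = FALSE)
  invisible(TRUE)
}

#' Write an R object as pretty JSON
#' @param x object. @param path file path.
#' @return `path`, invisibly.
#' @keywords internal
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
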