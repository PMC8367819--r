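# internal helpers shared across modules

# Deterministic child seed from (seed, stream labels). Keeps every model /
# fold / purpose on an independent stream so adding a classifier to the
# registry does not perturb the randomness of the others. Plain polynomial
# hash mod a Mersenne prime; all intermediates stay below 2^53 so doubles
# are exact.
childSeed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("|", as.character(part)))) {
      h <- (h * 31 + ch) %% 2147483647
    }
  }
  as.integer(h)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-stochastic guard used by every probability producer
stopifnotProb <- function(p, tol = 1e-6) {
  if (any(p < -tol) || any(abs(rowSums(p) - 1) > tol)) {
    stop("probability rows must be nonnegative and sum to 1")
  }
  invisible(p)
}

# column-major recycling versions of sweep(A, 2, v, op); several times
# faster in hot training loops (sweep pays for aperm)
addCols <- function(A, v) A + rep(v, each = nrow(A))
subCols <- function(A, v) A - rep(v, each = nrow(A))
divCols <- function(A, v) A / rep(v, each = nrow(A))
mulCols <- function(A, v) A * rep(v, each = nrow(A))
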