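# Internal helpers shared across modules.

# Tissue label codes used throughout: 0 = outside, 1 = scalp, 2 = skull,
# 3 = CSF, 4 = gray matter, 5 = white matter.
TISSUE_LABELS <- c(scalp = 1L, skull = 2L, csf = 3L, gray = 4L, white = 5L)

tissue_name <- function(label) {
  out <- rep(NA_character_, length(label))
  out[label == 0L] <- "outside"
  m <- match(label, TISSUE_LABELS)
  out[!is.na(m)] <- names(TISSUE_LABELS)[m[!is.na(m)]]
  out
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

vnorm <- function(x) sqrt(sum(x^2))

unit_vec <- function(x) {
  n <- vnorm(x)
  if (n == 0) stop("cannot normalize a zero vector")
  x / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name))
  invisible(x)
}
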