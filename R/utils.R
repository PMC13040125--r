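#' @useDynLib usradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate binomial chisq.test coef cor fisher.test glm
#'   loess median optim pbinom pnorm predict quantile rbinom rgamma rnorm
#'   rpois runif sd setNames step t.test var
#' @importFrom utils combn read.csv write.csv head
NULL

# Classed errors so callers (and tests) can distinguish failure modes.
usr_stop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "usr_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

usr_warn <- function(msg) warning(msg, call. = FALSE)

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' user-supplied seed and the stage name, so stages are independently
#' reproducible and adding a stage never perturbs the draws of another.
#' The result is kept strictly below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483629 + 1)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Symmetric (reflective) padding of a matrix by r rows/cols on each side.
pad_sym <- function(m, rpad, cpad = rpad) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rev(seq_len(min(rpad, nr))), seq_len(nr),
          nr + 1 - seq_len(min(rpad, nr)))
  ci <- c(rev(seq_len(min(cpad, nc))), seq_len(nc),
          nc + 1 - seq_len(min(cpad, nc)))
  m[ri, ci, drop = FALSE]
}

# Separable 2D convolution with symmetric border padding.
conv_sep <- function(m, kern) {
  r <- (length(kern) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_sym(m, r, r)
  out <- matrix(0, nr + 2L * r, nc + 2L * r)
  # rows
  for (j in seq_along(kern)) {
    sh <- j - 1L - r
    out[(1L + r):(nr + r), ] <- out[(1L + r):(nr + r), ] +
      kern[j] * p[(1L + r + sh):(nr + r + sh), , drop = FALSE]
  }
  p2 <- out
  out <- matrix(0, nr, nc)
  for (j in seq_along(kern)) {
    sh <- j - 1L - r
    out <- out + kern[j] * p2[(1L + r):(nr + r), (1L + r + sh):(nc + r + sh),
                              drop = FALSE]
  }
  out
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  conv_sep(m, gaussian_kernel(sigma))
}

# Local window mean with an rk x ck box, symmetric padding (used by Wiener).
box_mean <- function(m, rk, ck) {
  rr <- (rk - 1L) %/% 2L; cr <- (ck - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_sym(m, rr, cr)
  acc <- matrix(0, nr, nc)
  for (i in seq_len(rk)) {
    for (j in seq_len(ck)) {
      acc <- acc + p[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
    }
  }
  acc / (rk * ck)
}

# Normal draws truncated below (rejection sampling; tails here are mild).
rnorm_trunc_min <- function(n, mean, sd, min) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(n - length(out), mean, sd)
    out <- c(out, x[x >= min])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
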