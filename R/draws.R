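#' Halton sequences and quasi-random normal draws
#'
#' `halton_sequence()` returns the raw (optionally digit-scrambled) Halton
#' points in (0, 1); `halton_draws()` wraps it into the standard-normal
#' draw matrix used by maximum simulated likelihood: one prime base per
#' dimension, the first `skip` points discarded, digit-permutation
#' scrambling (permutations fixing 0, drawn reproducibly from `seed`), and
#' an inverse normal CDF transform.  Rows are grouped by respondent:
#' respondent `i` owns rows `(i-1)*n_draws + 1:n_draws`.
#'
#' @param n Number of points.
#' @param n_dims Number of dimensions (at most 25).
#' @param skip Leading points to discard (burn-in), default 50.
#' @param scramble Apply digit-permutation scrambling?
#' @param seed Integer seed for the scrambling permutations.
#' @param n_respondents,n_draws Rows of the draw matrix are
#'   `n_respondents * n_draws`.
#' @return `halton_sequence()`: an `n` x `n_dims` matrix in (0, 1);
#'   `halton_draws()`: an `(n_respondents * n_draws)` x `n_dims` matrix of
#'   standard-normal quasi-random draws.
#' @export
#' @examples
#' halton_sequence(3, 1, skip = 0, scramble = FALSE)  # 1/2, 1/4, 3/4
halton_sequence <- function(n, n_dims, skip = 50L, scramble = TRUE,
                            seed = 1L) {
  primes <- c(2L, 3L, 5L, 7L, 11L, 13L, 17L, 19L, 23L, 29L, 31L, 37L,
              41L, 43L, 47L, 53L, 59L, 61L, 67L, 71L, 73L, 79L, 83L,
              89L, 97L)
  if (n_dims > length(primes))
    stop("at most ", length(primes), " Halton dimensions supported",
         call. = FALSE)
  perms <- NULL
  if (scramble) {
    perms <- with_local_seed(seed, lapply(primes[seq_len(n_dims)],
      function(b) {
        # permutation of digits 0..b-1 fixing 0 (finite expansions stay valid)
        if (b == 2L) c(0L, 1L) else c(0L, sample(seq_len(b - 1L)))
      }))
  }
  idx <- skip + seq_len(n)
  out <- matrix(0, n, n_dims)
  for (d in seq_len(n_dims)) {
    out[, d] <- radical_inverse(idx, primes[d],
                                if (scramble) perms[[d]] else NULL)
  }
  out
}

#' @rdname halton_sequence
#' @param antithetic Pair every draw with its mirror image (`-z`)?  The
#'   first half of each respondent's rows are base points, the second half
#'   their negations; `n_draws` must then be even.  Antithetic pairs
#'   reduce both the variance and the Jensen bias of the simulated
#'   likelihood at a given draw budget.
#' @export
halton_draws <- function(n_respondents, n_draws, n_dims, seed = 1L,
                         skip = 50L, scramble = TRUE, antithetic = FALSE) {
  if (antithetic) {
    if (n_draws %% 2L != 0L)
      stop("antithetic draws require an even n_draws", call. = FALSE)
    half <- n_draws %/% 2L
    u <- halton_sequence(n_respondents * half, n_dims, skip = skip,
                         scramble = scramble, seed = seed)
    zh <- stats::qnorm(u)
    z <- matrix(0, n_respondents * n_draws, n_dims)
    for (i in seq_len(n_respondents)) {
      src <- (i - 1L) * half + seq_len(half)
      dst <- (i - 1L) * n_draws
      z[dst + seq_len(half), ] <- zh[src, , drop = FALSE]
      z[dst + half + seq_len(half), ] <- -zh[src, , drop = FALSE]
    }
  } else {
    u <- halton_sequence(n_respondents * n_draws, n_dims, skip = skip,
                         scramble = scramble, seed = seed)
    z <- stats::qnorm(u)
  }
  structure(z, n_respondents = n_respondents, n_draws = n_draws,
            seed = seed, antithetic = antithetic)
}

#' Modified Latin hypercube draws for panel simulation
#'
#' Per-respondent stratified uniforms: for each respondent and dimension,
#' a randomly shifted, randomly permuted grid `(perm(0:(R-1)) + shift)/R`
#' transformed to standard normal.  Unlike consecutive blocks of a Halton
#' sequence, every respondent's draw set covers each dimension evenly —
#' which matters for the per-respondent probability integrals of a panel
#' mixed logit when the draw count is small.  Rows are grouped by
#' respondent as in [halton_draws()].
#'
#' @inheritParams halton_sequence
#' @return An `(n_respondents * n_draws)` x `n_dims` standard-normal draw
#'   matrix.
#' @export
mlhs_draws <- function(n_respondents, n_draws, n_dims, seed = 1L) {
  z <- with_local_seed(seed, {
    out <- matrix(0, n_respondents * n_draws, n_dims)
    grid <- seq_len(n_draws) - 1L
    for (i in seq_len(n_respondents)) {
      rows <- (i - 1L) * n_draws + seq_len(n_draws)
      for (d in seq_len(n_dims)) {
        u <- (sample(grid) + stats::runif(1)) / n_draws
        out[rows, d] <- stats::qnorm(u)
      }
    }
    out
  })
  structure(z, n_respondents = n_respondents, n_draws = n_draws,
            seed = seed)
}

radical_inverse <- function(idx, base, perm = NULL) {
  r <- numeric(length(idx))
  f <- 1 / base
  i <- idx
  while (any(i > 0L)) {
    d <- i %% base
    if (!is.null(perm)) d <- perm[d + 1L]
    r <- r + f * d
    i <- i %/% base
    f <- f / base
  }
  r
}

# reshape a draw matrix into the R x D x N cube expected by the C++ kernel
draws_to_cube <- function(z, n_respondents, n_draws, dims) {
  D <- length(dims)
  cube <- array(0, dim = c(n_draws, D, n_respondents))
  for (i in seq_len(n_respondents)) {
    rows <- (i - 1L) * n_draws + seq_len(n_draws)
    cube[, , i] <- z[rows, dims, drop = FALSE]
  }
  cube
}

# run code under a temporary RNG seed, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
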