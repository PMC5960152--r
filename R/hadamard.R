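#' Hadamard sign matrix for balanced half-sample designs
#'
#' Constructs an `n` x `n` matrix of +1/-1 with mutually orthogonal columns,
#' row-normalized so the first column is all +1. Orders are reached by the
#' Paley construction (when `n - 1` is a prime congruent to 3 mod 4) and by
#' Sylvester doubling from orders 1 and 2; multiples of 4 outside that closure
#' (the smallest is 28) are rejected.
#'
#' Columns 2..n serve as stratum patterns in [simulate_replicate_weights()]:
#' each column sums to zero (it is orthogonal to the all-ones first column),
#' which is exactly the balance property replicate weights need.
#'
#' @param n Order; 1, 2, or a multiple of 4.
#' @return An `n` x `n` matrix with entries in `{-1, 1}` satisfying
#'   `H %*% t(H) == n * diag(n)`.
#' @export
hadamard_matrix <- function(n) {
  h <- hadamard_build(n)
  if (is.null(h)) {
    abort(paste0("no Hadamard construction available for order ", n,
                 " (need 1, 2, or a Paley/Sylvester-reachable multiple of 4)."))
  }
  # flip rows so the first column is +1 everywhere
  h * sign(h[, 1])
}

hadamard_build <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  if (n == 2) return(matrix(c(1, 1, 1, -1), 2, 2))
  if (n < 4 || n %% 4 != 0) return(NULL)
  q <- n - 1
  if (is_prime(q) && q %% 4 == 3) return(hadamard_paley(q))
  if (n %% 2 == 0) {
    h <- hadamard_build(n / 2)
    if (!is.null(h)) return(kronecker(matrix(c(1, 1, 1, -1), 2, 2), h))
  }
  NULL
}

is_prime <- function(q) {
  if (q < 2) return(FALSE)
  if (q < 4) return(TRUE)
  if (q %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= q) {
    if (q %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

# Paley I: q prime, q = 3 (mod 4); order q + 1 via the quadratic-residue
# (Jacobsthal) matrix.
hadamard_paley <- function(q) {
  res <- unique((seq_len(q - 1)^2) %% q)
  chi <- integer(q)           # chi[x + 1] for x in 0..q-1
  chi[res + 1] <- 1L
  chi[setdiff(1:(q - 1), res) + 1] <- -1L
  idx <- outer(0:(q - 1), 0:(q - 1), function(i, j) (i - j) %% q)
  Q <- matrix(chi[idx + 1], q, q)
  S <- rbind(c(0, rep(1, q)), cbind(rep(-1, q), Q))
  S + diag(q + 1)
}
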