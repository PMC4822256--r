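# internal helpers shared across modules

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
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

# Dirichlet draws via independent gammas; rows sum to 1 exactly.
rdirichlet <- function(n, alpha) {
  stopifnot(all(alpha > 0))
  g <- matrix(rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

# Scale a vector to a target standard deviation; zero-variance input stays zero.
scale_to_sd <- function(x, target_sd) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s * target_sd
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
}
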