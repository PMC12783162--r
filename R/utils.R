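logit <- function(p) log(p) - log1p(-p)

inv_logit <- function(x) plogis(x)

## central-difference gradient of a scalar function; step scaled to |x|
num_grad <- function(f, x, eps = 1e-6) {
  g <- numeric(length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    g[j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Bernoulli log pmf with NA occasions contributing 0, computed stably.
## h, p are conformable matrices (sites x occasions).
bern_logsum <- function(h, p) {
  ll <- h * log(p) + (1 - h) * log1p(-p)
  ll[is.na(ll)] <- 0
  rowSums(ll)
}
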