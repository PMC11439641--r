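# Small neural-network toolbox: parameter initialisation, activations, and
# an Adam optimiser operating on nested lists of numeric arrays. All
# randomness flows through R's RNG so seeded runs are bit-reproducible.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Derivative mask of relu evaluated at pre-activation z.
drelu <- function(z) (z > 0) * 1

# Numerically stable softplus log(1 + exp(x)).
softplus <- function(x) {
  out <- pmax(x, 0) + log1p(exp(-abs(x)))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

activation_fun <- function(name) {
  switch(name,
    relu = relu,
    identity = identity,
    tanh = tanh,
    stop("unknown activation: ", name)
  )
}

activation_grad <- function(name) {
  switch(name,
    relu = drelu,
    identity = function(z) array(1, dim = dim(z) %||% length(z)),
    tanh = function(z) 1 - tanh(z)^2,
    stop("unknown activation: ", name)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Glorot-uniform weight matrix (fan_in x fan_out).
glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Flatten a nested list of arrays into a flat list (depth-first, stable
# order). Used by the optimiser and the parameter-count audit.
flatten_params <- function(p) {
  out <- list()
  walk <- function(x) {
    if (is.list(x)) {
      for (el in x) walk(el)
    } else {
      out[[length(out) + 1L]] <<- x
    }
  }
  walk(p)
  out
}

# Total number of scalar parameters in a nested parameter list.
count_params <- function(p) {
  sum(vapply(flatten_params(p), length, numeric(1)))
}

# Elementwise map over two structurally identical nested lists.
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- map2_params(a[[i]], b[[i]], f)
    out
  } else {
    f(a, b)
  }
}

zero_like <- function(p) {
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = zero_like(params), v = zero_like(params))
}

# One Adam update; returns list(params, state).
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  state$m <- map2_params(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  state$v <- map2_params(state$v, grads,
                         function(v, g) b2 * v + (1 - b2) * g * g)
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  lr <- state$lr
  eps <- state$eps
  upd <- map2_params(state$m, state$v,
                     function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- map2_params(params, upd, function(p, u) p - u)
  list(params = params, state = state)
}
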