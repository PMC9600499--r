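# Low-level neural-network primitives with hand-derived backward passes.
# Weight containers are plain nested lists of numeric matrices/vectors so
# that optimizer state and gradients can mirror the same tree shape.

# --- seeded RNG scoping -----------------------------------------------------

# Run expr with a private RNG stream; restores the caller's .Random.seed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# --- activations ------------------------------------------------------------

act_forward <- function(x, kind) {
  switch(kind,
    tanh = tanh(x),
    relu = pmax(x, 0),
    identity = x,
    stop("unknown activation: ", kind)
  )
}

# gradient expressed in terms of the activation *output* y
act_backward <- function(dy, y, kind) {
  switch(kind,
    tanh = dy * (1 - y * y),
    relu = dy * (y > 0),
    identity = dy,
    stop("unknown activation: ", kind)
  )
}

# numerically stable softplus and its derivative (sigmoid)
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

# --- linear layers ----------------------------------------------------------

init_linear <- function(n_in, n_out) {
  list(
    W = matrix(stats::rnorm(n_in * n_out, sd = 1 / sqrt(n_in)), n_in, n_out),
    b = numeric(n_out)
  )
}

# Inference-determinism switch: optimized matrix multiplication may give
# results that depend on a row's position in the batch (blocked kernels),
# which would break the bitwise symmetry guarantees of the user-facing
# assignment path. Inside with_rowsafe() every row is computed by an
# independent vector product, so identical inputs give identical outputs
# wherever they appear.
.rowsafe <- new.env(parent = emptyenv())
.rowsafe$on <- FALSE

with_rowsafe <- function(expr) {
  old <- .rowsafe$on
  .rowsafe$on <- TRUE
  on.exit(.rowsafe$on <- old)
  expr
}

linear_forward <- function(X, lay) {
  if (isTRUE(.rowsafe$on) && nrow(X) > 1) {
    out <- matrix(0, nrow(X), length(lay$b))
    for (r in seq_len(nrow(X))) {
      out[r, ] <- X[r, , drop = FALSE] %*% lay$W + lay$b
    }
    return(out)
  }
  sweep(X %*% lay$W, 2, lay$b, "+")
}

# returns list(dX, grad = list(W, b))
linear_backward <- function(dY, X, lay) {
  list(
    dX = dY %*% t(lay$W),
    grad = list(W = crossprod(X, dY), b = colSums(dY))
  )
}

# --- two-layer perceptron (hidden activation, linear output) ----------------

init_mlp <- function(n_in, n_hidden, n_out) {
  list(l1 = init_linear(n_in, n_hidden), l2 = init_linear(n_hidden, n_out))
}

mlp_forward <- function(X, mlp, activation) {
  H <- act_forward(linear_forward(X, mlp$l1), activation)
  list(out = linear_forward(H, mlp$l2), cache = list(X = X, H = H))
}

mlp_backward <- function(dOut, cache, mlp, activation) {
  b2 <- linear_backward(dOut, cache$H, mlp$l2)
  dH <- act_backward(b2$dX, cache$H, activation)
  b1 <- linear_backward(dH, cache$X, mlp$l1)
  list(dX = b1$dX, grad = list(l1 = b1$grad, l2 = b2$grad))
}

# --- weight-tree utilities --------------------------------------------------

tree_map <- function(f, a) {
  if (is.list(a)) {
    out <- lapply(a, function(x) tree_map(f, x))
    names(out) <- names(a)
    out
  } else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_zeros_like <- function(a) tree_map(function(x) x * 0, a)

# flatten a tree of numerics into one vector (fixed traversal order)
tree_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, tree_flatten), use.names = FALSE) else as.numeric(a)
}

# write a flat vector back into the shape of template tree
tree_unflatten <- function(template, v) {
  pos <- 0L
  rebuild <- function(a) {
    if (is.list(a)) {
      out <- lapply(a, rebuild)
      names(out) <- names(a)
      out
    } else {
      n <- length(a)
      x <- v[(pos + 1L):(pos + n)]
      pos <<- pos + n
      if (is.matrix(a)) dim(x) <- dim(a)
      x
    }
  }
  out <- rebuild(template)
  stopifnot(pos == length(v))
  out
}

# --- Adam optimizer ---------------------------------------------------------

adam_init <- function(weights) {
  list(m = tree_zeros_like(weights), v = tree_zeros_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) (m / c1) / (sqrt(v / c2) + eps), state$m, state$v)
  weights <- tree_map2(function(w, u) w - lr * u, weights, upd)
  list(weights = weights, state = state)
}

# --- indexed scatter-add ----------------------------------------------------

# rowsum() onto a fixed number of rows n (rows absent from idx stay zero)
index_rowsum <- function(X, idx, n) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  out <- matrix(0, n, ncol(X))
  rs <- rowsum(X, group = idx, reorder = FALSE)
  out[as.integer(rownames(rs)), ] <- rs
  out
}
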