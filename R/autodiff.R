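#' @title Reverse-mode automatic differentiation over matrices
#'
#' @description
#' A minimal tape-based reverse-mode autodiff engine used by the graph
#' encoders and task heads. Nodes hold plain numeric matrices; every
#' operation records itself on a tape so that [ad_backward()] can accumulate
#' gradients in reverse creation order. The op vocabulary is exactly what the
#' model architectures need: dense layers, elementwise nonlinearities,
#' row/segment softmax (for graph attention over variable-size
#' neighbourhoods), gather/scatter for edge endpoints, pooling, and layer
#' normalization.
#'
#' Creation order is a valid topological order because parents are always
#' built before children, so the backward pass is a single reverse sweep.
#' @name autodiff
#' @keywords internal
NULL

.ad <- new.env(parent = emptyenv())
.ad$tape <- vector("list", 4096L)
.ad$n <- 0L

#' Reset the autodiff tape
#'
#' Must be called before building a fresh computation graph (one forward
#' pass). Leaf and op nodes created afterwards are recorded in order.
#' @return Invisibly, the number of nodes discarded.
#' @keywords internal
ad_reset <- function() {
  n_old <- .ad$n
  .ad$tape <- vector("list", 4096L)
  .ad$n <- 0L
  invisible(n_old)
}

ad_record <- function(node) {
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) {
    .ad$tape <- c(.ad$tape, vector("list", length(.ad$tape)))
  }
  .ad$tape[[n]] <- node
  .ad$n <- n
  node$id <- n
  node
}

new_ad_node <- function(value, parents = list(), backfn = NULL, track = TRUE) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$track <- track
  ad_record(node)
}

#' Create a leaf node (input or parameter)
#' @param value numeric matrix.
#' @param track logical; FALSE for constants that need no gradient.
#' @keywords internal
ad_leaf <- function(value, track = TRUE) {
  if (!is.matrix(value)) value <- as.matrix(value)
  new_ad_node(value, track = track)
}

ad_value <- function(node) node$value

is_ad_node <- function(x) is.environment(x) && !is.null(x$value)

#' Backward pass: accumulate gradients of a scalar loss
#' @param loss an autodiff node holding a 1x1 matrix.
#' @keywords internal
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1, 1)
  for (i in seq(loss$id, 1L)) {
    node <- .ad$tape[[i]]
    if (is.null(node) || is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    ps <- node$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!isTRUE(p$track) && is.null(p$backfn)) next
      gk <- gs[[k]]
      if (is.null(gk)) next
      p$grad <- if (is.null(p$grad)) gk else p$grad + gk
    }
  }
  invisible(loss)
}

## ---- primitive operations ----------------------------------------------

ad_matmul <- function(a, b) {
  v <- a$value %*% b$value
  new_ad_node(v, list(a, b), function(g) {
    list(g %*% t(b$value), t(a$value) %*% g)
  })
}

ad_add <- function(a, b) {
  new_ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  new_ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  new_ad_node(a$value * b$value, list(a, b), function(g) {
    list(g * b$value, g * a$value)
  })
}

## add a 1 x d row vector (bias) to every row of an n x d matrix
ad_add_rowvec <- function(a, b) {
  v <- sweep(a$value, 2L, as.numeric(b$value), "+")
  new_ad_node(v, list(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

ad_smul <- function(a, s) {
  new_ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_one_minus <- function(a) {
  new_ad_node(1 - a$value, list(a), function(g) list(-g))
}

ad_leaky_relu <- function(a, slope = 0.01) {
  x <- a$value
  v <- ifelse(x > 0, x, slope * x)
  new_ad_node(v, list(a), function(g) list(g * ifelse(x > 0, 1, slope)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  new_ad_node(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  new_ad_node(v, list(a), function(g) list(g * (1 - v^2)))
}

ad_log <- function(a) {
  new_ad_node(log(a$value), list(a), function(g) list(g / a$value))
}

ad_pow_const <- function(a, p) {
  x <- a$value
  new_ad_node(x^p, list(a), function(g) list(g * p * x^(p - 1)))
}

ad_clip <- function(a, lo, hi) {
  x <- a$value
  v <- pmin(pmax(x, lo), hi)
  inside <- (x >= lo & x <= hi) * 1
  new_ad_node(v, list(a), function(g) list(g * inside))
}

ad_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  v <- do.call(cbind, lapply(nodes, ad_value))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  new_ad_node(v, nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[, starts[k]:ends[k], drop = FALSE])
  })
}

ad_rbind <- function(nodes) {
  hts <- vapply(nodes, function(n) nrow(n$value), integer(1))
  v <- do.call(rbind, lapply(nodes, ad_value))
  ends <- cumsum(hts)
  starts <- c(1L, head(ends, -1L) + 1L)
  new_ad_node(v, nodes, function(g) {
    lapply(seq_along(nodes), function(k) g[starts[k]:ends[k], , drop = FALSE])
  })
}

ad_slice_cols <- function(a, idx) {
  nc <- ncol(a$value)
  new_ad_node(a$value[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(g), nc)
    out[, idx] <- g
    list(out)
  })
}

ad_gather_rows <- function(a, idx) {
  nr <- nrow(a$value)
  new_ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    out <- rowsum(g, group = idx)
    full <- matrix(0, nr, ncol(g))
    full[as.integer(rownames(out)), ] <- out
    list(full)
  })
}

ad_rowsums <- function(a) {
  d <- ncol(a$value)
  v <- matrix(rowSums(a$value), ncol = 1L)
  new_ad_node(v, list(a), function(g) list(g[, rep(1L, d), drop = FALSE]))
}

ad_sum <- function(a) {
  dm <- dim(a$value)
  new_ad_node(matrix(sum(a$value), 1, 1), list(a), function(g) {
    list(matrix(as.numeric(g), dm[1], dm[2]))
  })
}

ad_mean_all <- function(a) {
  n <- length(a$value)
  dm <- dim(a$value)
  new_ad_node(matrix(mean(a$value), 1, 1), list(a), function(g) {
    list(matrix(as.numeric(g) / n, dm[1], dm[2]))
  })
}

## column means over rows: n x d -> 1 x d
ad_colmean <- function(a) {
  n <- nrow(a$value)
  v <- matrix(colMeans(a$value), 1L)
  new_ad_node(v, list(a), function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

## column-wise max over rows: n x d -> 1 x d (gradient to first argmax)
ad_colmax <- function(a) {
  x <- a$value
  am <- apply(x, 2L, which.max)
  v <- matrix(x[cbind(am, seq_len(ncol(x)))], 1L)
  new_ad_node(v, list(a), function(g) {
    out <- matrix(0, nrow(x), ncol(x))
    out[cbind(am, seq_len(ncol(x)))] <- as.numeric(g)
    list(out)
  })
}

## scatter-add rows of an m x d matrix into n_out groups
ad_segment_sum <- function(a, groups, n_out) {
  d <- ncol(a$value)
  rs <- rowsum(a$value, group = groups)
  v <- matrix(0, n_out, d)
  v[as.integer(rownames(rs)), ] <- rs
  new_ad_node(v, list(a), function(g) list(g[groups, , drop = FALSE]))
}

## softmax within segments (rows sharing a group id), each column independent
ad_segment_softmax <- function(a, groups) {
  x <- a$value
  lev <- sort(unique(groups))
  pos <- match(groups, lev)
  p <- x
  for (k in seq_along(lev)) {
    r <- which(pos == k)
    xs <- x[r, , drop = FALSE]
    xs <- sweep(xs, 2L, apply(xs, 2L, max), "-")
    e <- exp(xs)
    p[r, ] <- sweep(e, 2L, colSums(e), "/")
  }
  new_ad_node(p, list(a), function(g) {
    gp <- g * p
    sums <- rowsum(gp, group = pos)
    list(p * (g - sums[pos, , drop = FALSE]))
  })
}

## row-wise softmax (each row sums to 1)
ad_softmax_rows <- function(a) {
  x <- a$value
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  p <- e / rowSums(e)
  new_ad_node(p, list(a), function(g) {
    s <- rowSums(g * p)
    list(p * (g - s))
  })
}

## per-row layer normalization with learnable 1 x d gain/offset
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$value
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  y <- sweep(sweep(xhat, 2L, as.numeric(gamma$value), "*"),
             2L, as.numeric(beta$value), "+")
  new_ad_node(y, list(a, gamma, beta), function(g) {
    dxhat <- sweep(g, 2L, as.numeric(gamma$value), "*")
    m1 <- rowMeans(dxhat)
    m2 <- rowMeans(dxhat * xhat)
    dx <- inv * (dxhat - m1 - xhat * m2)
    list(dx,
         matrix(colSums(g * xhat), 1L),
         matrix(colSums(g), 1L))
  })
}

ad_dropout <- function(a, p, train = FALSE) {
  if (!train || p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$value), 1L, 1 - p),
                 nrow(a$value)) / (1 - p)
  new_ad_node(a$value * mask, list(a), function(g) list(g * mask))
}

## a %*% t(b) without materializing the transpose as a node
ad_matmul_t <- function(a, b) {
  v <- a$value %*% t(b$value)
  new_ad_node(v, list(a, b), function(g) {
    list(g %*% b$value, t(g) %*% a$value)
  })
}

ad_transpose <- function(a) {
  new_ad_node(t(a$value), list(a), function(g) list(t(g)))
}

## multiply each row of an n x d matrix by the matching entry of an
## n x 1 column vector (broadcast across columns)
ad_mul_colvec <- function(a, cvec) {
  w <- as.numeric(cvec$value)
  new_ad_node(a$value * w, list(a, cvec), function(g) {
    list(g * w, matrix(rowSums(g * a$value), ncol = 1L))
  })
}

## dense layer helper: x W (+ b)
nn_linear <- function(x, W, b = NULL) {
  y <- ad_matmul(x, W)
  if (!is.null(b)) y <- ad_add_rowvec(y, b)
  y
}

## ---- parameters and optimizer ------------------------------------------

#' Glorot-uniform matrix initialization
#' @keywords internal
glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

#' Wrap a named list of parameter matrices as tape leaves
#' @keywords internal
ad_wrap_params <- function(params) lapply(params, ad_leaf)

#' Extract accumulated gradients from wrapped parameter nodes
#' @keywords internal
ad_grads <- function(nodes) {
  lapply(nodes, function(n) {
    if (is.null(n$grad)) matrix(0, nrow(n$value), ncol(n$value)) else n$grad
  })
}

#' Adam optimizer state
#' @keywords internal
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

#' One Adam update; returns list(params, state)
#' @keywords internal
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
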