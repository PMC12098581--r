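## A minimal reverse-mode automatic differentiation tape over dense
## matrices. Every node is an environment holding a value, an accumulated
## gradient and a backward closure; `ad_backward()` walks the tape in
## reverse creation order. This is deliberately small: just the operations
## the variational autoencoder needs (affine layers, ReLU, sigmoid,
## softmax/log-softmax, batch-norm building blocks, slicing, reductions,
## and a clamp with straight-through-zero gradient on the clamped side).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$tape <- tape
  tape$n <- tape$n + 1L
  nd$id <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_leaf <- function(tape, value) ad_node(tape, as.matrix(value))

.acc <- function(nd, g) {
  if (is.null(nd$grad)) nd$grad <- g else nd$grad <- nd$grad + g
}

#' @noRd
ad_backward <- function(root) {
  tape <- root$tape
  root$grad <- matrix(1, nrow(root$value), ncol(root$value))
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd)
  }
  invisible(NULL)
}

## ---- primitive ops --------------------------------------------------------

ad_matmul <- function(A, B) {
  ad_node(A$tape, A$value %*% B$value, list(A, B), function(nd) {
    .acc(nd$parents[[1L]], nd$grad %*% t(nd$parents[[2L]]$value))
    .acc(nd$parents[[2L]], crossprod(nd$parents[[1L]]$value, nd$grad))
  })
}

ad_add <- function(A, B) {
  ad_node(A$tape, A$value + B$value, list(A, B), function(nd) {
    .acc(nd$parents[[1L]], nd$grad)
    .acc(nd$parents[[2L]], nd$grad)
  })
}

ad_sub <- function(A, B) {
  ad_node(A$tape, A$value - B$value, list(A, B), function(nd) {
    .acc(nd$parents[[1L]], nd$grad)
    .acc(nd$parents[[2L]], -nd$grad)
  })
}

ad_mul <- function(A, B) {
  ad_node(A$tape, A$value * B$value, list(A, B), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * nd$parents[[2L]]$value)
    .acc(nd$parents[[2L]], nd$grad * nd$parents[[1L]]$value)
  })
}

## add a 1 x d row vector to every row
ad_addrow <- function(A, b) {
  ad_node(A$tape, sweep(A$value, 2L, drop(b$value), `+`), list(A, b),
          function(nd) {
    .acc(nd$parents[[1L]], nd$grad)
    .acc(nd$parents[[2L]], matrix(colSums(nd$grad), 1L))
  })
}

ad_subrow <- function(A, b) {
  ad_node(A$tape, sweep(A$value, 2L, drop(b$value), `-`), list(A, b),
          function(nd) {
    .acc(nd$parents[[1L]], nd$grad)
    .acc(nd$parents[[2L]], matrix(-colSums(nd$grad), 1L))
  })
}

## multiply / divide columns by a 1 x d row vector
ad_mulrow <- function(A, b) {
  ad_node(A$tape, sweep(A$value, 2L, drop(b$value), `*`), list(A, b),
          function(nd) {
    .acc(nd$parents[[1L]],
         sweep(nd$grad, 2L, drop(nd$parents[[2L]]$value), `*`))
    .acc(nd$parents[[2L]],
         matrix(colSums(nd$grad * nd$parents[[1L]]$value), 1L))
  })
}

ad_divrow <- function(A, b) {
  ad_node(A$tape, sweep(A$value, 2L, drop(b$value), `/`), list(A, b),
          function(nd) {
    bv <- drop(nd$parents[[2L]]$value)
    .acc(nd$parents[[1L]], sweep(nd$grad, 2L, bv, `/`))
    .acc(nd$parents[[2L]],
         matrix(colSums(-nd$grad * nd$value) / bv, 1L))
  })
}

## multiply every column of A (n x d) by a length-n column vector
ad_mulcol <- function(A, v) {
  ad_node(A$tape, A$value * drop(v$value), list(A, v), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * drop(nd$parents[[2L]]$value))
    .acc(nd$parents[[2L]],
         matrix(rowSums(nd$grad * nd$parents[[1L]]$value), ncol = 1L))
  })
}

ad_scale <- function(A, s) {
  ad_node(A$tape, A$value * s, list(A), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * s)
  })
}

ad_shift <- function(A, s) {
  ad_node(A$tape, A$value + s, list(A), function(nd) {
    .acc(nd$parents[[1L]], nd$grad)
  })
}

ad_relu <- function(A) {
  ad_node(A$tape, pmax(A$value, 0), list(A), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * (nd$parents[[1L]]$value > 0))
  })
}

ad_sigmoid <- function(A) {
  v <- stats::plogis(A$value)
  ad_node(A$tape, v, list(A), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * nd$value * (1 - nd$value))
  })
}

ad_exp <- function(A) {
  ad_node(A$tape, exp(A$value), list(A), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * nd$value)
  })
}

ad_sqrt <- function(A) {
  ad_node(A$tape, sqrt(A$value), list(A), function(nd) {
    .acc(nd$parents[[1L]], nd$grad / (2 * nd$value))
  })
}

ad_softmax_rows <- function(A) {
  v <- softmax_rows(A$value)
  ad_node(A$tape, v, list(A), function(nd) {
    q <- nd$value
    dot <- rowSums(nd$grad * q)
    .acc(nd$parents[[1L]], q * (nd$grad - dot))
  })
}

ad_logsoftmax_rows <- function(A) {
  v <- A$value - logsumexp_rows(A$value)
  ad_node(A$tape, v, list(A), function(nd) {
    q <- exp(nd$value)
    .acc(nd$parents[[1L]], nd$grad - q * rowSums(nd$grad))
  })
}

ad_cbind <- function(A, B) {
  ad_node(A$tape, cbind(A$value, B$value), list(A, B), function(nd) {
    a <- ncol(nd$parents[[1L]]$value)
    .acc(nd$parents[[1L]], nd$grad[, seq_len(a), drop = FALSE])
    .acc(nd$parents[[2L]], nd$grad[, -seq_len(a), drop = FALSE])
  })
}

## column slice (scatter gradient back)
ad_cols <- function(A, idx) {
  ad_node(A$tape, A$value[, idx, drop = FALSE], list(A), function(nd) {
    g <- matrix(0, nrow(nd$parents[[1L]]$value),
                ncol(nd$parents[[1L]]$value))
    g[, idx] <- nd$grad
    .acc(nd$parents[[1L]], g)
  })
}

## single row as 1 x d (for per-component prior parameters)
ad_row <- function(A, i) {
  ad_node(A$tape, A$value[i, , drop = FALSE], list(A), function(nd) {
    g <- matrix(0, nrow(nd$parents[[1L]]$value),
                ncol(nd$parents[[1L]]$value))
    g[i, ] <- nd$grad
    .acc(nd$parents[[1L]], g)
  })
}

ad_col <- function(A, j) {
  ad_node(A$tape, A$value[, j, drop = FALSE], list(A), function(nd) {
    g <- matrix(0, nrow(nd$parents[[1L]]$value),
                ncol(nd$parents[[1L]]$value))
    g[, j] <- nd$grad
    .acc(nd$parents[[1L]], g)
  })
}

ad_sum <- function(A) {
  ad_node(A$tape, matrix(sum(A$value), 1L, 1L), list(A), function(nd) {
    .acc(nd$parents[[1L]],
         matrix(nd$grad[1L], nrow(nd$parents[[1L]]$value),
                ncol(nd$parents[[1L]]$value)))
  })
}

ad_mean <- function(A) {
  n <- length(A$value)
  ad_node(A$tape, matrix(mean(A$value), 1L, 1L), list(A), function(nd) {
    .acc(nd$parents[[1L]],
         matrix(nd$grad[1L] / n, nrow(nd$parents[[1L]]$value),
                ncol(nd$parents[[1L]]$value)))
  })
}

ad_colmeans <- function(A) {
  n <- nrow(A$value)
  ad_node(A$tape, matrix(colMeans(A$value), 1L), list(A), function(nd) {
    .acc(nd$parents[[1L]],
         matrix(nd$grad / n, nrow(nd$parents[[1L]]$value),
                ncol(nd$parents[[1L]]$value), byrow = TRUE))
  })
}

ad_rowsums <- function(A) {
  ad_node(A$tape, matrix(rowSums(A$value), ncol = 1L), list(A),
          function(nd) {
    .acc(nd$parents[[1L]],
         matrix(drop(nd$grad), nrow(nd$parents[[1L]]$value),
                ncol(nd$parents[[1L]]$value)))
  })
}

## elementwise max(A, cmin); gradient is zero where the floor binds
ad_clamp_min <- function(A, cmin) {
  ad_node(A$tape, pmax(A$value, cmin), list(A), function(nd) {
    .acc(nd$parents[[1L]], nd$grad * (nd$parents[[1L]]$value > cmin))
  })
}

## affine layer: X %*% W + b
ad_linear <- function(X, W, b) ad_addrow(ad_matmul(X, W), b)

## batch normalization over rows; in training mode uses batch statistics
## and updates `stats_env[[key]]` (running mean/var, momentum 0.1); in
## eval mode normalizes by the stored running statistics.
ad_batchnorm <- function(X, gamma, beta, stats_env, key, training,
                         eps = 1e-5, momentum = 0.1) {
  if (training) {
    mu <- ad_colmeans(X)
    xc <- ad_subrow(X, mu)
    v <- ad_colmeans(ad_mul(xc, xc))
    ## update running stats (plain numerics; unbiased var like torch)
    n <- nrow(X$value)
    bvar <- drop(v$value) * if (n > 1L) n / (n - 1L) else 1
    st <- stats_env[[key]]
    if (is.null(st)) st <- list(mean = drop(mu$value) * 0,
                                var = drop(v$value) * 0 + 1)
    st$mean <- (1 - momentum) * st$mean + momentum * drop(mu$value)
    st$var <- (1 - momentum) * st$var + momentum * bvar
    stats_env[[key]] <- st
    sd_ <- ad_sqrt(ad_shift(v, eps))
    xn <- ad_divrow(xc, sd_)
  } else {
    st <- stats_env[[key]]
    if (is.null(st)) {
      st <- list(mean = rep(0, ncol(X$value)), var = rep(1, ncol(X$value)))
    }
    mu <- ad_leaf(X$tape, matrix(st$mean, 1L))
    sd_ <- ad_leaf(X$tape, matrix(sqrt(st$var + eps), 1L))
    xn <- ad_divrow(ad_subrow(X, mu), sd_)
  }
  ad_addrow(ad_mulrow(xn, gamma), beta)
}
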