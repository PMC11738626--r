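# Reverse-mode automatic differentiation over dense matrices.
#
# The neural components of this package (graph-network backbones and the MIL
# attention head) are trained with gradients computed by this small tape-free
# engine: every op returns a node environment holding its value, its parent
# nodes and a backward closure; ad_backward() walks the graph in reverse
# topological order. Plain matrices mixed into ops are treated as constants
# (no gradient). Correctness is property-tested against numerical
# differentiation in the test suite.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

ad_is_node <- function(x) inherits(x, "ad_node")

ad_val <- function(x) if (ad_is_node(x)) x$val else x

ad_node <- function(val, parents = list(), backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$val <- val
  n$parents <- Filter(ad_is_node, parents)
  n$backward <- backward
  n$grad <- NULL
  .ad_env$counter <- .ad_env$counter + 1L
  n$id <- .ad_env$counter
  class(n) <- "ad_node"
  n
}

#' @noRd
ad_param <- function(val) ad_node(as.matrix(val))

ad_const <- function(val) ad_node(as.matrix(val))

# accumulate gradient g into node (if it is a node)
.ad_acc <- function(x, g) {
  if (!ad_is_node(x)) return(invisible())
  x$grad <- if (is.null(x$grad)) g else x$grad + g
  invisible()
}

ad_matmul <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_node(xv %*% yv, list(x, y), function(g) {
    if (ad_is_node(x)) .ad_acc(x, g %*% t(yv))
    if (ad_is_node(y)) .ad_acc(y, crossprod(xv, g))
  })
}

# add with row-vector broadcast (bias): y may be 1 x d while x is n x d
ad_add <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  bcast <- nrow(as.matrix(yv)) == 1L && nrow(as.matrix(xv)) > 1L
  out <- if (bcast) xv + rep(as.numeric(yv), each = nrow(xv)) else xv + yv
  ad_node(out, list(x, y), function(g) {
    .ad_acc(x, g)
    if (ad_is_node(y)) {
      .ad_acc(y, if (bcast) matrix(colSums(g), 1L) else g)
    }
  })
}

ad_sub <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_node(xv - yv, list(x, y), function(g) {
    .ad_acc(x, g)
    .ad_acc(y, -g)
  })
}

# elementwise product; shapes must match
ad_mul <- function(x, y) {
  xv <- ad_val(x); yv <- ad_val(y)
  ad_node(xv * yv, list(x, y), function(g) {
    .ad_acc(x, g * yv)
    .ad_acc(y, g * xv)
  })
}

# multiply every column of x (n x d) by column vector w (n x 1)
ad_mul_colvec <- function(x, w) {
  xv <- ad_val(x); wv <- as.numeric(ad_val(w))
  ad_node(xv * wv, list(x, w), function(g) {
    .ad_acc(x, g * wv)
    if (ad_is_node(w)) .ad_acc(w, matrix(rowSums(g * xv), ncol = 1L))
  })
}

ad_scale <- function(x, s) {
  xv <- ad_val(x)
  ad_node(xv * s, list(x), function(g) .ad_acc(x, g * s))
}

ad_tanh <- function(x) {
  v <- tanh(ad_val(x))
  ad_node(v, list(x), function(g) .ad_acc(x, g * (1 - v^2)))
}

ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-ad_val(x)))
  ad_node(v, list(x), function(g) .ad_acc(x, g * v * (1 - v)))
}

ad_relu <- function(x) {
  xv <- ad_val(x)
  v <- pmax(xv, 0)
  ad_node(v, list(x), function(g) .ad_acc(x, g * (xv > 0)))
}

# silu / swish: x * sigmoid(x)
ad_silu <- function(x) {
  xv <- ad_val(x)
  s <- 1 / (1 + exp(-xv))
  ad_node(xv * s, list(x), function(g) .ad_acc(x, g * (s * (1 + xv * (1 - s)))))
}

ad_cbind <- function(...) {
  args <- list(...)
  vals <- lapply(args, ad_val)
  widths <- vapply(vals, ncol, 1L)
  stops <- cumsum(widths)
  starts <- c(1L, head(stops, -1L) + 1L)
  ad_node(do.call(cbind, vals), args, function(g) {
    for (i in seq_along(args)) {
      .ad_acc(args[[i]], g[, starts[i]:stops[i], drop = FALSE])
    }
  })
}

# gather rows: out[r, ] = x[idx[r], ]
ad_rows <- function(x, idx) {
  xv <- ad_val(x)
  n <- nrow(xv)
  ad_node(xv[idx, , drop = FALSE], list(x), function(g) {
    if (!ad_is_node(x)) return(invisible())
    rs <- rowsum(g, group = idx)
    gp <- matrix(0, n, ncol(g))
    gp[as.integer(rownames(rs)), ] <- rs
    .ad_acc(x, gp)
  })
}

# scatter-add rows of x into ngroups rows by integer group id
ad_rowsum <- function(x, groups, ngroups) {
  xv <- ad_val(x)
  rs <- rowsum(xv, group = groups)
  out <- matrix(0, ngroups, ncol(xv))
  out[as.integer(rownames(rs)), ] <- rs
  ad_node(out, list(x), function(g) {
    .ad_acc(x, g[groups, , drop = FALSE])
  })
}

ad_sum <- function(x) {
  xv <- ad_val(x)
  ad_node(matrix(sum(xv)), list(x), function(g) {
    .ad_acc(x, matrix(as.numeric(g), nrow(xv), ncol(xv)))
  })
}

ad_mean <- function(x) {
  xv <- ad_val(x)
  n <- length(xv)
  ad_node(matrix(mean(xv)), list(x), function(g) {
    .ad_acc(x, matrix(as.numeric(g) / n, nrow(xv), ncol(xv)))
  })
}

# softmax of a column vector of logits within integer groups; masked entries
# (mask == FALSE) receive weight exactly 0 and pass no gradient
ad_group_softmax <- function(logits, groups, mask = NULL) {
  lv <- as.numeric(ad_val(logits))
  n <- length(lv)
  if (is.null(mask)) mask <- rep(TRUE, n)
  w <- rep(0, n)
  act <- which(mask)
  ga <- groups[act]
  mx <- tapply(lv[act], ga, max)
  e <- exp(lv[act] - as.numeric(mx[as.character(ga)]))
  tot <- tapply(e, ga, sum)
  w[act] <- e / as.numeric(tot[as.character(ga)])
  wv <- matrix(w, ncol = 1L)
  ad_node(wv, list(logits), function(g) {
    if (!ad_is_node(logits)) return(invisible())
    gv <- as.numeric(g)
    dot <- rep(0, n)
    s <- tapply(gv[act] * w[act], ga, sum)
    dot[act] <- as.numeric(s[as.character(ga)])
    .ad_acc(logits, matrix(w * (gv - dot), ncol = 1L))
  })
}

# mean squared error against a constant target
ad_mse <- function(pred, target) {
  pv <- ad_val(pred)
  tv <- as.matrix(target)
  d <- pv - tv
  n <- length(d)
  ad_node(matrix(mean(d^2)), list(pred), function(g) {
    .ad_acc(pred, 2 * d * as.numeric(g) / n)
  })
}

# reverse topological order by DFS from the loss node
ad_backward <- function(loss) {
  stopifnot(ad_is_node(loss), length(loss$val) == 1L)
  order <- vector("list", 256L)
  norder <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(seen[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      norder <- norder + 1L
      if (norder > length(order)) order <- c(order, vector("list", length(order)))
      order[[norder]] <- node
    }
  }
  loss$grad <- matrix(1)
  for (i in seq(norder, 1L)) {
    node <- order[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node$grad)
  }
  invisible(loss)
}

ad_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible()
}

# Glorot-uniform initialized parameter matrix
ad_glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  ad_param(matrix(stats::runif(nin * nout, -lim, lim), nin, nout))
}

ad_zeros <- function(nin, nout) ad_param(matrix(0, nin, nout))

# RMSprop optimizer state and step (alpha = 0.99, eps = 1e-8)
rmsprop_new <- function(params, alpha = 0.99, eps = 1e-8) {
  list(params = params, alpha = alpha, eps = eps,
       v = lapply(params, function(p) p$val * 0))
}

rmsprop_step <- function(opt, lr) {
  for (i in seq_along(opt$params)) {
    p <- opt$params[[i]]
    if (is.null(p$grad)) next
    opt$v[[i]] <- opt$alpha * opt$v[[i]] + (1 - opt$alpha) * p$grad^2
    p$val <- p$val - lr * p$grad / (sqrt(opt$v[[i]]) + opt$eps)
  }
  opt
}
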