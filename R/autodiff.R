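#' @keywords internal
"_PACKAGE"

## Reverse-mode automatic differentiation over plain numeric arrays.
##
## Nodes are environments holding a value, a list of parent nodes and one
## vector-Jacobian-product closure per parent. The graph is built implicitly
## during the forward pass; ad_backward() walks it in reverse creation order.
## All heavy lifting (convolution, attention, patch retrieval) is expressed
## through a handful of primitives -- matmul, row gather/scatter, reshape --
## so the backward pass reuses BLAS and rowsum().

.ad <- new.env(parent = emptyenv())
.ad$count <- 0L

#' Create an autodiff node
#'
#' Low-level constructor used by every differentiable operation. `parents`
#' must contain only nodes; `vjps[[i]](grad)` returns the gradient
#' contribution to `parents[[i]]` given the node's own gradient.
#'
#' @param value numeric array/matrix/scalar held by the node.
#' @param parents list of parent nodes.
#' @param vjps list of vector-Jacobian-product closures, one per parent.
#' @return an object of class `ad_node`.
#' @keywords internal
ad_node <- function(value, parents = list(), vjps = list()) {
  e <- new.env(parent = emptyenv())
  .ad$count <- .ad$count + 1L
  e$id <- .ad$count
  e$value <- value
  e$parents <- parents
  e$vjps <- vjps
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

is_ad_node <- function(x) inherits(x, "ad_node")

#' Wrap a plain array as a constant (leaf) node
#' @param x numeric array.
#' @return an `ad_node` with no parents.
#' @keywords internal
ad_const <- function(x) ad_node(x)

## value of a node or plain numeric
nval <- function(x) if (is_ad_node(x)) x$value else x

## build an op node, silently dropping non-node arguments (constants)
ad_op <- function(value, args, vjps) {
  keep <- vapply(args, is_ad_node, logical(1))
  ad_node(value, args[keep], vjps[keep])
}

#' Backpropagate from a scalar node
#'
#' Accumulates gradients into the `grad` field of every node reachable from
#' `root`. `root$value` must have length 1.
#'
#' @param root scalar `ad_node` (typically a loss).
#' @return invisibly, `root`.
#' @keywords internal
ad_backward <- function(root) {
  stopifnot(is_ad_node(root), length(root$value) == 1L)
  seen <- new.env(parent = emptyenv())
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  stack <- list(root)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    if (length(nd$parents)) stack <- c(stack, nd$parents)
  }
  nodes <- nodes[seq_len(n_nodes)]
  ids <- vapply(nodes, function(n) n$id, integer(1))
  ord <- order(ids, decreasing = TRUE)
  for (nd in nodes) nd$grad <- NULL
  root$grad <- 1
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || !length(nd$parents)) next
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      g <- nd$vjps[[i]](nd$grad)
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

## ---- elementwise and linear-algebra primitives -----------------------------

ad_add <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  ad_op(va + vb, list(a, b), list(
    function(g) g,
    function(g) if (length(vb) == 1L && length(va) > 1L) sum(g) else g
  ))
}

ad_sub <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  ad_op(va - vb, list(a, b), list(
    function(g) g,
    function(g) if (length(vb) == 1L && length(va) > 1L) -sum(g) else -g
  ))
}

ad_mul <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  ad_op(va * vb, list(a, b), list(
    function(g) if (length(va) == 1L && length(vb) > 1L) sum(g * vb) else g * vb,
    function(g) if (length(vb) == 1L && length(va) > 1L) sum(g * va) else g * va
  ))
}

ad_scale <- function(a, s) {
  va <- nval(a)
  ad_op(va * s, list(a), list(function(g) g * s))
}

ad_matmul <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  ad_op(va %*% vb, list(a, b), list(
    function(g) g %*% t(vb),
    function(g) crossprod(va, g)
  ))
}

ad_transpose <- function(a) {
  va <- nval(a)
  ad_op(t(va), list(a), list(function(g) t(g)))
}

## add a length-C bias vector to every row of an N x C matrix
ad_add_bias <- function(x, b) {
  vx <- nval(x); vb <- nval(b)
  ad_op(vx + rep(vb, each = nrow(vx)), list(x, b), list(
    function(g) g,
    function(g) colSums(g)
  ))
}

## multiply row i of x by scalar w[i]
ad_mul_rows <- function(x, w) {
  vx <- nval(x); vw <- as.vector(nval(w))
  ad_op(vx * vw, list(x, w), list(
    function(g) g * vw,
    function(g) rowSums(g * vx)
  ))
}

## multiply column c of x by scalar s[c]
ad_mul_cols <- function(x, s) {
  vx <- nval(x); vs <- as.vector(nval(s))
  ad_op(vx * rep(vs, each = nrow(vx)), list(x, s), list(
    function(g) g * rep(vs, each = nrow(vx)),
    function(g) colSums(g * vx)
  ))
}

ad_relu <- function(x) {
  vx <- nval(x)
  m <- vx > 0
  ad_op(vx * m, list(x), list(function(g) g * m))
}

ad_gelu <- function(x) {
  vx <- nval(x)
  k <- sqrt(2 / pi)
  inner <- k * (vx + 0.044715 * vx^3)
  th <- tanh(inner)
  val <- 0.5 * vx * (1 + th)
  ad_op(val, list(x), list(function(g) {
    dinner <- k * (1 + 3 * 0.044715 * vx^2)
    g * (0.5 * (1 + th) + 0.5 * vx * (1 - th^2) * dinner)
  }))
}

ad_sigmoid <- function(x) {
  vx <- nval(x)
  s <- 1 / (1 + exp(-vx))
  ad_op(s, list(x), list(function(g) g * s * (1 - s)))
}

## numerically-stable softplus, used by the adversarial objective
ad_softplus <- function(x) {
  vx <- nval(x)
  val <- ifelse(vx > 30, vx, log1p(exp(pmin(vx, 30))))
  ad_op(val, list(x), list(function(g) g / (1 + exp(-vx))))
}

ad_mean <- function(x) {
  vx <- nval(x)
  n <- length(vx)
  ad_op(mean(vx), list(x), list(function(g) array(g / n, dim = dim(vx) %||% n)))
}

ad_sum <- function(x) {
  vx <- nval(x)
  ad_op(sum(vx), list(x), list(function(g) array(g, dim = dim(vx) %||% length(vx))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## mean(|a - b|); subgradient 0 at ties
ad_mean_abs_diff <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  d <- va - vb
  n <- length(d)
  ad_op(mean(abs(d)), list(a, b), list(
    function(g) g * sign(d) / n,
    function(g) -g * sign(d) / n
  ))
}

ad_mean_sq_diff <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  d <- va - vb
  n <- length(d)
  ad_op(mean(d * d), list(a, b), list(
    function(g) g * 2 * d / n,
    function(g) -g * 2 * d / n
  ))
}

## row-wise softmax of an N x M matrix
ad_softmax_rows <- function(x) {
  vx <- nval(x)
  mx <- apply(vx, 1L, max)
  e <- exp(vx - mx)
  s <- e / rowSums(e)
  ad_op(s, list(x), list(function(g) (g - rowSums(g * s)) * s))
}

## layer normalization across columns, independently per row (per spatial
## position over channels); gamma/beta are length-C vectors
ad_layernorm_rows <- function(x, gamma, beta, eps = 1e-5) {
  vx <- nval(x); vg <- nval(gamma)
  n <- nrow(vx); C <- ncol(vx)
  mu <- rowMeans(vx)
  xc <- vx - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- xhat * rep(vg, each = n) + rep(nval(beta), each = n)
  ad_op(val, list(x, gamma, beta), list(
    function(g) {
      dy <- g * rep(vg, each = n)
      (dy - rowMeans(dy) - xhat * rowMeans(dy * xhat)) * inv
    },
    function(g) colSums(g * xhat),
    function(g) colSums(g)
  ))
}

## batch normalization across rows, per column (per channel over spatial
## positions). `state` is an environment slot list(mean, var) updated as a
## side effect in training mode.
ad_batchnorm_cols <- function(x, gamma, beta, state, training = TRUE,
                              momentum = 0.1, eps = 1e-5) {
  vx <- nval(x); vg <- nval(gamma)
  n <- nrow(vx)
  if (training) {
    mu <- colMeans(vx)
    xc <- vx - rep(mu, each = n)
    v <- colMeans(xc * xc)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v * n / max(n - 1L, 1L)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rep(inv, each = n)
    val <- xhat * rep(vg, each = n) + rep(nval(beta), each = n)
    ad_op(val, list(x, gamma, beta), list(
      function(g) {
        dy <- g * rep(vg, each = n)
        (dy - rep(colMeans(dy), each = n) -
           xhat * rep(colMeans(dy * xhat), each = n)) * rep(inv, each = n)
      },
      function(g) colSums(g * xhat),
      function(g) colSums(g)
    ))
  } else {
    inv <- 1 / sqrt(state$var + eps)
    a <- vg * inv
    xhat <- (vx - rep(state$mean, each = n)) * rep(inv, each = n)
    val <- xhat * rep(vg, each = n) + rep(nval(beta), each = n)
    ad_op(val, list(x, gamma, beta), list(
      function(g) g * rep(a, each = n),
      function(g) colSums(g * xhat),
      function(g) colSums(g)
    ))
  }
}

## ---- gather / scatter / reshape primitives ---------------------------------

## rows of x selected by integer index vector; the workhorse behind padding,
## im2col and patch retrieval
ad_gather_rows <- function(x, idx) {
  vx <- nval(x)
  nr <- nrow(vx)
  ad_op(vx[idx, , drop = FALSE], list(x), list(function(g) {
    out <- matrix(0, nr, ncol(vx))
    rs <- rowsum(g, group = idx)
    out[as.integer(rownames(rs)), ] <- rs
    out
  }))
}

## scatter-add rows of x into n_out rows at positions idx (adjoint of gather)
ad_scatter_rows <- function(x, idx, n_out) {
  vx <- nval(x)
  out <- matrix(0, n_out, ncol(vx))
  rs <- rowsum(vx, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  ad_op(out, list(x), list(function(g) g[idx, , drop = FALSE]))
}

## change dim attribute; column-major layout makes this a free reinterpret
ad_set_dim <- function(x, d) {
  vx <- nval(x)
  od <- dim(vx) %||% length(vx)
  v <- vx
  dim(v) <- d
  ad_op(v, list(x), list(function(g) { dim(g) <- od; g }))
}

ad_cbind <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  ca <- ncol(va)
  ad_op(cbind(va, vb), list(a, b), list(
    function(g) g[, seq_len(ca), drop = FALSE],
    function(g) g[, -seq_len(ca), drop = FALSE]
  ))
}

ad_rbind_list <- function(xs) {
  vals <- lapply(xs, nval)
  nr <- vapply(vals, nrow, integer(1))
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  vjps <- lapply(seq_along(xs), function(i) {
    force(i)
    function(g) g[starts[i]:ends[i], , drop = FALSE]
  })
  ad_op(do.call(rbind, vals), xs, vjps)
}

## L2-normalize each row (zero rows stay zero); eps guards the norm
ad_unit_rows <- function(x, eps = 1e-12) {
  vx <- nval(x)
  nr <- sqrt(rowSums(vx * vx))
  nrs <- pmax(nr, eps)
  u <- vx / nrs
  ad_op(u, list(x), list(function(g) {
    (g - u * rowSums(g * u)) / nrs
  }))
}

## row-wise dot product of two equal-shape matrices -> length-N vector
ad_rowdot <- function(a, b) {
  va <- nval(a); vb <- nval(b)
  ad_op(rowSums(va * vb), list(a, b), list(
    function(g) as.vector(g) * vb,
    function(g) as.vector(g) * va
  ))
}

ad_colmeans <- function(x) {
  vx <- nval(x)
  n <- nrow(vx)
  ad_op(colMeans(vx), list(x), list(function(g) matrix(rep(g / n, each = n), n)))
}
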