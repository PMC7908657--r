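# A compact reverse-mode network engine on (H, W, C) arrays.
#
# No deep-learning framework exists in the supported dependency set, so the
# few primitives the detector needs — 2D convolution (Rcpp/Armadillo im2col),
# ReLU/sigmoid/tanh, channel concatenation/slicing, x2 bilinear upsampling,
# and the detection losses — are implemented here with hand-written adjoints.
# A "tape" records operations in execution order; backward() walks it in
# reverse, accumulating gradients for named parameters. With grad = FALSE the
# same ops run forward-only (inference mode) with no recording.

nn_params <- function() {
  e <- new.env(parent = emptyenv())
  e$val <- list()
  e$m <- list()
  e$v <- list()
  e$step <- 0L
  class(e) <- "nn_params"
  e
}

param_add <- function(store, name, value) {
  if (!is.null(store$val[[name]])) stop("duplicate parameter: ", name)
  store$val[[name]] <- value
  store$m[[name]] <- array(0, dim(value) %||% length(value))
  store$v[[name]] <- array(0, dim(value) %||% length(value))
  invisible(store)
}

# He-style initialisation draws from the *current* RNG stream; callers wrap
# model construction in with_seed().
init_conv_w <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

nn_tape <- function(params, grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$params <- params
  tp$grad <- grad
  tp$n <- 0L
  tp$bws <- list()
  class(tp) <- "nn_tape"
  tp
}

# a node is list(id, v); id is NA in inference mode
emit <- function(tp, v, bw = NULL) {
  if (!tp$grad) return(list(id = NA_integer_, v = v))
  tp$n <- tp$n + 1L
  tp$bws[[tp$n]] <- bw
  list(id = tp$n, v = v)
}

op_input <- function(tp, v) emit(tp, v, bw = NULL)

# run backward from a scalar node; returns env of parameter gradients (by
# name) and stores nothing else
nn_backward <- function(tp, node) {
  stopifnot(tp$grad, !is.na(node$id))
  grads <- vector("list", tp$n)
  grads[[node$id]] <- 1
  pg <- new.env(parent = emptyenv())
  acc <- function(id, g) {
    if (is.null(grads[[id]])) grads[[id]] <<- g else grads[[id]] <<- grads[[id]] + g
  }
  accp <- function(name, g) {
    if (is.null(pg[[name]])) pg[[name]] <- g else pg[[name]] <- pg[[name]] + g
  }
  for (id in seq(node$id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    bw <- tp$bws[[id]]
    if (!is.null(bw)) bw(g, acc, accp)
    grads[id] <- list(NULL)  # free
  }
  pg
}

# ---- primitive ops ---------------------------------------------------------

op_conv <- function(tp, x, wname, bname, stride = 1L, pad = NULL) {
  w <- tp$params$val[[wname]]
  b <- tp$params$val[[bname]]
  if (is.null(w)) stop("unknown conv weight: ", wname)
  if (is.null(pad)) pad <- (dim(w)[1] - 1L) %/% 2L
  v <- cpp_conv2d(x$v, w, b, as.integer(stride), as.integer(pad))
  xv <- x$v; xid <- x$id
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.array(g)) g <- array(g, dim(v))
    bwd <- cpp_conv2d_bwd(xv, tp$params$val[[wname]], g,
                          as.integer(stride), as.integer(pad))
    accp(wname, bwd$dw)
    accp(bname, bwd$db)
    if (!is.na(xid)) acc(xid, bwd$dx)
  })
}

op_relu <- function(tp, x) {
  v <- pmax(x$v, 0)
  xid <- x$id; pos <- x$v > 0
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(xid)) acc(xid, g * pos)
  })
}

op_sigmoid <- function(tp, x) {
  v <- 1 / (1 + exp(-x$v))
  xid <- x$id
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(xid)) acc(xid, g * v * (1 - v))
  })
}

op_tanh <- function(tp, x) {
  v <- tanh(x$v)
  xid <- x$id
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(xid)) acc(xid, g * (1 - v^2))
  })
}

op_add <- function(tp, a, b) {
  v <- a$v + b$v
  aid <- a$id; bid <- b$id
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(aid)) acc(aid, g)
    if (!is.na(bid)) acc(bid, g)
  })
}

op_mul <- function(tp, a, b) {
  v <- a$v * b$v
  aid <- a$id; bid <- b$id; av <- a$v; bv <- b$v
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(aid)) acc(aid, g * bv)
    if (!is.na(bid)) acc(bid, g * av)
  })
}

op_concat <- function(tp, xs) {
  dims <- lapply(xs, function(x) dim(x$v))
  cs <- vapply(dims, function(d) d[3], numeric(1))
  H <- dims[[1]][1]; W <- dims[[1]][2]
  v <- array(0, c(H, W, sum(cs)))
  off <- 0
  for (x in xs) {
    v[, , off + seq_len(dim(x$v)[3])] <- x$v
    off <- off + dim(x$v)[3]
  }
  ids <- vapply(xs, function(x) x$id, integer(1))
  emit(tp, v, bw = function(g, acc, accp) {
    off <- 0
    for (i in seq_along(ids)) {
      ci <- cs[i]
      if (!is.na(ids[i]))
        acc(ids[i], g[, , off + seq_len(ci), drop = FALSE])
      off <- off + ci
    }
  })
}

op_slice_ch <- function(tp, x, from, to) {
  v <- x$v[, , from:to, drop = FALSE]
  xid <- x$id; d <- dim(x$v)
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(xid)) {
      full <- array(0, d)
      full[, , from:to] <- g
      acc(xid, full)
    }
  })
}

# cached x2 bilinear interpolation matrices (half-pixel-center convention)
upsample_mat_cache <- new.env(parent = emptyenv())
upsample_mat <- function(n) {
  key <- as.character(n)
  A <- upsample_mat_cache[[key]]
  if (is.null(A)) {
    A <- matrix(0, 2 * n, n)
    for (i in seq_len(2 * n) - 1) {
      src <- (i + 0.5) / 2 - 0.5
      lo <- floor(src); fr <- src - lo
      lo_c <- min(max(lo, 0), n - 1); hi_c <- min(max(lo + 1, 0), n - 1)
      A[i + 1, lo_c + 1] <- A[i + 1, lo_c + 1] + (1 - fr)
      A[i + 1, hi_c + 1] <- A[i + 1, hi_c + 1] + fr
    }
    upsample_mat_cache[[key]] <- A
  }
  A
}

op_upsample2x <- function(tp, x) {
  d <- dim(x$v)
  A <- upsample_mat(d[1]); B <- upsample_mat(d[2])
  v <- array(0, c(2 * d[1], 2 * d[2], d[3]))
  for (c in seq_len(d[3])) v[, , c] <- A %*% x$v[, , c] %*% t(B)
  xid <- x$id
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(xid)) {
      dx <- array(0, d)
      for (c in seq_len(d[3])) dx[, , c] <- t(A) %*% g[, , c] %*% B
      acc(xid, dx)
    }
  })
}

# ---- losses (scalar nodes with analytic adjoints) --------------------------

# penalty-reduced focal loss on an activated heatmap (CenterNet style)
op_focal_loss <- function(tp, hm, target, alpha = 2, beta = 4, eps = 1e-6) {
  p <- pmin(pmax(hm$v, eps), 1 - eps)
  y <- target
  pos <- y >= 1 - 1e-9
  npos <- max(1, sum(pos))
  neg_w <- (1 - y)^beta
  l_pos <- (1 - p)^alpha * log(p)
  l_neg <- neg_w * p^alpha * log(1 - p)
  v <- -(sum(l_pos[pos]) + sum(l_neg[!pos])) / npos
  hid <- hm$id
  emit(tp, v, bw = function(g, acc, accp) {
    if (is.na(hid)) return()
    d <- array(0, dim(p))
    d[pos] <- -(-alpha * (1 - p[pos])^(alpha - 1) * log(p[pos]) +
                  (1 - p[pos])^alpha / p[pos])
    d[!pos] <- -neg_w[!pos] * (alpha * p[!pos]^(alpha - 1) * log(1 - p[!pos]) -
                                 p[!pos]^alpha / (1 - p[!pos]))
    acc(hid, g * d / npos)
  })
}

# L1 regression loss evaluated at peak cells only; mask is (H, W) logical
op_l1_masked <- function(tp, pred, target, mask) {
  n <- max(1, sum(mask))
  m3 <- array(rep(mask, dim(pred$v)[3]), dim(pred$v))
  diff <- (pred$v - target) * m3
  v <- sum(abs(diff)) / n
  pid <- pred$id
  emit(tp, v, bw = function(g, acc, accp) {
    if (!is.na(pid)) acc(pid, g * sign(diff) / n)
  })
}

op_weighted_sum <- function(tp, nodes, weights) {
  v <- 0
  for (i in seq_along(nodes)) v <- v + weights[i] * nodes[[i]]$v
  ids <- vapply(nodes, function(x) x$id, integer(1))
  emit(tp, v, bw = function(g, acc, accp) {
    for (i in seq_along(ids)) if (!is.na(ids[i])) acc(ids[i], g * weights[i])
  })
}

# ---- optimizer -------------------------------------------------------------

adam_step <- function(store, pgrads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, lr_mult = NULL) {
  store$step <- store$step + 1L
  t <- store$step
  for (name in ls(pgrads)) {
    g <- pgrads[[name]]
    lr_i <- lr
    if (!is.null(lr_mult)) {
      for (pre in names(lr_mult))
        if (startsWith(name, pre)) lr_i <- lr * lr_mult[[pre]]
    }
    store$m[[name]] <- beta1 * store$m[[name]] + (1 - beta1) * g
    store$v[[name]] <- beta2 * store$v[[name]] + (1 - beta2) * g^2
    mhat <- store$m[[name]] / (1 - beta1^t)
    vhat <- store$v[[name]] / (1 - beta2^t)
    store$val[[name]] <- store$val[[name]] - lr_i * mhat / (sqrt(vhat) + eps)
  }
  invisible(store)
}

# serialize a parameter store to a plain-text JSON checkpoint; doubles are
# written as C99 hex-float strings so the round trip is bit-exact
params_to_list <- function(store) {
  lapply(store$val, function(v) list(dim = dim(v),
                                     data = sprintf("%a", as.numeric(v))))
}

params_from_list <- function(lst) {
  store <- nn_params()
  for (name in names(lst)) {
    v <- as.numeric(lst[[name]]$data)
    d <- lst[[name]]$dim
    if (!is.null(d) && length(d) > 0) v <- array(v, as.integer(d))
    param_add(store, name, v)
  }
  store
}
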