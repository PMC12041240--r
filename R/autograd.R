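# Reverse-mode automatic differentiation on dense R arrays.
#
# The engine is deliberately small: a global tape records op nodes in forward
# order; ag_backward() walks it in reverse, calling each node's closure to
# push gradients to its parents. Tensors are plain numeric arrays, network
# feature maps use the (H, W, C, B) layout. When the tape is not recording
# every op degrades to a plain array computation, so the same loss and model
# code serves both training (with gradients) and evaluation (without).

.ag <- new.env(parent = emptyenv())
.ag$recording <- FALSE
.ag$tape <- NULL
.ag$n <- 0L

ag_recording <- function() isTRUE(.ag$recording)

#' @keywords internal
ag_start <- function() {
  .ag$tape <- vector("list", 512L)
  .ag$n <- 0L
  .ag$recording <- TRUE
  invisible(NULL)
}

#' @keywords internal
ag_stop <- function() {
  .ag$recording <- FALSE
  .ag$tape <- NULL
  .ag$n <- 0L
  invisible(NULL)
}

is_node <- function(x) inherits(x, "ag_node")
nval <- function(x) if (is_node(x)) x$value else x

ag_leaf <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- NULL
  e$backfn <- NULL
  class(e) <- "ag_node"
  e
}

# A trainable parameter: an ag_node that persists across tapes and carries
# AdamW state.
ag_param <- function(value) {
  e <- ag_leaf(value)
  e$m <- 0
  e$v <- 0
  e$t <- 0L
  class(e) <- c("ag_param", "ag_node")
  e
}

ag_push <- function(value, parents, backfn) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  class(e) <- "ag_node"
  .ag$n <- .ag$n + 1L
  if (.ag$n > length(.ag$tape)) length(.ag$tape) <- 2L * length(.ag$tape)
  .ag$tape[[.ag$n]] <- e
  e
}

# Generic op constructor. `inputs` may mix nodes and plain arrays; `backfn`
# receives the output gradient and must return one gradient per input (NULL
# for inputs that need none).
ag_op <- function(value, inputs, backfn) {
  if (ag_recording() && any(vapply(inputs, is_node, logical(1)))) {
    ag_push(value, inputs, backfn)
  } else {
    value
  }
}

#' @keywords internal
ag_backward <- function(root) {
  stopifnot(is_node(root))
  root$grad <- if (is.null(dim(root$value))) rep(1, length(root$value)) else
    array(1, dim(root$value))
  if (.ag$n < 1L) return(invisible(NULL))
  for (i in seq(.ag$n, 1L)) {
    nd <- .ag$tape[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!is_node(p)) next
      g <- gs[[j]]
      if (is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL # free memory as we go
  }
  invisible(NULL)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise and reduction ops -----------------------------------------

ag_add <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  ag_op(av + bv, list(a, b), function(g) {
    list(if (length(av) == 1L && length(bv) > 1L) sum(g) else g,
         if (length(bv) == 1L && length(av) > 1L) sum(g) else g)
  })
}

ag_sub <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  ag_op(av - bv, list(a, b), function(g) {
    list(if (length(av) == 1L && length(bv) > 1L) sum(g) else g,
         if (length(bv) == 1L && length(av) > 1L) -sum(g) else -g)
  })
}

ag_mul <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  ag_op(av * bv, list(a, b), function(g) {
    ga <- g * bv
    gb <- g * av
    list(if (length(av) == 1L && length(bv) > 1L) sum(ga) else ga,
         if (length(bv) == 1L && length(av) > 1L) sum(gb) else gb)
  })
}

ag_div <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  ag_op(av / bv, list(a, b), function(g) {
    ga <- g / bv
    gb <- -g * av / (bv * bv)
    list(if (length(av) == 1L && length(bv) > 1L) sum(ga) else ga,
         if (length(bv) == 1L && length(av) > 1L) sum(gb) else gb)
  })
}

ag_scale <- function(a, k) {
  av <- nval(a)
  ag_op(av * k, list(a), function(g) list(g * k))
}

ag_pow <- function(a, p) {
  av <- nval(a)
  ag_op(av^p, list(a), function(g) list(g * p * av^(p - 1)))
}

ag_log <- function(a, eps = 1e-12) {
  av <- pmax(nval(a), eps)
  ag_op(log(av), list(a), function(g) list(g / av))
}

ag_clamp_min <- function(a, lo) {
  av <- nval(a)
  out <- pmax(av, lo)
  ag_op(out, list(a), function(g) list(g * (av > lo)))
}

ag_relu <- function(a) {
  av <- nval(a)
  out <- av * (av > 0)
  ag_op(out, list(a), function(g) list(g * (av > 0)))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-nval(a)))
  ag_op(s, list(a), function(g) list(g * s * (1 - s)))
}

ag_tanh <- function(a) {
  t <- tanh(nval(a))
  ag_op(t, list(a), function(g) list(g * (1 - t * t)))
}

ag_mean <- function(a) {
  av <- nval(a)
  n <- length(av)
  d <- dim(av)
  ag_op(mean(av), list(a), function(g) {
    gx <- array(as.numeric(g) / n, if (is.null(d)) n else d)
    list(gx)
  })
}

ag_sum <- function(a) {
  av <- nval(a)
  d <- dim(av)
  ag_op(sum(av), list(a), function(g) {
    gx <- array(as.numeric(g), if (is.null(d)) length(av) else d)
    list(gx)
  })
}

# ---- structural ops ---------------------------------------------------------

ag_reshape <- function(a, newdim) {
  av <- nval(a)
  olddim <- dim(av)
  out <- av
  dim(out) <- newdim
  ag_op(out, list(a), function(g) {
    dim(g) <- olddim
    list(g)
  })
}

ag_concat_c <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  da <- dim(av); db <- dim(bv)
  stopifnot(length(da) == 4L, all(da[-3] == db[-3]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- av
  out[, , da[3] + seq_len(db[3]), ] <- bv
  ag_op(out, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

ag_take_c <- function(a, idx) {
  av <- nval(a)
  d <- dim(av)
  out <- av[, , idx, , drop = FALSE]
  ag_op(out, list(a), function(g) {
    gx <- array(0, d)
    gx[, , idx, ] <- g
    list(gx)
  })
}

# Sub-pixel (pixel-shuffle) upsampling by integer factor r:
# (H, W, C*r^2, B) -> (H*r, W*r, C, B). Input channel (c-1)*r^2+(ri-1)*r+rj
# lands on output offset (ri, rj) inside each r x r cell.
ag_pixel_shuffle <- function(a, r) {
  av <- nval(a)
  d <- dim(av)
  H <- d[1]; W <- d[2]; Crr <- d[3]; B <- d[4]
  stopifnot(Crr %% (r * r) == 0L)
  C <- Crr %/% (r * r)
  # (H, W, rj, ri, C, B) -> want out[(h-1)r+ri, (w-1)r+rj, c, b]
  tmp <- av
  dim(tmp) <- c(H, W, r, r, C, B)       # channel index decomposed as (rj, ri, c)
  tmp <- aperm(tmp, c(4, 1, 3, 2, 5, 6)) # (ri, H, rj, W, C, B)
  dim(tmp) <- c(H * r, W * r, C, B)
  ag_op(tmp, list(a), function(g) {
    dim(g) <- c(r, H, r, W, C, B)
    g <- aperm(g, c(2, 4, 3, 1, 5, 6))   # back to (H, W, rj, ri, C, B)
    dim(g) <- d
    list(g)
  })
}

ag_avgpool2 <- function(a) {
  av <- nval(a)
  d <- dim(av)
  H <- d[1] - d[1] %% 2L; W <- d[2] - d[2] %% 2L # crop odd edge
  x <- av[seq_len(H), seq_len(W), , , drop = FALSE]
  o <- (x[seq(1, H, 2), seq(1, W, 2), , , drop = FALSE] +
        x[seq(2, H, 2), seq(1, W, 2), , , drop = FALSE] +
        x[seq(1, H, 2), seq(2, W, 2), , , drop = FALSE] +
        x[seq(2, H, 2), seq(2, W, 2), , , drop = FALSE]) / 4
  ag_op(o, list(a), function(g) {
    gx <- array(0, d)
    ge <- g[rep(seq_len(H %/% 2L), each = 2), rep(seq_len(W %/% 2L), each = 2), , ,
            drop = FALSE] / 4
    gx[seq_len(H), seq_len(W), , ] <- ge
    list(gx)
  })
}

ag_gap <- function(a) {
  av <- nval(a)
  d <- dim(av)
  n <- d[1] * d[2]
  m <- apply(av, c(3, 4), mean)
  out <- array(m, c(1, 1, d[3], d[4]))
  ag_op(out, list(a), function(g) {
    gx <- array(rep(as.vector(g) / n, each = n), d)
    list(gx)
  })
}

# Separable same-size blur with a fixed symmetric 1-D kernel (self-adjoint).
ag_sepblur <- function(a, k) {
  av <- nval(a)
  out <- .cpp_sepconv2d(av, k)
  ag_op(out, list(a), function(g) list(.cpp_sepconv2d(g, k)))
}

# ---- learned layers ---------------------------------------------------------

ag_conv2d <- function(x, w, b, pad = 1L, stride = 1L) {
  xv <- nval(x); wv <- nval(w); bv <- nval(b)
  out <- .cpp_conv2d_fwd(xv, wv, bv, as.integer(pad), as.integer(stride))
  ag_op(out, list(x, w, b), function(g) {
    r <- .cpp_conv2d_bwd(xv, wv, g, as.integer(pad), as.integer(stride))
    list(r$gx, r$gw, r$gb)
  })
}

# Batch normalization over (H, W, B) per channel. `state` is an environment
# holding running_mean / running_var used in eval mode.
ag_batchnorm <- function(x, gamma, beta, state, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  xv <- nval(x)
  gv <- as.vector(nval(gamma)); bv <- as.vector(nval(beta))
  d <- dim(xv)
  C <- d[3]
  n <- d[1] * d[2] * d[4]
  xm <- aperm(xv, c(1, 2, 4, 3))
  dim(xm) <- c(n, C)
  if (training) {
    mu <- colMeans(xm)
    vr <- colMeans(xm^2) - mu^2
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * vr * n / max(n - 1, 1)
  } else {
    mu <- state$running_mean
    vr <- state$running_var
  }
  ivar <- 1 / sqrt(vr + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, ivar, "*")
  ym <- sweep(sweep(xhat, 2, gv, "*"), 2, bv, "+")
  y <- ym
  dim(y) <- c(d[1], d[2], d[4], C)
  y <- aperm(y, c(1, 2, 4, 3))
  ag_op(y, list(x, gamma, beta), function(g) {
    gm <- aperm(g, c(1, 2, 4, 3))
    dim(gm) <- c(n, C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- sweep(gm, 2, gv, "*")
    if (training) {
      m1 <- colMeans(dxhat)
      m2 <- colMeans(dxhat * xhat)
      dxm <- sweep(sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*"), 2, ivar, "*")
    } else {
      dxm <- sweep(dxhat, 2, ivar, "*")
    }
    dx <- dxm
    dim(dx) <- c(d[1], d[2], d[4], C)
    dx <- aperm(dx, c(1, 2, 4, 3))
    list(dx, dgamma, dbeta)
  })
}

# Bicubic (Catmull-Rom, a = -0.5) resize along H and W, realized as two
# matrix contractions so the adjoint is exact in the backward pass.
.bicubic_cache <- new.env(parent = emptyenv())

bicubic_matrix <- function(n_in, n_out) {
  key <- paste0(n_in, ">", n_out)
  if (!is.null(.bicubic_cache[[key]])) return(.bicubic_cache[[key]])
  A <- matrix(0, n_out, n_in)
  a <- -0.5
  cub <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
           ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
  }
  scale <- n_out / n_in
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) / scale + 0.5 # 1-based center position in source
    i0 <- floor(src - 2) + 1
    idx <- i0:(i0 + 3)
    wts <- cub(src - idx)
    idx <- pmin(pmax(idx, 1L), n_in) # clamp at edges
    s <- sum(wts)
    if (s != 0) wts <- wts / s
    for (j in seq_along(idx)) A[i, idx[j]] <- A[i, idx[j]] + wts[j]
  }
  .bicubic_cache[[key]] <- A
  A
}

.apply_rows <- function(x, M) {
  # x: (H, W, C, B) -> (nrow(M), W, C, B), contracting over H
  d <- dim(x)
  dim(x) <- c(d[1], prod(d[-1]))
  y <- M %*% x
  dim(y) <- c(nrow(M), d[-1])
  y
}

ag_resize_bicubic <- function(x, h_out, w_out) {
  xv <- nval(x)
  d <- dim(xv)
  A <- bicubic_matrix(d[1], h_out)
  B <- bicubic_matrix(d[2], w_out)
  fwd <- function(v) {
    y <- .apply_rows(v, A)
    y <- aperm(y, c(2, 1, 3, 4))
    y <- .apply_rows(y, B)
    aperm(y, c(2, 1, 3, 4))
  }
  bwd <- function(g) {
    y <- .apply_rows(g, t(A))
    y <- aperm(y, c(2, 1, 3, 4))
    y <- .apply_rows(y, t(B))
    aperm(y, c(2, 1, 3, 4))
  }
  ag_op(fwd(xv), list(x), function(g) list(bwd(g)))
}

# Reverse Huber penalty as a primitive op: L1 inside |d| <= c, scaled
# quadratic outside, summed over all elements.
ag_berhu_sum <- function(pred, target, c) {
  pv <- nval(pred); tv <- nval(target)
  d <- pv - tv
  ad <- abs(d)
  inl <- ad <= c
  val <- sum(ad[inl]) + sum((d[!inl]^2 + c^2) / (2 * c))
  ag_op(val, list(pred, target), function(g) {
    gd <- ifelse(inl, sign(d), d / c) * as.numeric(g)
    list(gd, -gd)
  })
}
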