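# Internal feed-forward engine.
#
# Convolutional activations are stored time-major: a (B*L) x C matrix whose
# row (t-1)*B + b holds sample b at position t.  A 1-D convolution with an
# odd kernel of size k and zero ("same") padding is then k contiguous-block
# matrix products, one per kernel tap, which keeps everything on BLAS.

.act_relu <- function(x) {
  x[x < 0] <- 0
  x
}

.softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# ---- layer shape / parameter bookkeeping ------------------------------------

# input: list(kind = "tokens", length = L) | list(kind = "dense", dim = D)
# returns a list of per-layer output shapes; a shape is either
# list(L = positions, C = channels) or list(D = width)
.walk_shapes <- function(input, layers) {
  shape <- if (input$kind == "tokens") list(L = input$length, C = NA_integer_)
           else list(D = input$dim)
  out <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    shape <- switch(ly$type,
      embedding = list(L = shape$L, C = ly$dim),
      conv = list(L = shape$L, C = ly$filters),
      maxpool = list(L = shape$L %/% ly$pool, C = shape$C),
      dropout = shape,
      flatten = list(D = shape$L * shape$C),
      dense = list(D = ly$units),
      stop(sprintf("unknown layer type '%s'", ly$type)))
    out[[k]] <- shape
  }
  out
}

.layer_param_count <- function(input, layers) {
  shapes <- .walk_shapes(input, layers)
  total <- 0L
  shape_in <- if (input$kind == "tokens") list(L = input$length, C = NA)
              else list(D = input$dim)
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    total <- total + switch(ly$type,
      embedding = ly$vocab * ly$dim,
      conv = ly$kernel * shape_in$C * ly$filters + ly$filters,
      dense = shape_in$D * ly$units + ly$units,
      0L)
    shape_in <- shapes[[k]]
  }
  total
}

.init_layers <- function(input, layers) {
  shapes <- .walk_shapes(input, layers)
  shape_in <- if (input$kind == "tokens") list(L = input$length, C = NA)
              else list(D = input$dim)
  w <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    w[[k]] <- switch(ly$type,
      embedding = list(W = matrix(runif(ly$vocab * ly$dim, -0.5, 0.5),
                                  ly$vocab, ly$dim)),
      conv = list(W = .glorot(ly$kernel * shape_in$C, ly$kernel * ly$filters,
                              c(ly$kernel * shape_in$C, ly$filters)),
                  b = numeric(ly$filters)),
      dense = list(W = .glorot(shape_in$D, ly$units,
                               c(shape_in$D, ly$units)),
                   b = numeric(ly$units)),
      list())
    shape_in <- shapes[[k]]
  }
  w
}

# ---- forward / backward -----------------------------------------------------

# x for a "tokens" branch: integer matrix B x L (codes, 0-based);
# for a "dense" branch: numeric matrix or dgCMatrix B x D.
# Returns list(out = B x D matrix, cache = per-layer forward state).
.branch_forward <- function(input, layers, weights, x, training = FALSE) {
  cache <- vector("list", length(layers))
  if (input$kind == "tokens") {
    B <- nrow(x); L <- ncol(x)
    cur <- NULL  # set by the embedding layer
  } else {
    B <- nrow(x); L <- NA_integer_
    cur <- x
  }
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    if (ly$type == "embedding") {
      idx <- as.vector(x) + 1L  # column-major == time-major rows
      cur <- weights[[k]]$W[idx, , drop = FALSE]
      cache[[k]] <- list(idx = idx)
    } else if (ly$type == "conv") {
      # im2col: zero-pad h positions on both sides, then column block 'tap'
      # is the contiguous padded row range for output positions 1..L
      h <- (ly$kernel - 1L) %/% 2L
      C <- ncol(cur)
      pad <- matrix(0, h * B, C)
      Xp <- rbind(pad, cur, pad)
      Xcol <- matrix(0, B * L, ly$kernel * C)
      for (tap in seq_len(ly$kernel)) {
        rows <- ((tap - 1L) * B + 1L):((L + tap - 1L) * B)
        Xcol[, ((tap - 1L) * C + 1L):(tap * C)] <- Xp[rows, ]
      }
      out <- Xcol %*% weights[[k]]$W
      out <- out + matrix(weights[[k]]$b, nrow(out), ncol(out), byrow = TRUE)
      mask <- out > 0
      out[!mask] <- 0
      cache[[k]] <- list(xcol = Xcol, mask = mask, C_in = C)
      cur <- out
    } else if (ly$type == "maxpool") {
      p <- ly$pool; T2 <- L %/% p
      A <- array(cur, c(B, L, ncol(cur)))
      C <- ncol(cur)
      out <- NULL; arg <- NULL
      for (j in seq_len(p)) {
        sl <- A[, seq.int(j, T2 * p, by = p), , drop = FALSE]
        dim(sl) <- c(B * T2, C)
        if (is.null(out)) {
          out <- sl; arg <- matrix(1L, B * T2, C)
        } else {
          upd <- sl > out
          out[upd] <- sl[upd]
          arg[upd] <- j
        }
      }
      cache[[k]] <- list(arg = arg, L_in = L)
      cur <- out
      L <- T2
    } else if (ly$type == "dropout") {
      if (training && ly$rate > 0) {
        keep <- 1 - ly$rate
        m <- matrix((runif(length(cur)) < keep) / keep,
                    nrow(cur), ncol(cur))
        cur <- cur * m
        cache[[k]] <- list(mask = m)
      } else cache[[k]] <- list(mask = NULL)
    } else if (ly$type == "flatten") {
      C <- ncol(cur)
      dim(cur) <- NULL
      cur <- matrix(cur, nrow = B, ncol = L * C)  # col index (c-1)*L + t
      cache[[k]] <- list(L = L, C = C)
    } else if (ly$type == "dense") {
      z <- as.matrix(cur %*% weights[[k]]$W)
      z <- z + matrix(weights[[k]]$b, nrow(z), ncol(z), byrow = TRUE)
      a <- switch(ly$activation,
                  relu = .act_relu(z),
                  softmax = .softmax_rows(z),
                  linear = z)
      cache[[k]] <- list(x = cur, z = z, a = a)
      cur <- a
    }
  }
  list(out = cur, cache = cache, B = B)
}

# dout: gradient wrt branch output.  Returns list(grads = per-layer grads).
.branch_backward <- function(input, layers, weights, cache, dout, B) {
  grads <- vector("list", length(layers))
  cur <- dout
  L_at <- integer(length(layers))  # L after each layer, reconstructed below
  for (k in rev(seq_along(layers))) {
    ly <- layers[[k]]
    cc <- cache[[k]]
    if (ly$type == "dense") {
      da <- cur
      dz <- switch(ly$activation,
        relu = da * (cc$z > 0),
        softmax = da,  # combined softmax + cross-entropy gradient arrives here
        linear = da)
      gW <- if (is(cc$x, "sparseMatrix")) as.matrix(Matrix::crossprod(cc$x, dz))
            else crossprod(cc$x, dz)
      grads[[k]] <- list(W = gW, b = colSums(dz))
      cur <- if (k == 1L && input$kind != "tokens") NULL
             else as.matrix(dz %*% t(weights[[k]]$W))
    } else if (ly$type == "flatten") {
      cur <- matrix(as.vector(cur), nrow = B * cc$L, ncol = cc$C)
      grads[[k]] <- list()
    } else if (ly$type == "dropout") {
      if (!is.null(cc$mask)) cur <- cur * cc$mask
      grads[[k]] <- list()
    } else if (ly$type == "maxpool") {
      p <- ly$pool; L_in <- cc$L_in; T2 <- L_in %/% p
      C <- ncol(cur)
      dY <- array(cur, c(B, T2, C))
      argA <- array(cc$arg, c(B, T2, C))
      dX <- array(0, c(B, L_in, C))
      for (j in seq_len(p)) {
        sel <- argA == j
        tmp <- array(0, c(B, T2, C))
        tmp[sel] <- dY[sel]
        cols <- seq.int(j, T2 * p, by = p)
        dX[, cols, ] <- dX[, cols, ] + tmp
      }
      dim(dX) <- c(B * L_in, C)
      cur <- dX
      grads[[k]] <- list()
    } else if (ly$type == "conv") {
      h <- (ly$kernel - 1L) %/% 2L
      dz <- cur * cc$mask
      L_here <- nrow(dz) %/% B
      C <- cc$C_in
      gW <- crossprod(cc$xcol, dz)
      dXcol <- dz %*% t(weights[[k]]$W)
      dXp <- matrix(0, (L_here + 2L * h) * B, C)
      for (tap in seq_len(ly$kernel)) {
        rows <- ((tap - 1L) * B + 1L):((L_here + tap - 1L) * B)
        dXp[rows, ] <- dXp[rows, ] +
          dXcol[, ((tap - 1L) * C + 1L):(tap * C)]
      }
      grads[[k]] <- list(W = gW, b = colSums(dz))
      cur <- dXp[(h * B + 1L):((h + L_here) * B), , drop = FALSE]
    } else if (ly$type == "embedding") {
      gW <- rowsum(cur, cc$idx)
      full <- matrix(0, ly$vocab, ly$dim)
      full[as.integer(rownames(gW)), ] <- gW
      grads[[k]] <- list(W = full)
      cur <- NULL
    }
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

.adam_init <- function(weights) {
  walk <- function(w) {
    if (is.list(w)) return(lapply(w, walk))
    list(m = w * 0, v = w * 0)
  }
  lapply(weights, walk)
}

.adam_update <- function(weights, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  upd <- function(w, g, s) {
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g * g
    mhat <- s$m / (1 - beta1^t)
    vhat <- s$v / (1 - beta2^t)
    w <- w - lr * mhat / (sqrt(vhat) + eps)
    list(w = w, s = s)
  }
  walk <- function(w, g, s) {
    if (is.list(w)) {
      for (nm in seq_along(w)) {
        r <- walk(w[[nm]], g[[nm]], s[[nm]])
        w[[nm]] <- r$w
        s[[nm]] <- r$s
      }
      return(list(w = w, s = s))
    }
    upd(w, g, s)
  }
  walk(weights, grads, state)
}
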