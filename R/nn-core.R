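# Minimal CNN engine for dense segmentation.
#
# Feature maps live as (B*H*W) x C matrices; pixel p of image b maps to row
# (b-1)*H*W + (c-1)*H + r (column-major within the image, matching R's
# matrix layout so a single-image channel reshapes with matrix(x, H, W)).
# Convolutions are im2col + BLAS matrix products; the input gradient is the
# correlation of the output gradient with the flipped kernel, so the same
# im2col machinery serves both directions. Index matrices are cached per
# (B, H, W, kernel) combination.

.oct_idx_cache <- new.env(parent = emptyenv())

idx_key <- function(...) paste(..., sep = "_")

# gather-index matrix (B*H*W) x (kh*kw) for same-padded correlation;
# out-of-image taps point at a sentinel zero row (B*H*W + 1)
im2col_idx <- function(B, H, W, kh, kw) {
  key <- idx_key("col", B, H, W, kh, kw)
  hit <- .oct_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- rep(seq_len(H), W)
  c <- rep(seq_len(W), each = H)
  seq_dr <- seq.int(-(kh - 1L) %/% 2L, (kh - 1L) %/% 2L)
  seq_dc <- seq.int(-(kw - 1L) %/% 2L, (kw - 1L) %/% 2L)
  dr_j <- rep(seq_dr, times = kw)
  dc_j <- rep(seq_dc, each = kh)
  k2 <- kh * kw
  HW <- H * W
  base <- matrix(NA_integer_, HW, k2)
  for (j in seq_len(k2)) {
    rr <- r + dr_j[j]
    cc <- c + dc_j[j]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    base[ok, j] <- (cc[ok] - 1L) * H + rr[ok]
  }
  full <- base[rep(seq_len(HW), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * HW, each = HW)
  full[is.na(full)] <- B * HW + 1L
  .oct_idx_cache[[key]] <- full
  full
}

im2col <- function(x, B, H, W, kh, kw) {
  idx <- im2col_idx(B, H, W, kh, kw)
  xa <- rbind(x, 0)
  k2 <- kh * kw
  cols <- vector("list", k2)
  for (j in seq_len(k2)) cols[[j]] <- xa[idx[, j], , drop = FALSE]
  do.call(cbind, cols)
}

# weight matrix for the transposed/backward correlation:
# W rows ordered (tap j, in-channel), W_back rows ordered (tap j, out-channel)
flip_weights <- function(W, k2, C_in, C_out) {
  Wa <- array(W, dim = c(C_in, k2, C_out))
  matrix(aperm(Wa[, k2:1, , drop = FALSE], c(3, 2, 1)), k2 * C_out, C_in)
}

pool_idx <- function(B, H, W) {
  key <- idx_key("pool", B, H, W)
  hit <- .oct_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- H %/% 2L; W2 <- W %/% 2L
  r2 <- rep(seq_len(H2), W2)
  c2 <- rep(seq_len(W2), each = H2)
  HW <- H * W
  boff <- rep((seq_len(B) - 1L) * HW, each = H2 * W2)
  qs <- lapply(1:4, function(q) {
    dr <- (q - 1L) %% 2L
    dc <- (q - 1L) %/% 2L
    rep.int((2L * c2 - 2L + dc) * H + (2L * r2 - 1L + dr), B) + boff
  })
  .oct_idx_cache[[key]] <- qs
  qs
}

up_idx <- function(B, H, W) {
  key <- idx_key("up", B, H, W)
  hit <- .oct_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  r2 <- rep(seq_len(2L * H), 2L * W)
  c2 <- rep(seq_len(2L * W), each = 2L * H)
  src <- ((c2 + 1L) %/% 2L - 1L) * H + (r2 + 1L) %/% 2L
  full <- rep.int(src, B) + rep((seq_len(B) - 1L) * H * W, each = 4L * H * W)
  .oct_idx_cache[[key]] <- full
  full
}

# edge-padded (replicate) 1-D conv index for length-L strips, kernel 3:
# clamping at the ends keeps a constant strip exactly constant under the conv
strip1d_idx <- function(B, L) {
  key <- idx_key("s1d", B, L)
  hit <- .oct_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- seq_len(L)
  base <- cbind(pmax(pos - 1L, 1L), pos, pmin(pos + 1L, L))
  full <- base[rep(seq_len(L), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * L, each = L)
  .oct_idx_cache[[key]] <- full
  full
}

conv1d_edge <- function(x, W, b, B, L) {
  idx <- strip1d_idx(B, L)
  col <- cbind(x[idx[, 1], , drop = FALSE], x[idx[, 2], , drop = FALSE],
               x[idx[, 3], , drop = FALSE])
  sweep(col %*% W, 2, b, "+")
}

conv1d_edge_backward <- function(x, W, dY, B, L) {
  idx <- strip1d_idx(B, L)
  C <- ncol(x)
  col <- cbind(x[idx[, 1], , drop = FALSE], x[idx[, 2], , drop = FALSE],
               x[idx[, 3], , drop = FALSE])
  dW <- crossprod(col, dY)
  db <- colSums(dY)
  dx <- matrix(0, nrow(x), C)
  for (j in 1:3) {
    blk <- W[((j - 1) * C + 1):(j * C), , drop = FALSE]
    contrib <- rowsum(dY %*% t(blk), idx[, j], reorder = FALSE)
    tgt <- as.integer(rownames(contrib))
    dx[tgt, ] <- dx[tgt, , drop = FALSE] + contrib
  }
  list(dW = dW, db = db, dx = dx)
}

strip_groups <- function(B, H, W) {
  key <- idx_key("strip", B, H, W)
  hit <- .oct_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  gh <- rep.int(rep(seq_len(H), W), B) + rep((seq_len(B) - 1L) * H, each = H * W)
  gv <- rep.int(rep(seq_len(W), each = H), B) + rep((seq_len(B) - 1L) * W, each = H * W)
  out <- list(gh = gh, gv = gv)
  .oct_idx_cache[[key]] <- out
  out
}

# ---- layer forward/backward -------------------------------------------------

layer_forward <- function(node, ins, B, training) {
  switch(node$op,
    conv = {
      m <- node$meta
      col <- im2col(ins[[1]], B, m$H, m$W, m$kh, m$kw)
      y <- col %*% node$params$W
      y <- sweep(y, 2, node$params$b, "+")
      list(out = y, cache = NULL)
    },
    bn = {
      x <- ins[[1]]
      eps <- node$meta$eps
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc^2)
        node$state$running_mean <- (1 - node$meta$momentum) * node$state$running_mean +
          node$meta$momentum * mu
        node$state$running_var <- (1 - node$meta$momentum) * node$state$running_var +
          node$meta$momentum * v
      } else {
        mu <- node$state$running_mean
        v <- node$state$running_var
        xc <- sweep(x, 2, mu)
      }
      inv_std <- 1 / sqrt(v + eps)
      xhat <- sweep(xc, 2, inv_std, "*")
      y <- sweep(sweep(xhat, 2, node$params$gamma, "*"), 2, node$params$beta, "+")
      list(out = y, cache = list(xhat = xhat, inv_std = inv_std), node = node)
    },
    relu = list(out = pmax(ins[[1]], 0), cache = NULL),
    sigmoid = {
      y <- 1 / (1 + exp(-ins[[1]]))
      list(out = y, cache = y)
    },
    pool = {
      m <- node$meta
      qs <- pool_idx(B, m$H, m$W)
      g <- ins[[1]][qs[[1]], , drop = FALSE]
      sel <- matrix(1L, nrow(g), ncol(g))
      for (q in 2:4) {
        gq <- ins[[1]][qs[[q]], , drop = FALSE]
        upd <- gq > g
        g[upd] <- gq[upd]
        sel[upd] <- q
      }
      list(out = g, cache = sel)
    },
    up = {
      m <- node$meta
      list(out = ins[[1]][up_idx(B, m$H, m$W), , drop = FALSE], cache = NULL)
    },
    concat = {
      list(out = cbind(ins[[1]], ins[[2]]), cache = ncol(ins[[1]]))
    },
    add = list(out = ins[[1]] + ins[[2]], cache = NULL),
    strip_pool = {
      m <- node$meta
      x <- ins[[1]]
      grp <- strip_groups(B, m$H, m$W)
      yh <- rowsum(x, grp$gh, reorder = FALSE) / m$W
      yv <- rowsum(x, grp$gv, reorder = FALSE) / m$H
      th <- conv1d_edge(yh, node$params$Wh, node$params$bh, B, m$H)
      tv <- conv1d_edge(yv, node$params$Wv, node$params$bv, B, m$W)
      s <- th[grp$gh, , drop = FALSE] + tv[grp$gv, , drop = FALSE]
      u <- sweep(s %*% node$params$Wf, 2, node$params$bf, "+")
      g <- 1 / (1 + exp(-u))
      list(out = x * g, cache = list(g = g, s = s, yh = yh, yv = yv))
    },
    stop("unknown op: ", node$op)
  )
}

layer_backward <- function(node, ins, cache, dY, B) {
  switch(node$op,
    conv = {
      m <- node$meta
      col <- im2col(ins[[1]], B, m$H, m$W, m$kh, m$kw)
      dW <- crossprod(col, dY)
      db <- colSums(dY)
      Wb <- flip_weights(node$params$W, m$kh * m$kw, m$C_in, m$C_out)
      dX <- im2col(dY, B, m$H, m$W, m$kh, m$kw) %*% Wb
      list(dins = list(dX), dparams = list(W = dW, b = db))
    },
    bn = {
      xhat <- cache$xhat
      n <- nrow(dY)
      dgamma <- colSums(dY * xhat)
      dbeta <- colSums(dY)
      coef <- node$params$gamma * cache$inv_std
      dX <- sweep(dY, 2, dbeta / n) - sweep(xhat, 2, dgamma / n, "*")
      dX <- sweep(dX, 2, coef, "*")
      list(dins = list(dX), dparams = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dins = list(dY * (ins[[1]] > 0)), dparams = NULL),
    sigmoid = list(dins = list(dY * cache * (1 - cache)), dparams = NULL),
    pool = {
      m <- node$meta
      qs <- pool_idx(B, m$H, m$W)
      dX <- matrix(0, nrow(ins[[1]]), ncol(ins[[1]]))
      for (q in 1:4) dX[qs[[q]], ] <- dY * (cache == q)
      list(dins = list(dX), dparams = NULL)
    },
    up = {
      m <- node$meta
      src <- up_idx(B, m$H, m$W)
      dX <- rowsum(dY, src, reorder = FALSE)
      # rowsum groups appear in first-appearance order; restore natural order
      dX <- dX[order(as.integer(rownames(dX))), , drop = FALSE]
      list(dins = list(dX), dparams = NULL)
    },
    concat = {
      n1 <- cache
      list(dins = list(dY[, seq_len(n1), drop = FALSE],
                       dY[, -seq_len(n1), drop = FALSE]),
           dparams = NULL)
    },
    add = list(dins = list(dY, dY), dparams = NULL),
    strip_pool = {
      m <- node$meta
      x <- ins[[1]]
      grp <- strip_groups(B, m$H, m$W)
      g <- cache$g
      dx_gate <- dY * g
      du <- (dY * x) * g * (1 - g)
      dWf <- crossprod(cache$s, du)
      dbf <- colSums(du)
      ds <- du %*% t(node$params$Wf)
      dth <- rowsum(ds, grp$gh, reorder = FALSE)
      dth <- dth[order(as.integer(rownames(dth))), , drop = FALSE]
      dtv <- rowsum(ds, grp$gv, reorder = FALSE)
      dtv <- dtv[order(as.integer(rownames(dtv))), , drop = FALSE]
      bh <- conv1d_edge_backward(cache$yh, node$params$Wh, dth, B, m$H)
      bv <- conv1d_edge_backward(cache$yv, node$params$Wv, dtv, B, m$W)
      dX <- dx_gate + bh$dx[grp$gh, , drop = FALSE] / m$W +
        bv$dx[grp$gv, , drop = FALSE] / m$H
      list(dins = list(dX),
           dparams = list(Wh = bh$dW, bh = bh$db, Wv = bv$dW, bv = bv$db,
                          Wf = dWf, bf = dbf))
    },
    stop("unknown op: ", node$op)
  )
}

# ---- graph execution --------------------------------------------------------

model_forward <- function(model, x, B, training = FALSE) {
  acts <- list(input = x)
  caches <- list()
  for (i in seq_along(model$nodes)) {
    node <- model$nodes[[i]]
    ins <- lapply(node$inputs, function(nm) acts[[nm]])
    res <- layer_forward(node, ins, B, training)
    acts[[node$name]] <- res$out
    caches[[node$name]] <- res$cache
    if (!is.null(res$node)) model$nodes[[i]] <- res$node  # bn running stats
  }
  list(out = acts[[model$out_name]], acts = acts, caches = caches, model = model)
}

# Re-estimate batch-norm running statistics with un-augmented forward passes.
# Training minibatches are small and photometrically jittered, so the running
# averages accumulated during optimization drift from the statistics of clean
# images; a few high-momentum calibration passes fix the inference-mode gap.
bn_recalibrate <- function(model, images, batch_size = 10L, passes = 3L,
                           momentum = 0.5) {
  old_mom <- lapply(model$nodes, function(n) n$meta$momentum)
  for (i in seq_along(model$nodes)) {
    if (model$nodes[[i]]$op == "bn") model$nodes[[i]]$meta$momentum <- momentum
  }
  n <- length(images)
  for (pass in seq_len(passes)) {
    for (start in seq(1, n, by = batch_size)) {
      ids <- start:min(start + batch_size - 1L, n)
      x <- matrix(unlist(images[ids], use.names = FALSE), ncol = 1)
      model <- model_forward(model, x, length(ids), training = TRUE)$model
    }
  }
  for (i in seq_along(model$nodes)) {
    if (model$nodes[[i]]$op == "bn") model$nodes[[i]]$meta$momentum <- old_mom[[i]]
  }
  model
}

model_backward <- function(model, acts, caches, dOut, B) {
  dacts <- list()
  dacts[[model$out_name]] <- dOut
  grads <- list()
  for (i in rev(seq_along(model$nodes))) {
    node <- model$nodes[[i]]
    g <- dacts[[node$name]]
    if (is.null(g)) next
    ins <- lapply(node$inputs, function(nm) acts[[nm]])
    res <- layer_backward(node, ins, caches[[node$name]], g, B)
    for (j in seq_along(node$inputs)) {
      nm <- node$inputs[[j]]
      if (nm == "input") next
      if (is.null(dacts[[nm]])) dacts[[nm]] <- res$dins[[j]]
      else dacts[[nm]] <- dacts[[nm]] + res$dins[[j]]
    }
    if (!is.null(res$dparams)) grads[[node$name]] <- res$dparams
    dacts[[node$name]] <- NULL  # free
  }
  grads
}
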