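# Independent brute-force oracles, deliberately naive implementations.

# Dice by explicit pixel-set counting.
oracle_dice <- function(x, y) {
  sx <- which(x == 1)
  sy <- which(y == 1)
  if (length(sx) == 0 && length(sy) == 0) return(1)
  2 * length(intersect(sx, sy)) / (length(sx) + length(sy))
}

# Surface points by explicit neighbour loops (4-neighbourhood, border =
# background).
oracle_surface <- function(m) {
  pts <- NULL
  h <- nrow(m); w <- ncol(m)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (m[r, c] != 1) next
      nb <- c(
        if (r > 1) m[r - 1, c] else 0,
        if (r < h) m[r + 1, c] else 0,
        if (c > 1) m[r, c - 1] else 0,
        if (c < w) m[r, c + 1] else 0
      )
      if (any(nb == 0) || r == 1 || r == h || c == 1 || c == w) {
        pts <- rbind(pts, c(r, c))
      }
    }
  }
  pts
}

# ASSD by all-pairs nearest distances, double loops.
oracle_assd <- function(x, y) {
  bx <- oracle_surface(x)
  by <- oracle_surface(y)
  nearest <- function(from, to) {
    vapply(seq_len(nrow(from)), function(i) {
      min(vapply(seq_len(nrow(to)), function(j) {
        sqrt(sum((from[i, ] - to[j, ])^2))
      }, numeric(1)))
    }, numeric(1))
  }
  dx <- nearest(bx, by)
  dy <- nearest(by, bx)
  (sum(dx) + sum(dy)) / (length(dx) + length(dy))
}

# Largest 8-connected component by recursive flood fill.
oracle_largest_component <- function(m) {
  h <- nrow(m); w <- ncol(m)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (m[r0, c0] != 1 || lab[r0, c0] != 0) next
    cur <- cur + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r >= 1 && r <= h && c >= 1 && c <= w &&
            m[r, c] == 1 && lab[r, c] == 0) {
          lab[r, c] <- cur
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  if (cur == 0) return(m)
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), h, w)
}

random_mask <- function(h = 8, w = 8, p = 0.4) {
  matrix(rbinom(h * w, 1, p), h, w)
}

# a quickly trained tiny model, shared across tests that need one
trained_tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- phantom_dataset(12, phantom_spec("tiny"), seed = 401)
      mod <- build_network(network_config("unet", "tiny"), init_seed = 401)
      cache <<- train_network(mod, ds, train_config(epochs = 8, seed = 401))$model
    }
    cache
  }
})
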