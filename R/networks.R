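#' Configuration of a segmentation network
#'
#' Two encoder-decoder architectures are available. `"unet"` is a U-Net with
#' batch normalization after every convolution. `"resnet101"` is a residual
#' encoder-decoder: a ResNet-style encoder (identity-shortcut residual
#' blocks) feeding a lightweight upsampling decoder with skip connections —
#' a classifier backbone alone cannot emit dense masks, so the decoder is a
#' declared convention. In both, the deepest (bottleneck) stage can be
#' replaced by a strip-pooling block that grows the receptive field along
#' entire image rows and columns (the natural axes of layered OCT anatomy).
#'
#' The `"tiny"` preset (64x96 input, 8 base channels, depth 2, ResNet-18-like
#' encoder) is the CPU test target; the `"full"` preset (496x768 input,
#' 64 base channels, depth 4, deeper residual stages) is buildable at full
#' scale but not exercised routinely.
#'
#' @param architecture `"unet"` or `"resnet101"`.
#' @param preset `"tiny"` or `"full"`; sets defaults, each overridable.
#' @param base_channels Channels of the first encoder stage (>= 4).
#' @param depth Number of 2x downsamplings (>= 2); input dimensions must be
#'   divisible by `2^depth`.
#' @param use_strip_pooling Replace the bottleneck with a strip-pooling block.
#' @param input_shape Integer `(rows, cols)` of the input B-scan.
#' @param blocks_per_stage Residual blocks per encoder stage
#'   (`"resnet101"` only).
#' @return A `network_config` object.
#' @export
network_config <- function(architecture = c("unet", "resnet101"),
                           preset = c("tiny", "full"),
                           base_channels = NULL, depth = NULL,
                           use_strip_pooling = TRUE,
                           input_shape = NULL,
                           blocks_per_stage = NULL) {
  architecture <- match.arg(architecture)
  preset <- match.arg(preset)
  def <- if (preset == "tiny") {
    list(base_channels = 8L, depth = 2L, input_shape = c(64L, 96L),
         blocks_per_stage = 2L)
  } else {
    list(base_channels = 64L, depth = 4L, input_shape = c(496L, 768L),
         blocks_per_stage = 4L)
  }
  cfg <- structure(list(
    architecture = architecture,
    preset = preset,
    base_channels = as.integer(base_channels %||% def$base_channels),
    depth = as.integer(depth %||% def$depth),
    use_strip_pooling = isTRUE(use_strip_pooling),
    input_shape = as.integer(input_shape %||% def$input_shape),
    blocks_per_stage = as.integer(blocks_per_stage %||% def$blocks_per_stage)
  ), class = "network_config")
  if (cfg$base_channels < 4) stop("base_channels must be >= 4")
  if (cfg$depth < 2) stop("depth must be >= 2")
  if (any(cfg$input_shape %% (2^cfg$depth) != 0)) {
    stop("input dimensions (", paste(cfg$input_shape, collapse = "x"),
         ") must be divisible by 2^depth = ", 2^cfg$depth)
  }
  cfg
}

#' Build a segmentation network
#'
#' Constructs the model graph described by a [network_config()] with seeded
#' He-normal weight initialization. The model maps a single-channel image to
#' a probability map of identical spatial shape; the final activation is an
#' elementwise logistic squashing, so outputs always lie in \[0, 1\].
#'
#' @param cfg A [network_config()].
#' @param init_seed Integer seed for weight initialization.
#' @return A `seg_model` object.
#' @export
build_network <- function(cfg, init_seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  builder <- if (cfg$architecture == "unet") build_unet_graph else build_resnet_graph
  model <- with_seed(as.integer(init_seed), builder(cfg))
  model$cfg <- cfg
  model$init_seed <- as.integer(init_seed)
  class(model) <- "seg_model"
  model
}

# ---- graph builders ---------------------------------------------------------

new_graph <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

g_add <- function(g, name, op, inputs, params = NULL, meta = NULL, state = NULL) {
  g$nodes[[length(g$nodes) + 1L]] <- list(
    name = name, op = op, inputs = inputs,
    params = params, meta = meta, state = state)
  name
}

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
}

g_conv <- function(g, name, input, C_in, C_out, H, W, kh = 3L, kw = 3L) {
  fan_in <- kh * kw * C_in
  g_add(g, name, "conv", input,
        params = list(W = he_init(fan_in, C_out, fan_in), b = numeric(C_out)),
        meta = list(H = H, W = W, kh = kh, kw = kw, C_in = C_in, C_out = C_out))
}

g_bn <- function(g, name, input, C) {
  g_add(g, name, "bn", input,
        params = list(gamma = rep(1, C), beta = numeric(C)),
        meta = list(eps = 1e-5, momentum = 0.1),
        state = list(running_mean = numeric(C), running_var = rep(1, C)))
}

g_cbr <- function(g, name, input, C_in, C_out, H, W) {
  c1 <- g_conv(g, paste0(name, "_conv"), input, C_in, C_out, H, W)
  b1 <- g_bn(g, paste0(name, "_bn"), c1, C_out)
  g_add(g, paste0(name, "_relu"), "relu", b1)
}

g_strip_pool <- function(g, name, input, C, H, W) {
  g_add(g, name, "strip_pool", input,
        params = list(
          Wh = he_init(3L * C, C, 3L * C), bh = numeric(C),
          Wv = he_init(3L * C, C, 3L * C), bv = numeric(C),
          Wf = he_init(C, C, C), bf = numeric(C)),
        meta = list(H = H, W = W, C = C))
}

build_unet_graph <- function(cfg) {
  g <- new_graph()
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  d <- cfg$depth; base <- cfg$base_channels
  enc_out <- character(d)
  cur <- "input"; C_in <- 1L
  for (i in seq_len(d)) {
    C <- base * 2^(i - 1L)
    a <- g_cbr(g, sprintf("enc%d_a", i), cur, C_in, C, H, W)
    b <- g_cbr(g, sprintf("enc%d_b", i), a, C, C, H, W)
    enc_out[i] <- b
    cur <- g_add(g, sprintf("pool%d", i), "pool", b, meta = list(H = H, W = W))
    H <- H %/% 2L; W <- W %/% 2L
    C_in <- C
  }
  Cb <- base * 2^d
  cur <- g_cbr(g, "bott_a", cur, C_in, Cb, H, W)
  cur <- if (cfg$use_strip_pooling) {
    g_strip_pool(g, "bott_sp", cur, Cb, H, W)
  } else {
    g_cbr(g, "bott_b", cur, Cb, Cb, H, W)
  }
  C_in <- Cb
  for (i in rev(seq_len(d))) {
    C <- base * 2^(i - 1L)
    cur <- g_add(g, sprintf("up%d", i), "up", cur, meta = list(H = H, W = W))
    H <- H * 2L; W <- W * 2L
    cur <- g_add(g, sprintf("cat%d", i), "concat", c(cur, enc_out[i]),
                 meta = list(H = H, W = W))
    cur <- g_cbr(g, sprintf("dec%d_a", i), cur, C_in + C, C, H, W)
    cur <- g_cbr(g, sprintf("dec%d_b", i), cur, C, C, H, W)
    C_in <- C
  }
  cur <- g_conv(g, "head", cur, C_in, 1L, H, W, kh = 1L, kw = 1L)
  out <- g_add(g, "prob", "sigmoid", cur)
  list(nodes = g$nodes, out_name = out)
}

g_res_block <- function(g, name, input, C, H, W) {
  a <- g_cbr(g, paste0(name, "_1"), input, C, C, H, W)
  c2 <- g_conv(g, paste0(name, "_2conv"), a, C, C, H, W)
  b2 <- g_bn(g, paste0(name, "_2bn"), c2, C)
  s <- g_add(g, paste0(name, "_add"), "add", c(b2, input))
  g_add(g, paste0(name, "_relu"), "relu", s)
}

build_resnet_graph <- function(cfg) {
  g <- new_graph()
  H <- cfg$input_shape[1]; W <- cfg$input_shape[2]
  d <- cfg$depth; base <- cfg$base_channels
  enc_out <- character(d)
  cur <- g_cbr(g, "stem", "input", 1L, base, H, W)
  C_in <- base
  for (i in seq_len(d)) {
    C <- base * 2^(i - 1L)
    if (C != C_in) cur <- g_cbr(g, sprintf("proj%d", i), cur, C_in, C, H, W)
    for (k in seq_len(cfg$blocks_per_stage)) {
      cur <- g_res_block(g, sprintf("res%d_%d", i, k), cur, C, H, W)
    }
    enc_out[i] <- cur
    cur <- g_add(g, sprintf("pool%d", i), "pool", cur, meta = list(H = H, W = W))
    H <- H %/% 2L; W <- W %/% 2L
    C_in <- C
  }
  Cb <- base * 2^d
  cur <- g_cbr(g, "bott_a", cur, C_in, Cb, H, W)
  cur <- if (cfg$use_strip_pooling) {
    g_strip_pool(g, "bott_sp", cur, Cb, H, W)
  } else {
    g_cbr(g, "bott_b", cur, Cb, Cb, H, W)
  }
  C_in <- Cb
  for (i in rev(seq_len(d))) {
    C <- base * 2^(i - 1L)
    cur <- g_add(g, sprintf("up%d", i), "up", cur, meta = list(H = H, W = W))
    H <- H * 2L; W <- W * 2L
    cur <- g_add(g, sprintf("cat%d", i), "concat", c(cur, enc_out[i]),
                 meta = list(H = H, W = W))
    cur <- g_cbr(g, sprintf("dec%d", i), cur, C_in + C, C, H, W)
    C_in <- C
  }
  cur <- g_conv(g, "head", cur, C_in, 1L, H, W, kh = 1L, kw = 1L)
  out <- g_add(g, "prob", "sigmoid", cur)
  list(nodes = g$nodes, out_name = out)
}

# ---- model utilities --------------------------------------------------------

#' Number of trainable parameters of a model
#' @param model A `seg_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "seg_model"))
  sum(vapply(model$nodes, function(n) {
    if (is.null(n$params)) 0 else sum(vapply(n$params, length, numeric(1)))
  }, numeric(1)))
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model %s/%s, %s input, %s params, strip pooling: %s>\n",
              x$cfg$architecture, x$cfg$preset,
              paste(x$cfg$input_shape, collapse = "x"),
              format(n_parameters(x), big.mark = ","),
              x$cfg$use_strip_pooling))
  invisible(x)
}

#' Predict a choroid probability map for one or more B-scans
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' augmentation). Deterministic for a fixed trained model.
#'
#' @param object A `seg_model`.
#' @param images A [bscan()], an intensity matrix, or a list of either.
#' @param ... Unused.
#' @return A `prob_map` (or list of them): `list(pixels = matrix in [0,1])`.
#' @export
predict.seg_model <- function(object, images, ...) {
  single <- !is.list(images) || inherits(images, "bscan")
  if (single) images <- list(images)
  px <- lapply(images, function(im) if (inherits(im, "bscan")) im$pixels else im)
  shp <- object$cfg$input_shape
  for (p in px) {
    if (!identical(dim(p), shp)) {
      stop("image shape ", paste(dim(p), collapse = "x"),
           " does not match the network input shape ", paste(shp, collapse = "x"))
    }
  }
  B <- length(px)
  x <- matrix(unlist(px, use.names = FALSE), ncol = 1)
  out <- model_forward(object, x, B, training = FALSE)$out
  HW <- shp[1] * shp[2]
  maps <- lapply(seq_len(B), function(b) {
    prob_map(matrix(out[((b - 1) * HW + 1):(b * HW), 1], shp[1], shp[2]))
  })
  if (single) maps[[1]] else maps
}

#' Probability-map container
#' @param pixels Matrix of probabilities in \[0, 1\].
#' @return A `prob_map` object.
#' @export
prob_map <- function(pixels) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("probabilities must lie in [0, 1]")
  }
  structure(list(pixels = pixels), class = "prob_map")
}

#' Late fusion of two probability maps
#'
#' Elementwise arithmetic mean of the two models' prediction scores, the
#' late-fusion ensembling used to combine the U-Net and residual branches.
#'
#' @param p1,p2 `prob_map`s or probability matrices of identical shape.
#' @return A `prob_map`.
#' @examples
#' fuse(prob_map(matrix(0, 2, 2)), prob_map(matrix(1, 2, 2)))$pixels
#' @export
fuse <- function(p1, p2) {
  a <- as_prob_matrix(p1)
  b <- as_prob_matrix(p2)
  check_same_shape(a, b)
  prob_map((a + b) / 2)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file embedding the `network_config`, the
#' initialization seed, all weights and batch-norm running statistics.
#'
#' @param model A `seg_model`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the `seg_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "seg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "seg_model")) stop(path, " is not a seg_model checkpoint")
  model
}
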