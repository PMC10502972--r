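test_that("network outputs are probability maps of the input shape", {
  for (arch in c("unet", "resnet101")) {
    cfg <- network_config(arch, "tiny", base_channels = 4,
                          input_shape = c(16, 24), blocks_per_stage = 1)
    m <- build_network(cfg, init_seed = 3)
    img <- matrix(runif(16 * 24), 16, 24)
    p <- predict(m, img)
    expect_s3_class(p, "prob_map")
    expect_identical(dim(p$pixels), c(16L, 24L))
    expect_true(all(p$pixels >= 0 & p$pixels <= 1))
  }
  expect_error(network_config("unet", "tiny", input_shape = c(30, 96)),
               "divisible")
  cfg <- network_config("unet", "tiny")
  m <- build_network(cfg)
  expect_error(predict(m, matrix(0.5, 32, 96)), "input shape")
})

test_that("a built model is deterministic in inference mode", {
  m1 <- build_network(network_config("unet", "tiny", base_channels = 4,
                                     input_shape = c(16, 16)), init_seed = 7)
  m2 <- build_network(network_config("unet", "tiny", base_channels = 4,
                                     input_shape = c(16, 16)), init_seed = 7)
  img <- matrix(runif(256), 16, 16)
  expect_identical(predict(m1, img)$pixels, predict(m2, img)$pixels)
})

test_that("strip pooling of a constant feature map is constant per channel", {
  ns <- asNamespace("octchoroid")
  C <- 3L; H <- 6L; W <- 8L
  node <- local({
    g <- ns$new_graph()
    set.seed(5)
    ns$g_strip_pool(g, "sp", "input", C, H, W)
    g$nodes[[1]]
  })
  x <- matrix(rep(c(0.3, -1.2, 2.5), each = H * W), H * W, C)
  out <- ns$layer_forward(node, list(x), B = 1L, training = FALSE)$out
  for (ch in seq_len(C)) {
    expect_lt(diff(range(out[, ch])), 1e-12)
  }
})

test_that("tiny preset has far fewer parameters than the full-scale preset", {
  tiny <- build_network(network_config("unet", "tiny"))
  full <- build_network(network_config("unet", "full"))
  expect_lt(n_parameters(tiny), n_parameters(full) / 50)
})

test_that("fuse averages probability maps elementwise", {
  p <- prob_map(matrix(runif(12), 3, 4))
  expect_equal(fuse(p, p)$pixels, p$pixels)
  expect_equal(fuse(prob_map(matrix(0, 2, 2)), prob_map(matrix(1, 2, 2)))$pixels,
               matrix(0.5, 2, 2))
  expect_equal(fuse(matrix(0.2, 3, 3), matrix(0.6, 3, 3))$pixels,
               matrix(0.4, 3, 3))
  q <- prob_map(matrix(runif(12), 3, 4))
  expect_equal(fuse(p, q)$pixels, fuse(q, p)$pixels)
  expect_true(all(fuse(p, q)$pixels >= pmin(p$pixels, q$pixels)))
  expect_true(all(fuse(p, q)$pixels <= pmax(p$pixels, q$pixels)))
  expect_error(fuse(matrix(0.2, 3, 3), matrix(0.6, 2, 3)), "mismatch")
})

test_that("analytic gradients match numerical differentiation", {
  ns <- asNamespace("octchoroid")
  set.seed(9)
  x <- matrix(runif(64), ncol = 1)
  y <- matrix(rbinom(64, 1, 0.5), ncol = 1)
  s <- 1
  loss_fn <- function(mod) {
    p <- ns$model_forward(mod, x, 1, training = TRUE)$out
    1 - (2 * sum(p * y) + s) / (sum(p) + sum(y) + s)
  }
  for (arch in c("unet", "resnet101")) {
    cfg <- network_config(arch, "tiny", base_channels = 4,
                          input_shape = c(8, 8), blocks_per_stage = 1)
    mod <- build_network(cfg, init_seed = 1)
    fwd <- ns$model_forward(mod, x, 1, training = TRUE)
    p <- fwd$out
    den <- sum(p) + sum(y) + s
    dldp <- (2 * sum(p * y) + s) / den^2 - 2 * y / den
    grads <- ns$model_backward(mod, fwd$acts, fwd$caches, dldp, 1)
    # probe a spread of parameters across layer types
    probes <- list(c("bott_sp", "Wh", 5), c("bott_sp", "Wv", 2),
                   c("bott_sp", "Wf", 3), c("head", "W", 1))
    probes <- c(probes, if (arch == "unet") {
      list(c("enc1_a_conv", "W", 3), c("enc1_a_bn", "gamma", 2),
           c("dec1_b_conv", "W", 4))
    } else {
      list(c("stem_conv", "W", 2), c("res1_1_2conv", "W", 5),
           c("dec1_conv", "W", 8))
    })
    eps <- 1e-6
    for (pr in probes) {
      i <- which(vapply(mod$nodes, `[[`, character(1), "name") == pr[1])
      k <- as.integer(pr[3])
      m_plus <- mod; m_plus$nodes[[i]]$params[[pr[2]]][k] <-
        m_plus$nodes[[i]]$params[[pr[2]]][k] + eps
      m_minus <- mod; m_minus$nodes[[i]]$params[[pr[2]]][k] <-
        m_minus$nodes[[i]]$params[[pr[2]]][k] - eps
      num <- (loss_fn(m_plus) - loss_fn(m_minus)) / (2 * eps)
      ana <- grads[[pr[1]]][[pr[2]]][k]
      expect_lt(abs(num - ana) / max(1e-8, abs(num) + abs(ana)), 1e-4)
    }
  }
})

test_that("checkpoints round-trip through disk", {
  m <- build_network(network_config("unet", "tiny", base_channels = 4,
                                    input_shape = c(16, 16)), init_seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  img <- matrix(runif(256), 16, 16)
  expect_identical(predict(m, img)$pixels, predict(m2, img)$pixels)
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(1:3, other)
  expect_error(load_checkpoint(other), "not a seg_model")
})
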