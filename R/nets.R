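# Volumetric segmentation networks, implemented natively as a small static
# computation graph: V-Net (5^3 convolutions, residual stages), 3D U-Net
# (two 3^3 convolutions per level, max pooling) and an attention-gated 3D
# U-Net.  The same graph is walked by the analytic FLOPs counter, so the
# counted cost always describes exactly the network that runs.

#' Segmentation network configuration
#'
#' @param architecture `"vnet"`, `"unet3d"` or `"unet3d_attention"`.
#' @param patch_shape integer length-3 input patch; each component must be
#'   divisible by `2^(depth - 1)`.
#' @param in_channels,num_classes input channels and output classes.
#' @param base_channels channels of the first level (doubling per level).
#' @param depth number of resolution levels.
#' @param vnet_decoder decoder channel schedule for V-Net.  The published
#'   design reads two ways: `"halve"` follows the text ("halve the number of
#'   channels at each up-convolution", stage convolutions keep the
#'   concatenated width) and `"skip"` follows the figure (up-convolution
#'   outputs the skip width, stages run at twice the skip width).
#' @param unet_scheme `"plain"` (constant channels within a level) or
#'   `"double"` (second convolution doubles the channels, as in the original
#'   3D U-Net).
#' @param unet_up `"half"` (up-convolution halves channels) or `"keep"`.
#' @return A validated `nv_netconfig` list.
#' @export
network_config <- function(architecture = c("vnet", "unet3d", "unet3d_attention"),
                           patch_shape = c(112, 144, 64),
                           in_channels = 1, num_classes = 2,
                           base_channels = 16, depth = 5,
                           vnet_decoder = c("halve", "skip"),
                           unet_scheme = c("plain", "double"),
                           unet_up = c("half", "keep")) {
  architecture <- match.arg(architecture)
  vnet_decoder <- match.arg(vnet_decoder)
  unet_scheme <- match.arg(unet_scheme)
  unet_up <- match.arg(unet_up)
  patch_shape <- as.integer(patch_shape)
  if (num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  if (depth < 2) stop("depth must be >= 2", call. = FALSE)
  div <- 2L^(depth - 1L)
  if (any(patch_shape %% div != 0))
    stop(sprintf("patch_shape must be divisible by 2^(depth-1) = %d", div),
         call. = FALSE)
  structure(list(architecture = architecture, patch_shape = patch_shape,
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 base_channels = as.integer(base_channels),
                 depth = as.integer(depth), vnet_decoder = vnet_decoder,
                 unet_scheme = unet_scheme, unet_up = unet_up),
            class = "nv_netconfig")
}

# --- graph construction -----------------------------------------------------

.graph_new <- function() new.env(parent = emptyenv())

.graph_add <- function(g, op, inputs = integer(0), ...) {
  if (is.null(g$nodes)) g$nodes <- list()
  node <- c(list(op = op, inputs = as.integer(inputs)), list(...))
  # output shape inference
  shp <- if (length(inputs) > 0) g$nodes[[inputs[1]]]$shape else NULL
  node$shape <- switch(op,
    input = node$shape0,
    conv = c(shp[1:3], node$cout),
    down2 = c(shp[1:3] %/% 2L, node$cout),
    up2 = c(shp[1:3] * 2L, node$cout),
    maxpool = c(shp[1:3] %/% 2L, shp[4]),
    relu = , sigmoid = , softmax = , add = shp,
    tile = c(shp[1:3], node$times),
    concat = c(shp[1:3], shp[4] + g$nodes[[inputs[2]]]$shape[4]),
    gate_mul = shp,
    stop("unknown op"))
  g$nodes[[length(g$nodes) + 1L]] <- node
  length(g$nodes)
}

.graph_conv_block <- function(g, x, k, cout, act = TRUE) {
  cid <- .graph_add(g, "conv", x, k = as.integer(k),
                    cin = g$nodes[[x]]$shape[4], cout = as.integer(cout))
  if (act) .graph_add(g, "relu", cid) else cid
}

.build_vnet_graph <- function(cfg) {
  g <- .graph_new()
  D <- cfg$depth
  ch <- cfg$base_channels * 2L^(0:(D - 1))
  nconvs <- pmin(c(1L, 2L, 3L, 3L, 3L, 3L, 3L), 3L)[1:D]
  x <- .graph_add(g, "input", shape0 = c(cfg$patch_shape, cfg$in_channels))
  skips <- integer(D)
  cur <- x
  for (i in seq_len(D)) {
    s_in <- cur
    cin <- g$nodes[[s_in]]$shape[4]
    h <- cur
    for (j in seq_len(nconvs[i]))
      h <- .graph_conv_block(g, h, 5L, ch[i], act = j < nconvs[i])
    if (cin == ch[i]) {
      h <- .graph_add(g, "add", c(h, s_in))
    } else if (cin == 1L) {
      tl <- .graph_add(g, "tile", s_in, times = ch[i])
      h <- .graph_add(g, "add", c(h, tl))
    }
    cur <- .graph_add(g, "relu", h)
    skips[i] <- cur
    if (i < D) {
      dn <- .graph_add(g, "down2", cur, cin = ch[i], cout = ch[i + 1])
      cur <- .graph_add(g, "relu", dn)
    }
  }
  for (i in rev(seq_len(D - 1))) {
    cprev <- g$nodes[[cur]]$shape[4]
    # "halve": the up-convolution halves the decoder channels and the stage
    # convolutions run at the published stage width 2*ch[i] (the V-Net
    # figure's 256/128/64/32 schedule); "skip": the up-convolution outputs
    # the skip width, so the stage width equals the concatenation width.
    up_out <- if (cfg$vnet_decoder == "halve") cprev %/% 2L else ch[i]
    up <- .graph_add(g, "up2", cur, cin = cprev, cout = up_out)
    up <- .graph_add(g, "relu", up)
    cat <- .graph_add(g, "concat", c(up, skips[i]))
    width <- 2L * ch[i]
    h <- cat
    for (j in seq_len(nconvs[i]))
      h <- .graph_conv_block(g, h, 5L, width, act = j < nconvs[i])
    # residual add with whichever upstream tensor matches the stage width
    if (g$nodes[[cat]]$shape[4] == width) h <- .graph_add(g, "add", c(h, cat))
    else if (g$nodes[[up]]$shape[4] == width) h <- .graph_add(g, "add", c(h, up))
    cur <- .graph_add(g, "relu", h)
  }
  logits <- .graph_add(g, "conv", cur, k = 1L, cin = g$nodes[[cur]]$shape[4],
                       cout = cfg$num_classes)
  .graph_add(g, "softmax", logits)
  g
}

.build_unet_graph <- function(cfg) {
  g <- .graph_new()
  D <- cfg$depth
  attention <- cfg$architecture == "unet3d_attention"
  f <- cfg$base_channels * 2L^(0:(D - 1))
  x <- .graph_add(g, "input", shape0 = c(cfg$patch_shape, cfg$in_channels))
  cur <- x
  skips <- integer(D)
  chout <- integer(D)
  for (i in seq_len(D)) {
    c2 <- if (cfg$unet_scheme == "double") 2L * f[i] else f[i]
    cur <- .graph_conv_block(g, cur, 3L, f[i])
    cur <- .graph_conv_block(g, cur, 3L, c2)
    chout[i] <- c2
    skips[i] <- cur
    if (i < D) cur <- .graph_add(g, "maxpool", cur)
  }
  for (i in rev(seq_len(D - 1))) {
    cprev <- g$nodes[[cur]]$shape[4]
    up_out <- if (cfg$unet_up == "keep") cprev else chout[i]
    up <- .graph_add(g, "up2", cur, cin = cprev, cout = up_out)
    skip <- skips[i]
    if (attention) {
      ci <- max(1L, chout[i] %/% 2L)
      gq <- .graph_add(g, "conv", up, k = 1L, cin = up_out, cout = ci)
      sq <- .graph_add(g, "conv", skip, k = 1L, cin = chout[i], cout = ci)
      aq <- .graph_add(g, "relu", .graph_add(g, "add", c(gq, sq)))
      psi <- .graph_add(g, "conv", aq, k = 1L, cin = ci, cout = 1L)
      att <- .graph_add(g, "sigmoid", psi)
      skip <- .graph_add(g, "gate_mul", c(skip, att))
    }
    cat <- .graph_add(g, "concat", c(up, skip))
    cur <- .graph_conv_block(g, cat, 3L, chout[i])
    cur <- .graph_conv_block(g, cur, 3L, chout[i])
  }
  logits <- .graph_add(g, "conv", cur, k = 1L, cin = g$nodes[[cur]]$shape[4],
                       cout = cfg$num_classes)
  .graph_add(g, "softmax", logits)
  g
}

.build_graph <- function(cfg) {
  if (cfg$architecture == "vnet") .build_vnet_graph(cfg) else .build_unet_graph(cfg)
}

# --- model construction -----------------------------------------------------

#' Build a segmentation model
#'
#' Parameters are He-initialized from the given seed; two builds with the
#' same configuration and seed are bit-identical.
#'
#' @param cfg a [network_config].
#' @param seed integer RNG seed for initialization.
#' @return An `nv_model` (graph + parameter arrays).
#' @export
build_model <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "nv_netconfig"))
  g <- .build_graph(cfg)
  params <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (id in seq_along(g$nodes)) {
    nd <- g$nodes[[id]]
    if (nd$op %in% c("conv", "down2", "up2")) {
      k <- if (nd$op == "conv") nd$k else 2L
      fan_in <- k^3 * nd$cin
      w <- array(stats::rnorm(k^3 * nd$cin * nd$cout, sd = sqrt(2 / fan_in)),
                 c(k, k, k, nd$cin, nd$cout))
      params[[sprintf("n%03d_w", id)]] <- w
      params[[sprintf("n%03d_b", id)]] <- numeric(nd$cout)
      g$nodes[[id]]$pw <- sprintf("n%03d_w", id)
      g$nodes[[id]]$pb <- sprintf("n%03d_b", id)
    }
  }
  structure(list(cfg = cfg, nodes = g$nodes, params = params),
            class = "nv_model")
}

#' @export
print.nv_model <- function(x, ...) {
  cat(sprintf("<nv_model %s> depth %d, base %d, patch %s; %s parameters, %.2f GFLOPs/pass\n",
              x$cfg$architecture, x$cfg$depth, x$cfg$base_channels,
              paste(x$cfg$patch_shape, collapse = "x"),
              format(count_params(x$cfg), big.mark = ","),
              count_flops(x$cfg)))
  invisible(x)
}

# --- forward / backward -----------------------------------------------------

.tile4 <- function(a, times) {
  d <- dim(a)
  array(rep(as.vector(a), times), c(d[1:3], times))
}

#' Forward pass of a segmentation model
#'
#' @param model an `nv_model`.
#' @param x input array `(X, Y, Z)` or `(X, Y, Z, C)` matching the model's
#'   patch shape.
#' @param keep_cache retain intermediate activations (needed for backward).
#' @return list with `probs` (X,Y,Z,classes), `logits`, and optionally `cache`.
#' @export
model_forward <- function(model, x, keep_cache = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  # fully convolutional: any shape divisible by the pooling factor works
  div <- 2L^(model$cfg$depth - 1L)
  if (any(dim(x)[1:3] %% div != 0) || dim(x)[4] != model$cfg$in_channels)
    stop(sprintf("input shape %s not divisible by %d (or channel mismatch)",
                 paste(dim(x)[1:3], collapse = "x"), div), call. = FALSE)
  nodes <- model$nodes; P <- model$params
  outs <- vector("list", length(nodes))
  extra <- vector("list", length(nodes))
  for (id in seq_along(nodes)) {
    nd <- nodes[[id]]
    inp <- lapply(nd$inputs, function(i) outs[[i]])
    outs[[id]] <- switch(nd$op,
      input = x,
      conv = cpp_conv3d_same(inp[[1]], P[[nd$pw]], P[[nd$pb]]),
      down2 = cpp_conv3d_down2(inp[[1]], P[[nd$pw]], P[[nd$pb]]),
      up2 = cpp_conv3d_up2(inp[[1]], P[[nd$pw]], P[[nd$pb]]),
      maxpool = { r <- cpp_maxpool2(inp[[1]]); extra[[id]] <- r$idx; r$y },
      relu = { a <- inp[[1]]; a[a < 0] <- 0; a },
      sigmoid = 1 / (1 + exp(-inp[[1]])),
      add = inp[[1]] + inp[[2]],
      tile = .tile4(inp[[1]], nd$times),
      concat = { d <- dim(inp[[1]]); array(c(inp[[1]], inp[[2]]),
                 c(d[1:3], d[4] + dim(inp[[2]])[4])) },
      gate_mul = inp[[1]] * .tile4(inp[[2]], dim(inp[[1]])[4]),
      softmax = { a <- inp[[1]]
        C <- dim(a)[4]
        mx <- a[, , , 1]
        if (C > 1) for (c in 2:C) mx <- pmax(mx, a[, , , c])
        e <- exp(a - as.vector(mx))
        s <- array(0, dim(a)[1:3])
        for (c in seq_len(C)) s <- s + e[, , , c]
        e / as.vector(s) })
  }
  nlog <- nodes[[length(nodes)]]$inputs[1]
  res <- list(probs = outs[[length(nodes)]], logits = outs[[nlog]])
  if (keep_cache) res$cache <- list(outs = outs, extra = extra)
  res
}

# flip kernel spatially and swap channel dims: used for grad-input of conv
.flip_w <- function(w) {
  k <- dim(w)[1]
  aperm(w[k:1, k:1, k:1, , , drop = FALSE], c(1, 2, 3, 5, 4))
}

# backward pass from d(loss)/d(logits); returns gradients for every param
model_backward <- function(model, cache, dlogits) {
  nodes <- model$nodes; P <- model$params
  outs <- cache$outs; extra <- cache$extra
  douts <- vector("list", length(nodes))
  grads <- list()
  nlog <- nodes[[length(nodes)]]$inputs[1]
  douts[[nlog]] <- dlogits
  acc <- function(i, g) {
    if (is.null(douts[[i]])) douts[[i]] <<- g else douts[[i]] <<- douts[[i]] + g
  }
  for (id in rev(seq_len(length(nodes) - 1L))) {  # softmax handled by caller
    nd <- nodes[[id]]
    dy <- douts[[id]]
    if (is.null(dy) || nd$op == "input") next
    ins <- nd$inputs
    switch(nd$op,
      conv = {
        x <- outs[[ins[1]]]
        grads[[nd$pw]] <- cpp_conv3d_same_gradw(x, dy, nd$k)
        grads[[nd$pb]] <- colSums(matrix(dy, ncol = dim(dy)[4]))
        zb <- numeric(dim(x)[4])
        acc(ins[1], cpp_conv3d_same(dy, .flip_w(P[[nd$pw]]), zb))
      },
      down2 = {
        r <- cpp_conv3d_down2_bwd(outs[[ins[1]]], P[[nd$pw]], dy)
        grads[[nd$pw]] <- r$dw; grads[[nd$pb]] <- r$db
        acc(ins[1], r$dx)
      },
      up2 = {
        r <- cpp_conv3d_up2_bwd(outs[[ins[1]]], P[[nd$pw]], dy)
        grads[[nd$pw]] <- r$dw; grads[[nd$pb]] <- r$db
        acc(ins[1], r$dx)
      },
      maxpool = acc(ins[1], cpp_maxpool2_bwd(dy, extra[[id]],
                                             dim(outs[[ins[1]]]))),
      relu = { x <- outs[[ins[1]]]; dy[x <= 0] <- 0; acc(ins[1], dy) },
      sigmoid = { s <- outs[[id]]; acc(ins[1], dy * s * (1 - s)) },
      add = { acc(ins[1], dy); acc(ins[2], dy) },
      tile = {
        d <- dim(dy)
        acc(ins[1], array(rowSums(matrix(dy, prod(d[1:3]), d[4])),
                          c(d[1:3], 1L)))
      },
      concat = {
        c1 <- dim(outs[[ins[1]]])[4]
        acc(ins[1], dy[, , , seq_len(c1), drop = FALSE])
        acc(ins[2], dy[, , , -seq_len(c1), drop = FALSE])
      },
      gate_mul = {
        xg <- outs[[ins[1]]]; a <- outs[[ins[2]]]
        C <- dim(xg)[4]
        acc(ins[1], dy * .tile4(a, C))
        da <- dy * xg
        d <- dim(da)
        acc(ins[2], array(rowSums(matrix(da, prod(d[1:3]), C)),
                          c(d[1:3], 1L)))
      })
  }
  grads
}

#' Segment a whole volume with a trained model
#'
#' Returns the probability of the foreground (last) class.  Volumes matching
#' the model's training patch are segmented in one pass; larger volumes are
#' segmented by a sliding window of training-patch-sized tiles (stride =
#' half a patch) whose probabilities are averaged in the overlaps, so the
#' network always sees the field of view it was trained on.
#'
#' @param model an `nv_model`.
#' @param v an [nv_volume] (or plain 3D array).
#' @return 3D array of foreground probabilities.
#' @export
predict_volume <- function(model, v) {
  x <- if (inherits(v, "nv_volume")) v$data else v
  patch <- as.integer(model$cfg$patch_shape)
  d <- dim(x)[1:3]
  one_pass <- function(xx) {
    r <- model_forward(model, xx)
    r$probs[, , , dim(r$probs)[4]]
  }
  if (all(d == patch)) return(one_pass(x))
  if (any(d < patch))
    stop(sprintf("volume %s smaller than the model patch %s",
                 paste(d, collapse = "x"), paste(patch, collapse = "x")),
         call. = FALSE)
  starts <- function(n, p) {
    s <- unique(c(seq(1L, n - p + 1L, by = max(1L, p %/% 2L)), n - p + 1L))
    s
  }
  acc <- array(0, d); wt <- array(0, d)
  for (sx in starts(d[1], patch[1]))
    for (sy in starts(d[2], patch[2]))
      for (sz in starts(d[3], patch[3])) {
        ix <- sx:(sx + patch[1] - 1L)
        iy <- sy:(sy + patch[2] - 1L)
        iz <- sz:(sz + patch[3] - 1L)
        acc[ix, iy, iz] <- acc[ix, iy, iz] + one_pass(x[ix, iy, iz])
        wt[ix, iy, iz] <- wt[ix, iy, iz] + 1
      }
  acc / wt
}

#' Save / load a model checkpoint
#'
#' Checkpoints use R's native serialization.
#'
#' @param model an `nv_model`.
#' @param path file path (`.rds`).
#' @return `path` / the loaded model.
#' @export
save_model <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

# --- analytic cost ----------------------------------------------------------

#' Analytic forward-pass cost in GFLOPs
#'
#' Walks the model graph and sums the floating-point operations of one
#' forward pass at the configured patch shape.  One multiply-accumulate
#' counts as two FLOPs (the most common convention); convolution bias adds,
#' activations, residual adds, attention gating and the softmax are counted
#' as elementwise operations; max-pooling is counted as its comparisons.
#'
#' Transposed convolutions are counted by the profiler convention
#' (`kernel volume x input channels x output channels x output elements`,
#' as the widely used network profilers report them), which makes the
#' counts comparable with published compute figures.  For a non-overlapping
#' stride-2 kernel-2 up-convolution the true dataflow is 8x cheaper; set
#' `transposed = "dataflow"` for that count.
#'
#' @param cfg a [network_config] (or an `nv_model`, whose config is used).
#' @param transposed `"profiler"` (default) or `"dataflow"` counting for
#'   transposed convolutions.
#' @return GFLOPs as a numeric scalar.
#' @export
count_flops <- function(cfg, transposed = c("profiler", "dataflow")) {
  if (inherits(cfg, "nv_model")) cfg <- cfg$cfg
  stopifnot(inherits(cfg, "nv_netconfig"))
  transposed <- match.arg(transposed)
  g <- .build_graph(cfg)
  fl <- 0
  for (nd in g$nodes) {
    n_out <- prod(as.numeric(nd$shape[1:3]))
    c_out <- as.numeric(nd$shape[4])
    fl <- fl + switch(nd$op,
      input = 0,
      conv = n_out * (2 * nd$k^3 * nd$cin * c_out + c_out),
      down2 = n_out * (2 * 8 * nd$cin * c_out + c_out),
      up2 = if (transposed == "profiler")
        n_out * (2 * 8 * nd$cin * c_out + c_out)
      else (n_out / 8) * 2 * 8 * nd$cin * c_out + n_out * c_out,
      maxpool = 7 * n_out * c_out,
      relu = , add = , gate_mul = n_out * c_out,
      sigmoid = 4 * n_out * c_out,
      tile = , concat = 0,
      softmax = 3 * n_out * c_out)
  }
  fl / 1e9
}

#' Number of trainable parameters
#'
#' @param cfg a [network_config] or `nv_model`.
#' @return integer-valued numeric.
#' @export
count_params <- function(cfg) {
  if (inherits(cfg, "nv_model")) cfg <- cfg$cfg
  g <- .build_graph(cfg)
  p <- 0
  for (nd in g$nodes)
    if (nd$op %in% c("conv", "down2", "up2")) {
      k <- if (nd$op == "conv") nd$k else 2L
      p <- p + k^3 * nd$cin * nd$cout + nd$cout
    }
  p
}

#' Standard configuration grid with analytic costs
#'
#' Enumerates the standard width/depth/decoder variants of an architecture
#' at a given patch shape and tabulates their analytic forward-pass cost.
#' This is the documented search space used to identify which published
#' configuration a reported compute figure corresponds to.
#'
#' @param architecture `"vnet"` or `"unet3d"`.
#' @param patch_shape integer length-3.
#' @param num_classes classes of the head.
#' @return A tibble with the configuration fields and `gflops`.
#' @export
flops_grid <- function(architecture = c("vnet", "unet3d"),
                       patch_shape = c(112, 144, 64), num_classes = 2) {
  architecture <- match.arg(architecture)
  rows <- list()
  if (architecture == "vnet") {
    for (base in c(8L, 16L, 32L)) for (depth in 4:5)
      for (dec in c("halve", "skip")) {
        cfg <- network_config("vnet", patch_shape, num_classes = num_classes,
                              base_channels = base, depth = depth,
                              vnet_decoder = dec)
        rows[[length(rows) + 1]] <- tibble::tibble(
          architecture = "vnet", base_channels = base, depth = depth,
          variant = dec, gflops = count_flops(cfg))
      }
  } else {
    for (base in c(16L, 32L, 64L)) for (depth in 4:5)
      for (sch in c("plain", "double")) for (up in c("half", "keep")) {
        cfg <- network_config("unet3d", patch_shape, num_classes = num_classes,
                              base_channels = base, depth = depth,
                              unet_scheme = sch, unet_up = up)
        rows[[length(rows) + 1]] <- tibble::tibble(
          architecture = "unet3d", base_channels = base, depth = depth,
          variant = paste(sch, up, sep = "/"), gflops = count_flops(cfg))
      }
  }
  do.call(rbind, rows)
}
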