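# --- Minimal CNN graph executor -------------------------------------------
#
# Feature maps are (H, W, C) arrays. An architecture is a list of layers;
# each layer reads one or more earlier outputs by absolute index
# (`from = 0` means the previous layer). Convolutions optionally carry a
# batch-norm affine (identity under random initialization) and an
# activation in {"linear", "relu", "leaky"}.

cl_conv <- function(filters, size, stride = 1, pad = size %/% 2,
                    activation = "leaky", batch_normalize = TRUE,
                    bias = !batch_normalize, from = 0L) {
  list(type = "conv", filters = filters, size = size, stride = stride,
       pad = pad, activation = activation,
       batch_normalize = batch_normalize, bias = bias, from = from)
}
cl_maxpool <- function(size, stride, pad = 0L, from = 0L) {
  list(type = "maxpool", size = size, stride = stride, pad = pad,
       from = from)
}
cl_avgpool <- function(size, stride, pad = 0L, from = 0L) {
  list(type = "avgpool", size = size, stride = stride, pad = pad,
       from = from)
}
cl_adaptive_avgpool <- function(out_h, out_w, from = 0L) {
  list(type = "adaptive_avgpool", out_h = out_h, out_w = out_w, from = from)
}
cl_upsample <- function(stride = 2L, from = 0L) {
  list(type = "upsample", stride = stride, from = from)
}
cl_shortcut <- function(with, from = 0L) {
  list(type = "shortcut", with = with, from = from)
}
cl_route <- function(layers) list(type = "route", layers = layers)
cl_relu <- function(from = 0L) list(type = "relu", from = from)
cl_identity <- function(from = 0L) list(type = "identity", from = from)

apply_activation <- function(x, activation) {
  switch(activation,
         linear = x,
         relu = pmax(x, 0),
         leaky = pmax(x, 0.1 * x),
         stop_radguide("unknown activation: ", activation))
}

# architecture builder: `add()` appends a layer and returns its index
arch_builder <- function() {
  layers <- list()
  add <- function(layer) {
    layers[[length(layers) + 1L]] <<- layer
    length(layers)
  }
  list(add = add, layers = function() layers)
}

resolve_from <- function(from, i) if (from == 0L) i - 1L else as.integer(from)

# shape propagation without weights; input_shape = c(H, W, C)
cnn_shapes <- function(arch, input_shape) {
  shp <- vector("list", length(arch))
  get <- function(i, j) if (j == 0L) input_shape else shp[[j]]
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    s <- if (l$type == "route") NULL else get(i, resolve_from(l$from, i))
    shp[[i]] <- switch(l$type,
      conv = {
        h <- (s[1] + 2 * l$pad - l$size) %/% l$stride + 1L
        w <- (s[2] + 2 * l$pad - l$size) %/% l$stride + 1L
        c(h, w, l$filters)
      },
      maxpool = ,
      avgpool = c((s[1] + 2 * l$pad - l$size) %/% l$stride + 1L,
                  (s[2] + 2 * l$pad - l$size) %/% l$stride + 1L, s[3]),
      adaptive_avgpool = c(l$out_h, l$out_w, s[3]),
      upsample = c(s[1] * l$stride, s[2] * l$stride, s[3]),
      shortcut = s,
      relu = s,
      identity = s,
      route = {
        parts <- lapply(l$layers, function(j) shp[[j]])
        c(parts[[1]][1], parts[[1]][2],
          sum(vapply(parts, function(p) p[3], 1)))
      },
      stop_radguide("unknown layer type: ", l$type))
    if (any(shp[[i]][1:2] < 1)) {
      stop_radguide("input too small: layer ", i, " (", l$type,
                    ") would have empty spatial extent")
    }
  }
  shp
}

# Random weight initialization, deterministic under `seed`.
# style "he": plain He-normal draws.
# style "scatter": He draws with the first convolution mean-centered per
# filter (random band-pass analysis) and deeper convolutions made
# nonnegative (energy pooling). A rectified band-pass cascade of random
# filters is sensitive to texture amplitude and scale the way pretrained
# early layers are, without shipping any weights.
cnn_init_weights <- function(arch, input_shape, seed, style = "he") {
  shapes <- cnn_shapes(arch, input_shape)
  cin_of <- function(i, l) {
    if (l$type == "route") {
      sum(vapply(l$layers, function(j) shapes[[j]][3], 1))
    } else {
      j <- resolve_from(l$from, i)
      if (j == 0L) input_shape[3] else shapes[[j]][3]
    }
  }
  first_conv <- which(vapply(arch, function(l) l$type == "conv",
                             logical(1)))[1]
  with_seed(seed, lapply(seq_along(arch), function(i) {
    l <- arch[[i]]
    if (l$type != "conv") return(NULL)
    cin <- cin_of(i, l)
    fan_in <- l$size^2 * cin
    w <- matrix(rnorm(fan_in * l$filters, sd = sqrt(2 / fan_in)),
                nrow = fan_in)
    if (style == "scatter") {
      w <- if (i == first_conv) sweep(w, 2, colMeans(w)) else abs(w)
    }
    list(w = w,
         b = if (l$bias) numeric(l$filters) else NULL,
         bn = if (l$batch_normalize) {
           list(gamma = rep(1, l$filters), beta = numeric(l$filters),
                mean = numeric(l$filters), var = rep(1, l$filters))
         })
  }))
}

cnn_forward <- function(arch, weights, input) {
  stopifnot(length(dim(input)) == 3)
  outs <- vector("list", length(arch))
  get <- function(i, j) if (j == 0L) input else outs[[j]]
  for (i in seq_along(arch)) {
    l <- arch[[i]]
    x <- if (l$type == "route") NULL else get(i, resolve_from(l$from, i))
    outs[[i]] <- switch(l$type,
      conv = {
        d <- dim(x)
        cols <- cpp_im2col(x, d[1], d[2], d[3], l$size, l$stride, l$pad)
        y <- cols %*% weights[[i]]$w
        if (!is.null(weights[[i]]$b)) {
          y <- sweep(y, 2, weights[[i]]$b, `+`)
        }
        if (!is.null(weights[[i]]$bn)) {
          bn <- weights[[i]]$bn
          y <- sweep(y, 2, bn$mean, `-`)
          y <- sweep(y, 2, bn$gamma / sqrt(bn$var + 1e-5), `*`)
          y <- sweep(y, 2, bn$beta, `+`)
        }
        h <- (d[1] + 2 * l$pad - l$size) %/% l$stride + 1L
        w <- (d[2] + 2 * l$pad - l$size) %/% l$stride + 1L
        apply_activation(array(y, dim = c(h, w, l$filters)), l$activation)
      },
      maxpool = cpp_maxpool(x, dim(x)[1], dim(x)[2], dim(x)[3],
                            l$size, l$stride, l$pad),
      avgpool = cpp_avgpool(x, dim(x)[1], dim(x)[2], dim(x)[3],
                            l$size, l$stride, l$pad),
      adaptive_avgpool = cpp_adaptive_avgpool(
        x, dim(x)[1], dim(x)[2], dim(x)[3], l$out_h, l$out_w),
      upsample = {
        s <- l$stride
        x[rep(seq_len(dim(x)[1]), each = s),
          rep(seq_len(dim(x)[2]), each = s), , drop = FALSE]
      },
      shortcut = x + outs[[l$with]],
      relu = pmax(x, 0),
      identity = x,
      route = {
        parts <- lapply(l$layers, function(j) outs[[j]])
        hw <- dim(parts[[1]])[1:2]
        array(unlist(parts, use.names = FALSE),
              dim = c(hw, sum(vapply(parts, function(p) dim(p)[3], 1))))
      })
  }
  outs[[length(arch)]]
}

# --- Backbone architectures ------------------------------------------------

# The full detection backbone graph (53-layer feature extractor, three-
# scale head with routes and nearest upsampling) truncated at the last
# 255-channel 1x1 convolution at the finest (1/8) scale -- the layer whose
# flattened activations serve as the deep features. Detection decoding is
# not part of the graph.
yolo_v3_l107_arch <- function() {
  b <- arch_builder()
  conv <- function(f, k, s = 1, act = "leaky", bn = TRUE, from = 0L) {
    b$add(cl_conv(f, k, s, activation = act, batch_normalize = bn,
                  from = from))
  }
  res <- function(f_half, f) { # 1x1 squeeze, 3x3 expand, additive shortcut
    inp <- length(b$layers())
    conv(f_half, 1)
    conv(f, 3)
    b$add(cl_shortcut(with = inp))
  }
  conv(32, 3)
  conv(64, 3, 2); res(32, 64)
  conv(128, 3, 2); for (i in 1:2) res(64, 128)
  conv(256, 3, 2); for (i in 1:8) res(128, 256)
  tap_8x <- length(b$layers()) # 1/8-scale backbone tap
  conv(512, 3, 2); for (i in 1:8) res(256, 512)
  tap_16x <- length(b$layers()) # 1/16-scale backbone tap
  conv(1024, 3, 2); for (i in 1:4) res(512, 1024)

  # coarse-scale head
  conv(512, 1); conv(1024, 3); conv(512, 1); conv(1024, 3)
  pre1 <- conv(512, 1)
  conv(1024, 3)
  conv(255, 1, act = "linear", bn = FALSE)

  # middle scale
  conv(256, 1, from = pre1)
  b$add(cl_upsample(2))
  b$add(cl_route(c(length(b$layers()), tap_16x)))
  conv(256, 1); conv(512, 3); conv(256, 1); conv(512, 3)
  pre2 <- conv(256, 1)
  conv(512, 3)
  conv(255, 1, act = "linear", bn = FALSE)

  # fine (1/8) scale; its 255-channel output is the feature layer
  conv(128, 1, from = pre2)
  b$add(cl_upsample(2))
  b$add(cl_route(c(length(b$layers()), tap_8x)))
  conv(128, 1); conv(256, 3); conv(128, 1); conv(256, 3); conv(128, 1)
  conv(256, 3)
  conv(255, 1, act = "linear", bn = FALSE)
  b$layers()
}

vgg19_features_arch <- function() {
  b <- arch_builder()
  conv <- function(f) {
    b$add(cl_conv(f, 3, 1, activation = "relu", batch_normalize = FALSE,
                  bias = TRUE))
  }
  pool <- function() b$add(cl_maxpool(2, 2))
  for (f in c(64, 64)) conv(f); pool()
  for (f in c(128, 128)) conv(f); pool()
  for (f in rep(256, 4)) conv(f); pool()
  for (f in rep(512, 4)) conv(f); pool()
  for (f in rep(512, 4)) conv(f); pool()
  b$add(cl_adaptive_avgpool(7, 7)) # fixed 512 x 7 x 7 feature tensor
  b$layers()
}

densenet201_features_arch <- function() {
  b <- arch_builder()
  growth <- 32
  conv <- function(f, k, s = 1, pad = k %/% 2, from = 0L) {
    b$add(cl_conv(f, k, s, pad, activation = "linear",
                  batch_normalize = TRUE, from = from))
  }
  conv(64, 7, 2, 3)
  b$add(cl_relu())
  b$add(cl_maxpool(3, 2, pad = 1))
  acc <- length(b$layers())
  ch <- 64
  for (block in c(6, 12, 48, 32)) {
    for (j in seq_len(block)) { # pre-activation bottleneck, concatenated
      b$add(cl_relu(from = acc))
      conv(4 * growth, 1)
      b$add(cl_relu())
      new <- conv(growth, 3)
      acc <- b$add(cl_route(c(acc, new)))
      ch <- ch + growth
    }
    if (block != 32) { # transition halves channels and resolution
      b$add(cl_relu(from = acc))
      ch <- ch %/% 2
      conv(ch, 1)
      acc <- b$add(cl_avgpool(2, 2))
    }
  }
  b$add(cl_relu(from = acc))
  b$layers()
}

random_cnn_test_arch <- function() {
  b <- arch_builder()
  for (f in c(16, 32, 32, 32)) { # bias-free ReLU stride-2 stack
    b$add(cl_conv(f, 3, 2, activation = "relu", batch_normalize = FALSE,
                  bias = FALSE))
  }
  b$layers()
}

backend_registry <- function() {
  list(
    yolo_v3_l107 = list(arch = yolo_v3_l107_arch, prefix = "Yolo",
                        default_input = 128L),
    densenet201_features = list(arch = densenet201_features_arch,
                                prefix = "DenseNet", default_input = 256L),
    vgg19_features = list(arch = vgg19_features_arch, prefix = "VGG",
                          default_input = 256L),
    random_cnn_test = list(arch = random_cnn_test_arch, prefix = "TestCNN",
                           default_input = 128L, init = "scatter"))
}

#' Frozen CNN feature-extractor specification
#'
#' Registered backends: `yolo_v3_l107` (the 255-channel 1/8-scale output of
#' the detection backbone, 65,280 features for a 128x128x3 input),
#' `densenet201_features` and `vgg19_features` (the convolutional feature
#' tensors with the classifier stages removed; VGG keeps its fixed 7x7
#' adaptive pooling so its dimension is 25,088 regardless of input size),
#' and `random_cnn_test`, a small seeded stride-2 stack for fast tests
#' whose random initialization is scattering-style: mean-centered
#' (band-pass) first-layer filters followed by nonnegative energy-pooling
#' layers, giving it texture sensitivity comparable to pretrained stacks.
#'
#' Weights are never bundled: `weights = "random"` draws a deterministic
#' He-normal initialization from `seed`; alternatively an `.rds` path to a
#' weight list previously produced by [build_extractor()] may be given.
#'
#' @param backend Backend name.
#' @param input_size In-plane input size in pixels (default per backend).
#' @param weights `"random"` or a path to an `.rds` weight list.
#' @param seed Seed for random weights.
#' @return An `extractor_spec` list.
#' @export
extractor_spec <- function(backend = c("yolo_v3_l107",
                                       "densenet201_features",
                                       "vgg19_features",
                                       "random_cnn_test"),
                           input_size = NULL, weights = "random",
                           seed = 1L) {
  backend <- match.arg(backend)
  reg <- backend_registry()[[backend]]
  structure(list(backend = backend,
                 input_size = as.integer(input_size %||% reg$default_input),
                 weights = weights, seed = as.integer(seed)),
            class = "extractor_spec")
}

#' Build a frozen feature extractor (architecture + weights)
#'
#' @param spec An [extractor_spec()].
#' @return List with `spec`, `arch` and `weights`, reusable across patches.
#' @export
build_extractor <- function(spec) {
  stopifnot(inherits(spec, "extractor_spec"))
  reg <- backend_registry()[[spec$backend]]
  arch <- reg$arch()
  input_shape <- c(spec$input_size, spec$input_size, 3L)
  w <- spec$weights
  if (identical(w, "random")) {
    weights <- cnn_init_weights(arch, input_shape,
                                derive_seed(spec$seed, "weights"),
                                style = reg$init %||% "he")
  } else if (is.character(w)) {
    if (!file.exists(w)) {
      stop_radguide("weight file not found: ", w, ". Provide an .rds ",
                    "weight list saved from build_extractor()$weights, ",
                    "or use weights = \"random\"; weights are never ",
                    "downloaded automatically.")
    }
    weights <- readRDS(w)
    if (length(weights) != length(arch)) {
      stop_radguide("weight list does not match the ", spec$backend,
                    " architecture")
    }
  } else if (is.list(w)) {
    weights <- w
  } else {
    stop_radguide("weights must be \"random\", a file path, or a list")
  }
  list(spec = spec, arch = arch, weights = weights,
       prefix = reg$prefix, input_shape = input_shape)
}

#' Architecture-determined flattened feature dimension
#'
#' Computes the length of the flattened feature vector from the layer
#' graph alone, without instantiating weights.
#'
#' @param spec An [extractor_spec()].
#' @param input_size Optional override of the in-plane input size.
#' @return Integer feature count.
#' @export
#' @examples
#' output_dim(extractor_spec("yolo_v3_l107"), 128) # 65280
output_dim <- function(spec, input_size = spec$input_size) {
  stopifnot(inherits(spec, "extractor_spec"))
  arch <- backend_registry()[[spec$backend]]$arch()
  shp <- cnn_shapes(arch, c(as.integer(input_size), as.integer(input_size),
                            3L))
  prod(shp[[length(shp)]])
}

#' Extract flattened frozen-CNN features from a patch
#'
#' Runs the patch through the frozen backbone and flattens the designated
#' feature tensor column-major (row index fastest, then column, then
#' channel). Features are named `<prefix>_Latent_<index>`.
#'
#' @param patch `H x W x 3` numeric array (see [extract_patch()] /
#'   [resize_patch()]); `H`, `W` must equal the spec's `input_size`.
#' @param spec An [extractor_spec()], or a prebuilt [build_extractor()]
#'   object (preferred when extracting many patches).
#' @return Named numeric feature vector.
#' @export
extract_dl_features <- function(patch, spec) {
  ext <- if (inherits(spec, "extractor_spec")) build_extractor(spec)
         else spec
  d <- dim(patch)
  if (length(d) != 3 || d[3] != 3) stop_radguide("patch must be H x W x 3")
  if (d[1] != ext$input_shape[1] || d[2] != ext$input_shape[2]) {
    stop_radguide("patch is ", d[1], "x", d[2], " but backend ",
                  ext$spec$backend, " expects ", ext$input_shape[1], "x",
                  ext$input_shape[2], "; use resize_patch()")
  }
  out <- cnn_forward(ext$arch, ext$weights, patch)
  v <- as.numeric(out)
  names(v) <- paste0(ext$prefix, "_Latent_", seq_along(v))
  v
}

#' Extract a deep-feature table for a cohort of patches
#'
#' @param patches List of `H x W x 3` arrays.
#' @param spec An [extractor_spec()].
#' @param patient_id Character vector of ids.
#' @return Tibble: `patient_id` plus one column per flattened feature.
#' @export
extract_dl_table <- function(patches, spec,
                             patient_id = sprintf("P%04d",
                                                  seq_along(patches))) {
  ext <- build_extractor(spec)
  rows <- vapply(patches, extract_dl_features, spec = ext,
                 numeric(output_dim(spec)))
  out <- tibble::as_tibble(t(rows))
  tibble::add_column(out, patient_id = patient_id, .before = 1)
}
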