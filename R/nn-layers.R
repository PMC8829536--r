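# Minimal CNN layer stack used by the DCT network encoders.
#
# Modules are plain nested lists (type, params, children, hyperparameters);
# activations are numeric arrays in channel-last layout (H x W x C). Having
# no closures in the module tree keeps checkpoints serializable and
# parameter counting a straight recursive walk.
#
# Batch normalization layers carry their trainable affine pair (gamma, beta)
# and their running statistics; networks here are randomly initialized and
# used in inference mode, so forward evaluation applies the affine map with
# the initial statistics (mean 0, var 1).

he_init <- function(n, fan_in) {
  stats::rnorm(n, sd = sqrt(2 / fan_in))
}

mk_conv <- function(cin, cout, k, stride = 1, pad = (k - 1) %/% 2,
                    groups = 1, bias = FALSE) {
  abort_if(cin %% groups != 0 || cout %% groups != 0,
           "conv groups must divide channel counts")
  cin_g <- cin %/% groups
  w <- array(he_init(k * k * cin_g * cout, k * k * cin_g),
             dim = c(k * k * cin_g, cout))
  params <- list(weight = w)
  if (bias) params$bias <- numeric(cout)
  list(type = "conv", params = params, cin = cin, cout = cout, k = k,
       stride = stride, pad = pad, groups = groups)
}

mk_bn <- function(ch) {
  list(type = "bn", params = list(gamma = rep(1, ch), beta = numeric(ch)))
}

mk_linear <- function(cin, cout, w_sd = 0.01) {
  list(type = "linear",
       params = list(weight = array(stats::rnorm(cin * cout, sd = w_sd),
                                    dim = c(cin, cout)),
                     bias = numeric(cout)))
}

mk_act <- function(kind) list(type = "act", params = list(), kind = kind)

mk_maxpool <- function(k = 3, stride = 2, pad = 1) {
  list(type = "maxpool", params = list(), k = k, stride = stride, pad = pad)
}

mk_seq <- function(...) {
  children <- list(...)
  if (length(children) == 1L && is.null(children[[1]]$type)) {
    children <- children[[1]]
  }
  list(type = "seq", params = list(), children = children)
}

# conv + batchnorm + optional activation, the standard block unit
mk_convbn <- function(cin, cout, k, stride = 1, pad = (k - 1) %/% 2,
                      groups = 1, act = "relu") {
  mods <- list(mk_conv(cin, cout, k, stride, pad, groups),
               mk_bn(cout))
  if (act != "none") mods <- c(mods, list(mk_act(act)))
  mk_seq(mods)
}

mk_basic_block <- function(cin, cout, stride) {
  down <- if (stride != 1 || cin != cout) {
    mk_convbn(cin, cout, 1, stride, pad = 0, act = "none")
  }
  list(type = "basic_block", params = list(),
       children = list(conv1 = mk_convbn(cin, cout, 3, stride),
                       conv2 = mk_convbn(cout, cout, 3, 1, act = "none"),
                       down = down))
}

mk_inverted_residual <- function(cin, cout, stride, expand) {
  hidden <- cin * expand
  children <- list()
  if (expand != 1) {
    children$expand <- mk_convbn(cin, hidden, 1, pad = 0, act = "relu6")
  }
  children$dw <- mk_convbn(hidden, hidden, 3, stride, groups = hidden,
                           act = "relu6")
  children$project <- mk_convbn(hidden, cout, 1, pad = 0, act = "none")
  list(type = "inverted_residual", params = list(), children = children,
       use_res = stride == 1 && cin == cout)
}

mk_shuffle_unit <- function(cin, cout, stride) {
  half <- cout %/% 2
  if (stride == 1) {
    abort_if(cin != cout, "stride-1 shuffle unit needs cin == cout")
    children <- list(
      branch2 = mk_seq(list(mk_convbn(half, half, 1, pad = 0),
                            mk_convbn(half, half, 3, 1, groups = half, act = "none"),
                            mk_convbn(half, half, 1, pad = 0))))
  } else {
    children <- list(
      branch1 = mk_seq(list(mk_convbn(cin, cin, 3, stride, groups = cin, act = "none"),
                            mk_convbn(cin, half, 1, pad = 0))),
      branch2 = mk_seq(list(mk_convbn(cin, half, 1, pad = 0),
                            mk_convbn(half, half, 3, stride, groups = half, act = "none"),
                            mk_convbn(half, half, 1, pad = 0))))
  }
  list(type = "shuffle_unit", params = list(), children = children,
       stride = stride)
}

# --- forward evaluation ----------------------------------------------------

pad_hw <- function(x, pad, value = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  out <- array(value, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

im2col <- function(x, k, stride) {
  d <- dim(x)
  oh <- (d[1] - k) %/% stride + 1L
  ow <- (d[2] - k) %/% stride + 1L
  abort_if(oh < 1 || ow < 1, "input too small for convolution kernel",
           class = "dctdetect_shape_error")
  m <- matrix(0, oh * ow, k * k * d[3])
  col <- 0L
  rows <- seq.int(1L, by = stride, length.out = oh)
  cols <- seq.int(1L, by = stride, length.out = ow)
  for (c in seq_len(d[3])) {
    for (dx in seq_len(k)) {
      for (dy in seq_len(k)) {
        col <- col + 1L
        m[, col] <- as.vector(x[rows + dy - 1L, cols + dx - 1L, c])
      }
    }
  }
  list(m = m, oh = oh, ow = ow)
}

conv_forward <- function(mod, x) {
  abort_if(dim(x)[3] != mod$cin, "channel mismatch in conv layer",
           class = "dctdetect_shape_error")
  xp <- pad_hw(x, mod$pad)
  g <- mod$groups
  cin_g <- mod$cin %/% g
  cout_g <- mod$cout %/% g
  out <- NULL
  for (gi in seq_len(g)) {
    xs <- xp[, , (gi - 1L) * cin_g + seq_len(cin_g), drop = FALSE]
    ic <- im2col(xs, mod$k, mod$stride)
    wg <- mod$params$weight[, (gi - 1L) * cout_g + seq_len(cout_g), drop = FALSE]
    og <- ic$m %*% wg
    if (is.null(out)) out <- array(0, dim = c(ic$oh, ic$ow, mod$cout))
    out[, , (gi - 1L) * cout_g + seq_len(cout_g)] <-
      array(og, dim = c(ic$oh, ic$ow, cout_g))
  }
  if (!is.null(mod$params$bias)) {
    out <- sweep(out, 3, mod$params$bias, "+")
  }
  out
}

maxpool_forward <- function(mod, x) {
  xp <- pad_hw(x, mod$pad, value = -Inf)
  d <- dim(xp)
  oh <- (d[1] - mod$k) %/% mod$stride + 1L
  ow <- (d[2] - mod$k) %/% mod$stride + 1L
  rows <- seq.int(1L, by = mod$stride, length.out = oh)
  cols <- seq.int(1L, by = mod$stride, length.out = ow)
  out <- array(-Inf, dim = c(oh, ow, d[3]))
  for (dy in seq_len(mod$k)) {
    for (dx in seq_len(mod$k)) {
      out <- pmax(out, xp[rows + dy - 1L, cols + dx - 1L, , drop = FALSE])
    }
  }
  out
}

channel_shuffle <- function(x, groups = 2L) {
  d <- dim(x)
  idx <- as.vector(matrix(seq_len(d[3]), nrow = groups, byrow = TRUE))
  x[, , idx, drop = FALSE]
}

module_forward <- function(mod, x) {
  switch(mod$type,
    conv = conv_forward(mod, x),
    bn = sweep(sweep(x, 3, mod$params$gamma, "*"), 3, mod$params$beta, "+"),
    act = switch(mod$kind,
                 relu = pmax(x, 0),
                 relu6 = pmin(pmax(x, 0), 6),
                 rlang::abort("unknown activation")),
    maxpool = maxpool_forward(mod, x),
    seq = Reduce(function(acc, m) module_forward(m, acc), mod$children, x),
    basic_block = {
      out <- module_forward(mod$children$conv2,
                            module_forward(mod$children$conv1, x))
      identity_path <- if (is.null(mod$children$down)) x else
        module_forward(mod$children$down, x)
      pmax(out + identity_path, 0)
    },
    inverted_residual = {
      h <- x
      if (!is.null(mod$children$expand)) h <- module_forward(mod$children$expand, h)
      h <- module_forward(mod$children$dw, h)
      h <- module_forward(mod$children$project, h)
      if (mod$use_res) h + x else h
    },
    shuffle_unit = {
      if (mod$stride == 1) {
        half <- dim(x)[3] %/% 2L
        x1 <- x[, , seq_len(half), drop = FALSE]
        x2 <- x[, , half + seq_len(half), drop = FALSE]
        out <- abind3(x1, module_forward(mod$children$branch2, x2))
      } else {
        out <- abind3(module_forward(mod$children$branch1, x),
                      module_forward(mod$children$branch2, x))
      }
      channel_shuffle(out)
    },
    rlang::abort(paste0("unknown module type: ", mod$type))
  )
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

global_average_pool <- function(x) {
  apply(x, 3, mean)
}

module_param_count <- function(mod) {
  if (is.null(mod)) return(0)
  n <- sum(vapply(mod$params, length, integer(1)))
  if (!is.null(mod$children)) {
    n <- n + sum(vapply(mod$children, module_param_count, numeric(1)))
  }
  n
}
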