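# Small U-Net built from scratch: im2col convolutions (C++ kernels), ReLU,
# 2x2 max pooling, nearest-neighbour upsampling, skip concatenation, softmax
# head. Feature maps are (H, W, C) arrays; parameters are kept in a flat
# named list so the Adam update is a simple loop.

# He-initialised conv parameter block: W is (k*k*Cin) x Cout, b length Cout
.conv_param <- function(cin, cout, k) {
  list(W = base::matrix(rnorm(cout * k * k * cin, 0, sqrt(2 / (k * k * cin))),
                        k * k * cin, cout),
       b = rep(0, cout), k = k, pad = (k - 1) %/% 2, cin = cin, cout = cout)
}

.conv_fwd <- function(x, p, relu = TRUE) {
  r <- conv_fwd_cpp(x, p$W, p$b, p$k, p$pad, relu)
  list(out = r$out,
       cache = list(cols = r$cols, out = if (relu) r$out, dim_in = dim(x),
                    relu = relu, p = p))
}

.conv_bwd <- function(dout, cache) {
  p <- cache$p
  d <- cache$dim_in
  conv_bwd_cpp(dout, if (cache$relu) cache$out else dout, cache$cols, p$W,
               d[1], d[2], p$cin, p$k, p$pad, cache$relu)
}

.up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
}

.up2_bwd <- function(dd) {
  d <- dim(dd)
  o <- dd[seq(1, d[1], 2), , , drop = FALSE] + dd[seq(2, d[1], 2), , , drop = FALSE]
  o[, seq(1, d[2], 2), , drop = FALSE] + o[, seq(2, d[2], 2), , drop = FALSE]
}

.softmax3 <- function(logits) {
  d <- dim(logits)
  m <- base::matrix(logits, d[1] * d[2], d[3])
  m <- m - do.call(pmax, as.data.frame(m))
  e <- exp(m)
  array(e / rowSums(e), d)
}

#' Initialise a small U-Net style segmentation model
#'
#' A plain convolutional encoder-decoder: per level one 3x3 conv + ReLU,
#' 2x2 max pooling on the way down, nearest-neighbour upsampling, an
#' up-convolution, skip concatenation and a merge convolution on the way up,
#' and a 1x1 linear head producing class logits. Channel widths are given
#' coarse-to-fine as in the full-scale architecture description (which uses
#' depth 5 and channels 256...16); the desk-scale default is depth 3 with
#' (32, 16, 8).
#'
#' @param in_channels input channels (1 for magnitude images).
#' @param n_classes output classes (3: background, healthy myocardium, scar).
#' @param encoder_depth number of downsampling steps.
#' @param decoder_channels coarse-to-fine channel widths, length
#'   `encoder_depth`.
#' @param seed RNG seed for the He initialisation (restores caller RNG).
#' @return a `scar_net` model object.
#' @export
unet_init <- function(in_channels = 1, n_classes = 3, encoder_depth = 3,
                      decoder_channels = c(32, 16, 8), seed = 1L) {
  if (length(decoder_channels) != encoder_depth)
    .stopf("decoder_channels must have length encoder_depth")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  ch <- rev(decoder_channels)               # fine-to-coarse encoder widths
  depth <- encoder_depth
  cb <- 2 * ch[depth]                       # bottleneck width
  P <- list()
  cin <- in_channels
  for (i in seq_len(depth)) {
    P[[paste0("enc", i)]] <- .conv_param(cin, ch[i], 3)
    cin <- ch[i]
  }
  P[["bott"]] <- .conv_param(ch[depth], cb, 3)
  cur <- cb
  for (i in rev(seq_len(depth))) {
    P[[paste0("up", i)]] <- .conv_param(cur, ch[i], 3)
    P[[paste0("mer", i)]] <- .conv_param(2 * ch[i], ch[i], 3)
    cur <- ch[i]
  }
  P[["head"]] <- .conv_param(ch[1], n_classes, 1)
  structure(list(params = P, depth = depth, channels = ch,
                 in_channels = in_channels, n_classes = n_classes,
                 init_seed = as.integer(seed)),
            class = "scar_net")
}

#' @export
print.scar_net <- function(x, ...) {
  npar <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), 0))
  cat(sprintf("scar_net: depth %d, channels (%s), %d classes, %d parameters\n",
              x$depth, paste(x$channels, collapse = ", "), x$n_classes, npar))
  invisible(x)
}

# forward pass; returns class probabilities and (optionally) the caches
# needed for backprop
.unet_forward <- function(model, x, want_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1))
  H <- dim(x)[1]
  if (H %% 2^model$depth != 0 || dim(x)[2] %% 2^model$depth != 0)
    .stopf("input size must be divisible by 2^depth")
  P <- model$params
  depth <- model$depth
  skips <- vector("list", depth)
  enc_cache <- vector("list", depth)
  cur <- x
  for (i in seq_len(depth)) {
    r <- .conv_fwd(cur, P[[paste0("enc", i)]])
    skips[[i]] <- r$out
    pl <- maxpool2_fwd_cpp(r$out)
    enc_cache[[i]] <- list(conv = r$cache, poolidx = pl$idx, dim = dim(r$out))
    cur <- pl$out
  }
  rb <- .conv_fwd(cur, P$bott)
  cur <- rb$out
  dec_cache <- vector("list", depth)
  for (i in rev(seq_len(depth))) {
    u <- .up2(cur)
    r1 <- .conv_fwd(u, P[[paste0("up", i)]])
    c1 <- dim(r1$out)[3]
    cat_x <- array(c(r1$out, skips[[i]]), c(dim(r1$out)[1], dim(r1$out)[2],
                                            c1 + dim(skips[[i]])[3]))
    r2 <- .conv_fwd(cat_x, P[[paste0("mer", i)]])
    dec_cache[[i]] <- list(up = r1$cache, mer = r2$cache, c1 = c1)
    cur <- r2$out
  }
  rh <- .conv_fwd(cur, P$head, relu = FALSE)
  probs <- .softmax3(rh$out)
  if (!want_cache) return(list(probs = probs))
  list(probs = probs,
       cache = list(enc = enc_cache, bott = rb$cache, dec = dec_cache,
                    head = rh$cache))
}

# backprop from d(loss)/d(logits); returns flat gradient list mirroring params
.unet_backward <- function(model, cache, dlogits) {
  depth <- model$depth
  G <- list()
  bh <- .conv_bwd(dlogits, cache$head)
  G$head <- bh[c("dW", "db")]
  d <- bh$dx
  dskips <- vector("list", depth)
  for (i in seq_len(depth)) {          # decoder was applied coarse->fine
    dc <- cache$dec[[i]]
    b2 <- .conv_bwd(d, dc$mer)
    G[[paste0("mer", i)]] <- b2[c("dW", "db")]
    c1 <- dc$c1
    ctot <- dim(b2$dx)[3]
    d_up_out <- b2$dx[, , seq_len(c1), drop = FALSE]
    dskips[[i]] <- b2$dx[, , (c1 + 1):ctot, drop = FALSE]
    b1 <- .conv_bwd(d_up_out, dc$up)
    G[[paste0("up", i)]] <- b1[c("dW", "db")]
    d <- .up2_bwd(b1$dx)
  }
  bb <- .conv_bwd(d, cache$bott)
  G$bott <- bb[c("dW", "db")]
  d <- bb$dx
  for (i in rev(seq_len(depth))) {
    ec <- cache$enc[[i]]
    dpool <- maxpool2_bwd_cpp(d, ec$poolidx, ec$dim[1], ec$dim[2], ec$dim[3])
    dtot <- dpool + dskips[[i]]
    be <- .conv_bwd(dtot, ec$conv)
    G[[paste0("enc", i)]] <- be[c("dW", "db")]
    d <- be$dx
  }
  G
}

# accumulate gradient lists (same structure)
.grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    a[[nm]]$dW <- a[[nm]]$dW + b[[nm]]$dW
    a[[nm]]$db <- a[[nm]]$db + b[[nm]]$db
  }
  a
}

.adam_init <- function(params) {
  st <- list(t = 0, m = list(), v = list())
  for (nm in names(params)) {
    st$m[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)
    st$v[[nm]] <- list(W = params[[nm]]$W * 0, b = params[[nm]]$b * 0)
  }
  st
}

.adam_step <- function(params, grads, st, lr, beta1, beta2, eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    for (f in c("W", "b")) {
      g <- grads[[nm]][[paste0("d", f)]]
      st$m[[nm]][[f]] <- beta1 * st$m[[nm]][[f]] + (1 - beta1) * g
      st$v[[nm]][[f]] <- beta2 * st$v[[nm]][[f]] + (1 - beta2) * g^2
      mh <- st$m[[nm]][[f]] / bc1
      vh <- st$v[[nm]][[f]] / bc2
      params[[nm]][[f]] <- params[[nm]][[f]] - lr * mh / (sqrt(vh) + eps)
    }
  }
  list(params = params, state = st)
}

# multi-class soft Dice loss over a batch, with smoothing eps in numerator
# and denominator so empty classes are well defined.
# probs/onehots: lists of (H,W,K) arrays. Returns loss, per-class soft dice,
# and d(loss)/d(probs) per sample.
.dice_loss_batch <- function(probs, onehots, eps = 1) {
  K <- dim(probs[[1]])[3]
  inter <- den <- rep(0, K)
  for (n in seq_along(probs)) {
    for (k in seq_len(K)) {
      p <- probs[[n]][, , k]; g <- onehots[[n]][, , k]
      inter[k] <- inter[k] + sum(p * g)
      den[k] <- den[k] + sum(p) + sum(g)
    }
  }
  num <- 2 * inter + eps
  dd <- den + eps
  dice_k <- num / dd
  loss <- 1 - mean(dice_k)
  dprobs <- vector("list", length(probs))
  for (n in seq_along(probs)) {
    dp <- array(0, dim(probs[[n]]))
    for (k in seq_len(K)) {
      g <- onehots[[n]][, , k]
      dp[, , k] <- -(1 / K) * (2 * g - dice_k[k]) / dd[k]
    }
    dprobs[[n]] <- dp
  }
  list(loss = loss, dice = dice_k, dprobs = dprobs)
}

# chain rule through the softmax: dz = p * (dp - sum_k dp_k p_k)
.softmax_bwd <- function(probs, dprobs) {
  s <- probs[, , 1] * dprobs[, , 1]
  for (k in 2:dim(probs)[3]) s <- s + probs[, , k] * dprobs[, , k]
  dz <- dprobs
  for (k in seq_len(dim(probs)[3])) dz[, , k] <- probs[, , k] * (dprobs[, , k] - s)
  dz
}
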