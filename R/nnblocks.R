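# Standalone neural operators on plain (C, H, W) arrays: fast-normalized
# weighted fusion, BiFPN node updates, efficient channel attention (ECA),
# residual connection, and convolutional block attention (CBAM). These are the
# forward-only reference forms; the trainable networks compose the same math
# through the autograd ops, and the two routes are cross-checked in the tests.

check_feature_map <- function(x, name = "x") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(name, " must be a rank-3 array (channels x height x width)")
  if (!all(is.finite(x))) stop(name, " contains non-finite values")
  invisible(x)
}

#' Fast-normalized weighted feature fusion
#'
#' Combines feature maps of identical shape as
#' \deqn{O = \sum_i \frac{w_i}{\epsilon + \sum_j w_j} I_i}
#' with learnable non-negative scalar weights and a small stabilizer
#' \eqn{\epsilon}. Raw weights are projected to be non-negative (ReLU) before
#' use, so each normalized coefficient lies in \[0, 1) and the coefficients
#' sum to \eqn{\sum w / (\epsilon + \sum w)}. This is the fusion rule used at
#' every BiFPN node. An all-zero weight vector is valid and yields the zero
#' map.
#'
#' @param maps List of arrays of identical dim `(C, H, W)`.
#' @param weights Numeric vector of raw weights, one per map.
#' @param epsilon Stabilizer constant, default `1e-4`.
#' @return Array of the common shape.
#' @export
#' @examples
#' m <- array(1, c(2, 4, 4))
#' out <- fast_normalized_fusion(list(m, m), c(1, 1))
#' range(out)  # 2 / 2.0001
fast_normalized_fusion <- function(maps, weights, epsilon = 1e-4) {
  stopifnot(is.list(maps), length(maps) >= 1L, length(weights) == length(maps))
  d <- dim(maps[[1]])
  for (i in seq_along(maps)) {
    check_feature_map(maps[[i]], sprintf("maps[[%d]]", i))
    if (!identical(dim(maps[[i]]), d)) stop("all maps must share one shape")
  }
  u <- pmax(as.numeric(weights), 0)
  co <- u / (epsilon + sum(u))
  out <- array(0, d)
  for (i in seq_along(maps)) out <- out + co[i] * maps[[i]]
  out
}

# nearest-neighbour resize by a factor of 2 (the BiFPN cross-level Resize)
resize_nn_up2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2]), each = 2L), rep(seq_len(d[3]), each = 2L), drop = FALSE]
}

resize_nn_down2 <- function(x) {
  d <- dim(x)
  x[, seq(1L, d[2], 2L), seq(1L, d[3], 2L), drop = FALSE]
}

# forward 2-D convolution on a (C,H,W) array; w is (Cout x Cin*kh*kw)
conv2d <- function(x, w, b, kh = 3L, kw = 3L, stride = 1L, pad = 1L) {
  .conv2d_fw(x, w, as.numeric(b), as.integer(kh), as.integer(kw),
             as.integer(stride), as.integer(pad))
}

#' Parameters for one BiFPN fusion node
#'
#' Creates the learnable state of a BiFPN node at one pyramid level: a
#' 2-weight fusion for the top-down (intermediate) path, a 3-weight fusion for
#' the bottom-up (output) path, and one 3x3 fusion convolution per path.
#' `conv = "identity"` skips the convolutions, which is convenient for
#' analytic checks.
#'
#' @param channels Channel width of the fused maps.
#' @param conv `"random"` for He-initialized 3x3 convolutions or
#'   `"identity"`.
#' @param epsilon Fusion stabilizer.
#' @return List with `td_w`, `out_w`, conv weights and `epsilon`.
#' @export
bifpn_node_params <- function(channels, conv = c("random", "identity"),
                              epsilon = 1e-4) {
  conv <- match.arg(conv)
  p <- list(td_w = c(1, 1), out_w = c(1, 1, 1), epsilon = epsilon)
  if (conv == "random") {
    p$conv_td <- init_conv(channels, channels, 3, 3)
    p$b_td <- numeric(channels)
    p$conv_out <- init_conv(channels, channels, 3, 3)
    p$b_out <- numeric(channels)
  }
  p
}

#' One BiFPN node: top-down then bottom-up fusion at a pyramid level
#'
#' Computes the intermediate (top-down) and output (bottom-up) maps of a
#' bidirectional feature pyramid node:
#' \deqn{P_l = Conv(Fuse(F_l, Resize(F_{up})))}
#' \deqn{N_l = Conv(Fuse(F_l, P_l, Resize(N_{down})))}
#' where `Fuse` is [fast_normalized_fusion()] with the node's 2- and 3-element
#' weight vectors and `Resize` is nearest-neighbour up/down-sampling by a
#' factor of 2.
#'
#' @param f_l Lateral feature map `(C, H, W)` at this level.
#' @param f_up Map from the coarser level (spatial size `H/2 x W/2`).
#' @param n_down Bottom-up map from the finer level (spatial size `2H x 2W`).
#' @param node Node parameters from [bifpn_node_params()].
#' @return List with maps `p` (intermediate) and `n` (output), both shaped
#'   like `f_l`.
#' @export
bifpn_node <- function(f_l, f_up, n_down, node) {
  check_feature_map(f_l, "f_l")
  up <- resize_nn_up2(f_up)
  dn <- resize_nn_down2(n_down)
  if (!identical(dim(up)[2:3], dim(f_l)[2:3]) ||
      !identical(dim(dn)[2:3], dim(f_l)[2:3]))
    stop("incompatible pyramid strides between levels")
  p <- fast_normalized_fusion(list(f_l, up), node$td_w, node$epsilon)
  if (!is.null(node$conv_td)) p <- conv2d(p, node$conv_td, node$b_td)
  n <- fast_normalized_fusion(list(f_l, p, dn), node$out_w, node$epsilon)
  if (!is.null(node$conv_out)) n <- conv2d(n, node$conv_out, node$b_out)
  list(p = p, n = n)
}

#' Learnable state for an ECA block
#'
#' The channel-attention form used here follows the printed equations of the
#' method: a two-layer fully connected reduction on the globally
#' average-pooled channel vector, a sigmoid squashing so channel weights lie
#' in (0, 1), and a learnable output scale `gamma` (initialized to 1). The
#' conventional efficient-channel-attention design replaces the FC pair with a
#' k-tap 1-D convolution across channels; that form is available as
#' `variant = "conv1d"`.
#'
#' @param channels Number of channels the block operates on.
#' @param reduction FC bottleneck ratio (FC variant), default 4.
#' @param gamma Initial output scale.
#' @param variant `"as_printed"` (FC pair) or `"conv1d"`.
#' @param k 1-D kernel size for the conv1d variant (odd), default 3.
#' @return List of weights understood by [eca_block()].
#' @export
eca_state <- function(channels, reduction = 4, gamma = 1,
                      variant = c("as_printed", "conv1d"), k = 3L) {
  variant <- match.arg(variant)
  s <- list(variant = variant, gamma = gamma, channels = channels)
  if (variant == "as_printed") {
    cr <- max(1L, as.integer(channels / reduction))
    s$fc1 <- init_fc(cr, channels); s$b1 <- numeric(cr)
    s$fc2 <- init_fc(channels, cr); s$b2 <- numeric(channels)
  } else {
    s$k <- as.integer(k)
    s$kernel <- rnorm(k, 0, sqrt(2 / k))
  }
  s
}

#' Efficient channel attention block
#'
#' Applies per-channel gating to a feature map:
#' `M = AvgPool(X)` (global average pool per channel),
#' `W = sigmoid(FC(ReLU(FC(M))))`, `Y = X (*) W` (broadcast over space),
#' `Z = Y * gamma`.
#'
#' @param x Feature map `(C, H, W)`.
#' @param state Weights from [eca_state()].
#' @return Array shaped like `x`.
#' @export
eca_block <- function(x, state) {
  check_feature_map(x)
  d <- dim(x)
  if (d[1] != state$channels) stop("channel mismatch: block configured for ",
                                   state$channels, ", got ", d[1])
  m <- rowMeans(matrix(x, nrow = d[1]))
  if (state$variant == "as_printed") {
    h <- pmax(as.numeric(state$fc1 %*% m + state$b1), 0)
    w <- plogis(as.numeric(state$fc2 %*% h + state$b2))
  } else {
    half <- (state$k - 1L) %/% 2L
    mp <- c(rep(0, half), m, rep(0, half))
    w <- vapply(seq_len(d[1]), function(c)
      sum(state$kernel * mp[c:(c + state$k - 1L)]), numeric(1))
    w <- plogis(w)
  }
  (x * w) * state$gamma
}

#' Residual connection
#'
#' `Y = X + F(X)` for a residual transform `F` whose output matches the shape
#' of `X`.
#'
#' @param x Feature map `(C, H, W)`.
#' @param residual_fn Function of one feature map returning an equal-shape map.
#' @return Array shaped like `x`.
#' @export
residual_block <- function(x, residual_fn) {
  check_feature_map(x)
  f <- residual_fn(x)
  if (!identical(dim(f), dim(x)))
    stop("residual_fn changed the shape (", paste(dim(f), collapse = "x"),
         " vs ", paste(dim(x), collapse = "x"), ")")
  x + f
}

#' Learnable state for a CBAM block
#'
#' Channel attention (CAM): a reduction-`r` FC pair on the globally
#' average-pooled channel vector, sigmoid. Spatial attention module (SAM), as
#' printed in the method: a single FC on the globally max-pooled channel
#' vector of the channel-gated map, sigmoid, broadcast per channel (a second
#' channel gate). The canonical CBAM spatial form — a 7x7 convolution over the
#' channel-pooled maps producing one weight per location — is available as
#' `sam_variant = "conv7x7"`.
#'
#' @param channels Number of channels.
#' @param reduction CAM bottleneck ratio, default 16.
#' @param sam_variant `"as_printed"` or `"conv7x7"`.
#' @return List of weights understood by [cbam_block()].
#' @export
cbam_state <- function(channels, reduction = 16,
                       sam_variant = c("as_printed", "conv7x7")) {
  sam_variant <- match.arg(sam_variant)
  cr <- max(1L, as.integer(channels / reduction))
  s <- list(channels = channels, sam_variant = sam_variant,
            cam_fc1 = init_fc(cr, channels), cam_b1 = numeric(cr),
            cam_fc2 = init_fc(channels, cr), cam_b2 = numeric(channels))
  if (sam_variant == "as_printed") {
    s$sam_fc <- init_fc(channels, channels)
    s$sam_b <- numeric(channels)
  } else {
    s$sam_conv <- init_conv(1, 2, 7, 7)
    s$sam_cb <- 0
  }
  s
}

#' Convolutional block attention (CBAM)
#'
#' Sequential channel then spatial attention:
#' `A_c = sigmoid(FC(AvgPool(X)))`, `X_c = A_c (*) X`,
#' `A_s = sigmoid(FC(MaxPool(X_c)))`, `Z = A_s (*) X_c`,
#' with the CAM weights broadcast over space. See [cbam_state()] for the two
#' SAM forms.
#'
#' @param x Feature map `(C, H, W)`.
#' @param state Weights from [cbam_state()].
#' @return Array shaped like `x`.
#' @export
cbam_block <- function(x, state) {
  check_feature_map(x)
  d <- dim(x)
  if (d[1] != state$channels) stop("channel mismatch: block configured for ",
                                   state$channels, ", got ", d[1])
  m <- rowMeans(matrix(x, nrow = d[1]))
  h <- pmax(as.numeric(state$cam_fc1 %*% m + state$cam_b1), 0)
  ac <- plogis(as.numeric(state$cam_fc2 %*% h + state$cam_b2))
  xc <- x * ac
  if (state$sam_variant == "as_printed") {
    mx <- apply(matrix(xc, nrow = d[1]), 1, max)
    as_ <- plogis(as.numeric(state$sam_fc %*% mx + state$sam_b))
    xc * as_
  } else {
    avg <- array(colMeans(matrix(xc, nrow = d[1])), c(1, d[2], d[3]))
    mxs <- array(apply(matrix(xc, nrow = d[1]), 2, max), c(1, d[2], d[3]))
    pooled <- array(0, c(2, d[2], d[3]))
    pooled[1, , ] <- avg; pooled[2, , ] <- mxs
    as_ <- plogis(conv2d(pooled, state$sam_conv, state$sam_cb,
                         kh = 7, kw = 7, pad = 3))
    sweep_map <- array(rep(as_[1, , ], each = d[1]), d)
    xc * sweep_map
  }
}
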