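# Independent scalar-loop oracles for the neural operators and metrics.
# These deliberately re-derive every quantity with plain loops (no shared
# code with the implementation).

oracle_fusion <- function(maps, weights, eps = 1e-4) {
  u <- ifelse(weights > 0, weights, 0)
  d <- dim(maps[[1]])
  out <- array(0, d)
  for (c in seq_len(d[1])) for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
    s <- 0
    for (i in seq_along(maps))
      s <- s + u[i] / (eps + sum(u)) * maps[[i]][c, h, w]
    out[c, h, w] <- s
  }
  out
}

oracle_eca <- function(x, st) {
  d <- dim(x)
  M <- numeric(d[1])
  for (c in seq_len(d[1])) M[c] <- mean(x[c, , ])
  hid <- numeric(nrow(st$fc1))
  for (k in seq_len(nrow(st$fc1)))
    hid[k] <- max(0, sum(st$fc1[k, ] * M) + st$b1[k])
  w <- numeric(d[1])
  for (c in seq_len(d[1]))
    w[c] <- 1 / (1 + exp(-(sum(st$fc2[c, ] * hid) + st$b2[c])))
  z <- array(0, d)
  for (c in seq_len(d[1])) for (h in seq_len(d[2])) for (ww in seq_len(d[3]))
    z[c, h, ww] <- x[c, h, ww] * w[c] * st$gamma
  z
}

oracle_cbam <- function(x, st) {
  d <- dim(x)
  M <- numeric(d[1])
  for (c in seq_len(d[1])) M[c] <- mean(x[c, , ])
  hid <- numeric(nrow(st$cam_fc1))
  for (k in seq_len(nrow(st$cam_fc1)))
    hid[k] <- max(0, sum(st$cam_fc1[k, ] * M) + st$cam_b1[k])
  ac <- numeric(d[1])
  for (c in seq_len(d[1]))
    ac[c] <- 1 / (1 + exp(-(sum(st$cam_fc2[c, ] * hid) + st$cam_b2[c])))
  xc <- array(0, d)
  for (c in seq_len(d[1])) for (h in seq_len(d[2])) for (w in seq_len(d[3]))
    xc[c, h, w] <- x[c, h, w] * ac[c]
  mx <- numeric(d[1])
  for (c in seq_len(d[1])) mx[c] <- max(xc[c, , ])
  as_ <- numeric(d[1])
  for (c in seq_len(d[1]))
    as_[c] <- 1 / (1 + exp(-(sum(st$sam_fc[c, ] * mx) + st$sam_b[c])))
  z <- array(0, d)
  for (c in seq_len(d[1])) for (h in seq_len(d[2])) for (w in seq_len(d[3]))
    z[c, h, w] <- xc[c, h, w] * as_[c]
  z
}

# AUC as the normalized Mann-Whitney U statistic (rank oracle)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# brute-force AP: greedy confidence-ordered matching re-derived with plain
# loops, all-points interpolated precision envelope
oracle_ap <- function(pred, gt, iou_thr = 0.5) {
  iou <- function(a, b) {
    iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
    ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
    inter <- iw * ih
    inter / ((a[3] - a[1]) * (a[4] - a[2]) +
               (b[3] - b[1]) * (b[4] - b[2]) - inter)
  }
  ord <- order(-pred$confidence, pred$x_min)
  used <- rep(FALSE, nrow(gt))
  tp <- numeric(nrow(pred))
  for (k in seq_along(ord)) {
    i <- ord[k]
    best <- 0; bj <- 0
    for (j in seq_len(nrow(gt))) {
      if (used[j] || gt$image[j] != pred$image[i]) next
      v <- iou(as.numeric(pred[i, c("x_min", "y_min", "x_max", "y_max")]),
               as.numeric(gt[j, c("x_min", "y_min", "x_max", "y_max")]))
      if (v > best) { best <- v; bj <- j }
    }
    if (bj > 0 && best >= iou_thr) { tp[k] <- 1; used[bj] <- TRUE }
  }
  rec <- cumsum(tp) / nrow(gt)
  prec <- cumsum(tp) / seq_along(tp)
  ap <- 0; prev_r <- 0
  for (k in seq_along(tp)) {
    p_env <- max(prec[k:length(prec)])
    ap <- ap + (rec[k] - prev_r) * p_env
    prev_r <- rec[k]
  }
  ap
}

rand_map <- function(d, lo = -1, hi = 1) array(runif(prod(d), lo, hi), d)
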