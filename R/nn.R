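# Minimal neural-network primitives for the MIL classifier.
#
# All layers operate on activation arrays of dim (S, S, C, N): spatial
# rows/cols, channels, instances. Convolutions are 3x3, stride 1, with
# EDGE (replicate) padding: on the small feature maps used here the
# border ring is a large share of the map, and edge padding guarantees
# that a spatially constant input stays exactly constant through the
# stack (a symmetry the class-activation maps rely on). Implemented as
# gather (im2col) + matrix multiply; backward scatters with `rowsum`.

# 3x3 tap source indices with edge clamping for an S x S plane.
# Returns an S^2 x 9 matrix of linear indices; tap order is row-offset
# fastest, matching the weight layout built in `nn_init`.
conv_gather_base <- function(S) {
  i <- rep(seq_len(S), S)           # row of output pixel
  j <- rep(seq_len(S), each = S)    # col
  B <- matrix(0L, S * S, 9L)
  k <- 0L
  for (dj in -1:1) {
    for (di in -1:1) {
      k <- k + 1L
      si <- pmin(S, pmax(1L, i + di))
      sj <- pmin(S, pmax(1L, j + dj))
      B[, k] <- si + (sj - 1L) * S
    }
  }
  B
}

# Cache of gather/scatter index plans keyed by (S, C, N). The plan
# holds a single flat gather index building the im2col matrix straight
# from the activation vector, and a presorted scatter order so the
# backward accumulation is a gather + cumsum instead of a sort per call.
nn_index_cache <- new.env(parent = emptyenv())

conv_indices <- function(S, C, N) {
  key <- paste(S, C, N, sep = "x")
  hit <- nn_index_cache[[key]]
  if (!is.null(hit)) return(hit)
  B <- conv_gather_base(S)
  P <- S * S
  p <- seq_len(P); n <- seq_len(N); k <- seq_len(9L); cc <- seq_len(C)
  # Xcol element (row = p + (n-1)P, col = k + (c-1)9), column-major:
  #   position = p + (n-1)P + (k-1)PN + (c-1)PN9
  #   source   = B[p,k] + (c-1)P + (n-1)PC
  src <- B[p, ]                                          # P x 9
  gather <- array(0L, c(P, N, 9L, C))
  for (ci in cc) for (ki in k)
    gather[, , ki, ci] <- outer(src[, ki] + (ci - 1L) * P,
                                (n - 1L) * P * C, `+`)
  gather <- as.integer(gather)
  # scatter: target of Xcol-gradient element at `position` is `gather`
  ord <- order(gather, method = "radix")
  ends <- cumsum(tabulate(gather, P * C * N))
  out <- list(gather = gather, ord = ord, ends = ends)
  nn_index_cache[[key]] <- out
  out
}

conv_forward <- function(X, W, b, S, C, N) {
  idx <- conv_indices(S, C, N)
  Xcol <- matrix(X[idx$gather], S * S * N, 9L * C)
  Y <- Xcol %*% W
  Y <- sweep(Y, 2L, b, `+`)
  f <- ncol(W)
  out <- aperm(array(Y, c(S * S, N, f)), c(1L, 3L, 2L))
  list(out = array(out, c(S, S, f, N)), Xcol = Xcol)
}

conv_backward <- function(dOut, Xcol, W, S, C, N) {
  f <- ncol(W)
  dY <- matrix(aperm(array(dOut, c(S * S, f, N)), c(1L, 3L, 2L)),
               S * S * N, f)
  dW <- crossprod(Xcol, dY)
  db <- colSums(dY)
  dXcol <- tcrossprod(dY, W)                          # (S^2*N) x (9*C)
  idx <- conv_indices(S, C, N)
  cs <- cumsum(dXcol[idx$ord])
  acc <- cs[idx$ends] - c(0, cs[idx$ends[-length(idx$ends)]])
  list(dX = array(acc, c(S, S, C, N)), dW = dW, db = db)
}

relu_forward <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_backward <- function(dOut, mask) dOut * mask

# 2x2 max pooling, stride 2; ties resolved in fixed tap order.
pool_forward <- function(X, S) {
  s <- seq(1L, S, 2L)
  x1 <- X[s, s, , , drop = FALSE]
  x2 <- X[s + 1L, s, , , drop = FALSE]
  x3 <- X[s, s + 1L, , , drop = FALSE]
  x4 <- X[s + 1L, s + 1L, , , drop = FALSE]
  which <- array(1L, dim(x1)); cur <- x1
  m <- x2 > cur; cur[m] <- x2[m]; which[m] <- 2L
  m <- x3 > cur; cur[m] <- x3[m]; which[m] <- 3L
  m <- x4 > cur; cur[m] <- x4[m]; which[m] <- 4L
  list(out = cur, which = which)
}

pool_backward <- function(dOut, which, S) {
  d <- dim(dOut)
  dX <- array(0, c(S, S, d[3L], d[4L]))
  s <- seq(1L, S, 2L)
  for (t in 1:4) {
    sel <- which == t
    if (!any(sel)) next
    blk <- array(0, d)
    blk[sel] <- dOut[sel]
    if (t == 1L) dX[s, s, , ] <- blk
    else if (t == 2L) dX[s + 1L, s, , ] <- blk
    else if (t == 3L) dX[s, s + 1L, , ] <- blk
    else dX[s + 1L, s + 1L, , ] <- blk
  }
  dX
}

gap_forward <- function(X, S, C, N) {
  H <- t(matrix(colMeans(matrix(X, S * S, C * N)), C, N))  # N x C
  H
}

gap_backward <- function(dH, S, C, N) {
  array(rep(as.vector(t(dH)) / (S * S), each = S * S), c(S, S, C, N))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- parameter containers ---------------------------------------------

# Architecture bookkeeping for the three-block backbone.
nn_arch <- function(input_side = 16L, in_channels = 3L,
                    conv_channels = c(8L, 16L, 32L),
                    attention_hidden_dim = 16L) {
  stopifnot(length(conv_channels) == 3L, input_side %% 4L == 0L)
  list(
    input_side = as.integer(input_side),
    in_channels = as.integer(in_channels),
    conv_channels = as.integer(conv_channels),
    sides = c(input_side, input_side %/% 2L, input_side %/% 4L),
    feature_dim = as.integer(conv_channels[3L]),
    attention_hidden_dim = as.integer(attention_hidden_dim)
  )
}

# He-initialised backbone weights plus gated-attention and scoring head.
nn_init <- function(arch, seed, head = c("mil", "patch")) {
  head <- match.arg(head)
  with_seed(seed, {
    ch <- c(arch$in_channels, arch$conv_channels)
    p <- list()
    for (l in 1:3) {
      fan_in <- 9L * ch[l]
      p[[paste0("W", l)]] <- matrix(
        stats::rnorm(fan_in * ch[l + 1L], sd = sqrt(2 / fan_in)),
        fan_in, ch[l + 1L])
      p[[paste0("b", l)]] <- numeric(ch[l + 1L])
    }
    fd <- arch$feature_dim
    if (head == "mil") {
      D <- arch$attention_hidden_dim
      p$Wv <- matrix(stats::rnorm(fd * D, sd = sqrt(1 / fd)), fd, D)
      p$bv <- numeric(D)
      p$Wu <- matrix(stats::rnorm(fd * D, sd = sqrt(1 / fd)), fd, D)
      p$bu <- numeric(D)
      p$ww <- matrix(stats::rnorm(D, sd = sqrt(1 / D)), D, 1L)
      p$wc <- matrix(stats::rnorm(fd, sd = sqrt(1 / fd)), fd, 1L)
      p$bc <- 0
    } else {
      p$wc <- matrix(stats::rnorm(fd, sd = sqrt(1 / fd)), fd, 1L)
      p$bc <- 0
    }
    p
  })
}

# ---- backbone ----------------------------------------------------------

# X: instance matrix N x (side^2 * channels), rows are flattened
# (side, side, channel) arrays in column-major order.
backbone_forward <- function(params, X, arch, keep = FALSE) {
  N <- nrow(X)
  s <- arch$sides; ch <- c(arch$in_channels, arch$conv_channels)
  A0 <- array(as.vector(t(X)), c(s[1L], s[1L], ch[1L], N))
  c1 <- conv_forward(A0, params$W1, params$b1, s[1L], ch[1L], N)
  r1 <- relu_forward(c1$out)
  p1 <- pool_forward(r1$out, s[1L])
  c2 <- conv_forward(p1$out, params$W2, params$b2, s[2L], ch[2L], N)
  r2 <- relu_forward(c2$out)
  p2 <- pool_forward(r2$out, s[2L])
  c3 <- conv_forward(p2$out, params$W3, params$b3, s[3L], ch[3L], N)
  r3 <- relu_forward(c3$out)
  H <- gap_forward(r3$out, s[3L], ch[4L], N)
  cache <- NULL
  if (keep)
    cache <- list(c1 = c1, r1m = r1$mask, p1 = p1, c2 = c2, r2m = r2$mask,
                  p2 = p2, c3 = c3, r3m = r3$mask, conv3_maps = r3$out,
                  N = N)
  list(H = H, cache = cache)
}

backbone_backward <- function(params, cache, dH, arch) {
  s <- arch$sides; ch <- c(arch$in_channels, arch$conv_channels)
  N <- cache$N
  d3 <- gap_backward(dH, s[3L], ch[4L], N)
  d3 <- relu_backward(d3, cache$r3m)
  g3 <- conv_backward(d3, cache$c3$Xcol, params$W3, s[3L], ch[3L], N)
  dp2 <- pool_backward(g3$dX, cache$p2$which, s[2L])
  dp2 <- relu_backward(dp2, cache$r2m)
  g2 <- conv_backward(dp2, cache$c2$Xcol, params$W2, s[2L], ch[2L], N)
  dp1 <- pool_backward(g2$dX, cache$p1$which, s[1L])
  dp1 <- relu_backward(dp1, cache$r1m)
  g1 <- conv_backward(dp1, cache$c1$Xcol, params$W1, s[1L], ch[1L], N)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db)
}

# ---- gated-attention MIL head -----------------------------------------

# Forward pass of backbone + gated attention + scoring head on an
# instance matrix. Returns attention weights (sum to 1), the bag
# embedding, and the bag score in [0, 1].
milnet_forward <- function(params, X, arch, keep = FALSE) {
  bb <- backbone_forward(params, X, arch, keep = keep)
  H <- bb$H                                            # N x fd
  Vh <- tanh(sweep(H %*% params$Wv, 2L, params$bv, `+`))
  Uh <- sigmoid(sweep(H %*% params$Wu, 2L, params$bu, `+`))
  G <- Vh * Uh
  e <- as.vector(G %*% params$ww)
  e <- e - max(e)
  a <- exp(e); a <- a / sum(a)
  z <- as.vector(crossprod(H, a))                      # fd
  logit <- sum(params$wc * z) + params$bc
  score <- sigmoid(logit)
  cache <- NULL
  if (keep) cache <- list(bb = bb$cache, H = H, Vh = Vh, Uh = Uh, G = G,
                          a = a, z = z, score = score)
  list(weights = a, embedding = z, score = score, logit = logit,
       cache = cache)
}

# Backward pass for bag-level binary cross-entropy; y in {0, 1}.
milnet_backward <- function(params, fw, y, arch) {
  cc <- fw$cache
  H <- cc$H; a <- cc$a; N <- nrow(H)
  dlogit <- fw$score - y
  dz <- params$wc * dlogit                             # fd x 1
  g <- list(wc = matrix(cc$z * dlogit, ncol = 1L), bc = dlogit)
  da <- as.vector(H %*% dz)                            # N
  dH <- a %*% t(as.vector(dz))                         # N x fd
  de <- a * (da - sum(a * da))
  dG <- de %*% t(as.vector(params$ww))                 # N x D
  g$ww <- matrix(crossprod(cc$G, de), ncol = 1L)
  dVh <- dG * cc$Uh
  dUh <- dG * cc$Vh
  dpv <- dVh * (1 - cc$Vh^2)
  dpu <- dUh * cc$Uh * (1 - cc$Uh)
  g$Wv <- crossprod(H, dpv); g$bv <- colSums(dpv)
  g$Wu <- crossprod(H, dpu); g$bu <- colSums(dpu)
  dH <- dH + tcrossprod(dpv, params$Wv) + tcrossprod(dpu, params$Wu)
  bb <- backbone_backward(params, cc$bb, dH, arch)
  c(g, bb)
}

# Per-patch classifier head (tissue segmentation network): backbone
# features -> logistic score per instance.
patchnet_forward <- function(params, X, arch, keep = FALSE) {
  bb <- backbone_forward(params, X, arch, keep = keep)
  logit <- as.vector(bb$H %*% params$wc) + params$bc
  list(prob = sigmoid(logit), logit = logit,
       cache = if (keep) list(bb = bb$cache, H = bb$H) else NULL)
}

patchnet_backward <- function(params, fw, y, arch) {
  cc <- fw$cache
  N <- nrow(cc$H)
  dlogit <- (fw$prob - y) / N                          # mean BCE
  g <- list(wc = matrix(crossprod(cc$H, dlogit), ncol = 1L),
            bc = sum(dlogit))
  dH <- dlogit %*% t(as.vector(params$wc))
  bb <- backbone_backward(params, cc$bb, dH, arch)
  c(g, bb)
}

bce_loss <- function(p, y, eps = 1e-7) {
  p <- pmin(1 - eps, pmax(eps, p))
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- Adam optimiser ----------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
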