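# Double-precision pure-R reference implementation of the U-Net forward and
# backward passes, mirroring the documented layer semantics (3x3 same-padding
# convs + ReLU, 2x2 max pool with first-of-equals argmax, 2x2 stride-2
# transposed conv, skip concatenation, 1x1 sigmoid output, combined Dice+BCE
# loss).  Used as the independent oracle for the compiled engine.

ref_im2col <- function(Xl, H, W) {
  Cin <- length(Xl)
  M <- matrix(0, 9 * Cin, H * W)
  for (dc in -1:1) for (dr in -1:1) {
    k <- (dr + 1) + 3 * (dc + 1)
    for (ci in seq_len(Cin)) {
      Xs <- matrix(0, H, W)
      rs <- max(1, 1 - dr):min(H, H - dr)
      cs <- max(1, 1 - dc):min(W, W - dc)
      Xs[rs, cs] <- Xl[[ci]][rs + dr, cs + dc]
      M[k * Cin + ci, ] <- as.vector(Xs)
    }
  }
  M
}

ref_upconv <- function(Xl, W4, b, H, W) {
  Cin <- length(Xl)
  Cout <- length(b)
  out <- lapply(seq_len(Cout), function(co) matrix(b[co], 2 * H, 2 * W))
  for (dj in 0:1) for (di in 0:1) {
    k <- di + 2 * dj
    for (co in seq_len(Cout)) {
      acc <- matrix(0, H, W)
      for (ci in seq_len(Cin))
        acc <- acc + W4[co, k * Cin + ci] * Xl[[ci]]
      rows <- seq(1 + di, 2 * H, 2)
      cols <- seq(1 + dj, 2 * W, 2)
      out[[co]][rows, cols] <- out[[co]][rows, cols] + acc
    }
  }
  out
}

# Forward pass only; returns the probability map for one image.
ref_unet_forward <- function(weights, img, depth, base) {
  S <- nrow(img)
  li <- 1
  getW <- function() { w <- weights[[li]]; li <<- li + 1; w }
  conv <- function(X, W, b, H, Wd) {
    Y <- W %*% ref_im2col(X, H, Wd) + b
    Y[Y < 0] <- 0
    lapply(seq_len(nrow(Y)), function(co) matrix(Y[co, ], H, Wd))
  }
  pool <- function(X, H, W) lapply(X, function(m) {
    out <- matrix(0, H / 2, W / 2)
    for (c2 in seq_len(W / 2)) for (r2 in seq_len(H / 2))
      out[r2, c2] <- max(m[(2 * r2 - 1):(2 * r2), (2 * c2 - 1):(2 * c2)])
    out
  })
  X <- list(img); H <- S; Wd <- S
  skips <- list()
  for (l in seq_len(depth)) {
    W1 <- getW(); b1 <- getW(); X <- conv(X, W1, b1, H, Wd)
    W2 <- getW(); b2 <- getW(); X <- conv(X, W2, b2, H, Wd)
    skips[[l]] <- X
    X <- pool(X, H, Wd); H <- H / 2; Wd <- Wd / 2
  }
  W1 <- getW(); b1 <- getW(); X <- conv(X, W1, b1, H, Wd)
  W2 <- getW(); b2 <- getW(); X <- conv(X, W2, b2, H, Wd)
  for (l in rev(seq_len(depth))) {
    Wu <- getW(); bu <- getW()
    X <- ref_upconv(X, Wu, bu, H, Wd); H <- 2 * H; Wd <- 2 * Wd
    X <- c(skips[[l]], X)
    W1 <- getW(); b1 <- getW(); X <- conv(X, W1, b1, H, Wd)
    W2 <- getW(); b2 <- getW(); X <- conv(X, W2, b2, H, Wd)
  }
  Wo <- getW(); bo <- getW()
  Z <- Reduce(`+`, lapply(seq_along(X), function(ci) Wo[1, ci] * X[[ci]])) + bo
  1 / (1 + exp(-Z))
}

# Forward + backward for one image; returns the full analytic gradient list
# (same layout as the weight list).
ref_unet_gradients <- function(weights, img, lb, depth, base) {
  S <- nrow(img)
  li <- 1
  getW <- function() { w <- weights[[li]]; li <<- li + 1; w }
  conv_f <- function(X, W, b, H, Wd) {
    M <- ref_im2col(X, H, Wd)
    Z <- W %*% M + b
    A <- pmax(Z, 0)
    list(A = lapply(seq_len(nrow(A)), function(co) matrix(A[co, ], H, Wd)),
         M = M, Z = Z, W = W, H = H, Wd = Wd, Cin = length(X))
  }
  caches <- list(); skips <- list(); pools <- list(); ups <- list()
  push <- function(cc) caches[[length(caches) + 1]] <<- cc
  X <- list(img); H <- S; Wd <- S
  for (l in seq_len(depth)) {
    W1 <- getW(); b1 <- getW(); cc <- conv_f(X, W1, b1, H, Wd); push(cc); X <- cc$A
    W2 <- getW(); b2 <- getW(); cc <- conv_f(X, W2, b2, H, Wd); push(cc); X <- cc$A
    skips[[l]] <- X
    H2 <- H / 2; W2d <- Wd / 2
    am <- vector("list", length(X)); Xp <- vector("list", length(X))
    for (ch in seq_along(X)) {
      o <- matrix(0, H2, W2d); a <- matrix(0, H2, W2d)
      for (c2 in seq_len(W2d)) for (r2 in seq_len(H2)) {
        v <- c(X[[ch]][2 * r2 - 1, 2 * c2 - 1], X[[ch]][2 * r2, 2 * c2 - 1],
               X[[ch]][2 * r2 - 1, 2 * c2], X[[ch]][2 * r2, 2 * c2])
        k <- which.max(v) # first of equals, matching the engine
        o[r2, c2] <- v[k]; a[r2, c2] <- k
      }
      Xp[[ch]] <- o; am[[ch]] <- a
    }
    pools[[l]] <- am
    X <- Xp; H <- H2; Wd <- W2d
  }
  W1 <- getW(); b1 <- getW(); cc <- conv_f(X, W1, b1, H, Wd); push(cc); X <- cc$A
  W2 <- getW(); b2 <- getW(); cc <- conv_f(X, W2, b2, H, Wd); push(cc); X <- cc$A
  for (l in rev(seq_len(depth))) {
    Wu <- getW(); bu <- getW()
    ups[[l]] <- list(W = Wu, b = bu, X = X, H = H, Wd = Wd)
    X <- ref_upconv(X, Wu, bu, H, Wd); H <- 2 * H; Wd <- 2 * Wd
    X <- c(skips[[l]], X)
    W1 <- getW(); b1 <- getW(); cc <- conv_f(X, W1, b1, H, Wd); push(cc); X <- cc$A
    W2 <- getW(); b2 <- getW(); cc <- conv_f(X, W2, b2, H, Wd); push(cc); X <- cc$A
  }
  Wo <- getW(); bo <- getW()
  Z <- Reduce(`+`, lapply(seq_along(X), function(ci) Wo[1, ci] * X[[ci]])) + bo
  P <- 1 / (1 + exp(-Z))

  s <- 1e-6; eps <- 1e-7
  y <- lb; p <- P
  sy <- sum(y); sp <- sum(p); syp <- sum(y * p); den <- sy + sp + s
  pc <- pmin(pmax(p, eps), 1 - eps)
  dP <- -(2 * y * den - (2 * syp + s)) / den^2 +
    (-y / pc + (1 - y) / (1 - pc)) / length(p)
  dZ <- dP * P * (1 - P)

  grads <- vector("list", length(weights))
  gW_out <- matrix(0, 1, length(X))
  for (ci in seq_along(X)) gW_out[1, ci] <- sum(dZ * X[[ci]])
  grads[[length(weights) - 1]] <- gW_out
  grads[[length(weights)]] <- sum(dZ)
  dX <- lapply(seq_along(X), function(ci) Wo[1, ci] * dZ)

  conv_b <- function(cc, dA) {
    Cout <- nrow(cc$Z)
    dYm <- matrix(0, Cout, cc$H * cc$Wd)
    for (co in seq_len(Cout)) {
      g <- as.vector(dA[[co]])
      g[cc$Z[co, ] <= 0] <- 0
      dYm[co, ] <- g
    }
    dW <- dYm %*% t(cc$M)
    db <- rowSums(dYm)
    dM <- t(cc$W) %*% dYm
    Cin <- cc$Cin; H <- cc$H; Wd <- cc$Wd
    dXl <- lapply(seq_len(Cin), function(i) matrix(0, H, Wd))
    for (dc in -1:1) for (dr in -1:1) {
      k <- (dr + 1) + 3 * (dc + 1)
      for (ci in seq_len(Cin)) {
        G <- matrix(dM[k * Cin + ci, ], H, Wd)
        rs <- max(1, 1 - dr):min(H, H - dr)
        cs <- max(1, 1 - dc):min(Wd, Wd - dc)
        dXl[[ci]][rs + dr, cs + dc] <- dXl[[ci]][rs + dr, cs + dc] + G[rs, cs]
      }
    }
    list(dW = dW, db = db, dX = dXl)
  }
  widx <- function(layer) c(2 * layer - 1, 2 * layer)
  dSkip <- list()
  for (l in seq_len(depth)) {
    cpos <- 2 * depth + 2 + 2 * (depth - l)
    lpos <- 2 * depth + 2 + 3 * (depth - l) + 1
    r2 <- conv_b(caches[[cpos + 2]], dX)
    grads[[widx(lpos + 2)[1]]] <- r2$dW; grads[[widx(lpos + 2)[2]]] <- r2$db
    r1 <- conv_b(caches[[cpos + 1]], r2$dX)
    grads[[widx(lpos + 1)[1]]] <- r1$dW; grads[[widx(lpos + 1)[2]]] <- r1$db
    Cl <- base * 2^(l - 1)
    dSkip[[l]] <- r1$dX[seq_len(Cl)]
    dU <- r1$dX[(Cl + 1):(2 * Cl)]
    up <- ups[[l]]
    Cin <- length(up$X); Cout <- Cl
    dWu <- matrix(0, Cout, 4 * Cin); dbu <- numeric(Cout)
    dXu <- lapply(seq_len(Cin), function(i) matrix(0, up$H, up$Wd))
    for (co in seq_len(Cout)) dbu[co] <- sum(dU[[co]])
    for (dj in 0:1) for (di in 0:1) {
      k <- di + 2 * dj
      for (co in seq_len(Cout)) {
        dT <- dU[[co]][seq(1 + di, 2 * up$H, 2), seq(1 + dj, 2 * up$Wd, 2)]
        for (ci in seq_len(Cin)) {
          dWu[co, k * Cin + ci] <- dWu[co, k * Cin + ci] + sum(dT * up$X[[ci]])
          dXu[[ci]] <- dXu[[ci]] + up$W[co, k * Cin + ci] * dT
        }
      }
    }
    grads[[widx(lpos)[1]]] <- dWu; grads[[widx(lpos)[2]]] <- dbu
    dX <- dXu
  }
  r2 <- conv_b(caches[[2 * depth + 2]], dX)
  grads[[widx(depth * 2 + 2)[1]]] <- r2$dW; grads[[widx(depth * 2 + 2)[2]]] <- r2$db
  r1 <- conv_b(caches[[2 * depth + 1]], r2$dX)
  grads[[widx(depth * 2 + 1)[1]]] <- r1$dW; grads[[widx(depth * 2 + 1)[2]]] <- r1$db
  dX <- r1$dX
  for (l in rev(seq_len(depth))) {
    Cl <- base * 2^(l - 1)
    H <- S / 2^(l - 1); Wd <- H
    dEnc <- lapply(seq_len(Cl), function(i) matrix(0, H, Wd))
    am <- pools[[l]]
    for (ch in seq_len(Cl)) {
      for (c2 in seq_len(Wd / 2)) for (r2i in seq_len(H / 2)) {
        k <- am[[ch]][r2i, c2]
        rr <- c(2 * r2i - 1, 2 * r2i, 2 * r2i - 1, 2 * r2i)[k]
        ccx <- c(2 * c2 - 1, 2 * c2 - 1, 2 * c2, 2 * c2)[k]
        dEnc[[ch]][rr, ccx] <- dEnc[[ch]][rr, ccx] + dX[[ch]][r2i, c2]
      }
      dEnc[[ch]] <- dEnc[[ch]] + dSkip[[l]][[ch]]
    }
    r2 <- conv_b(caches[[2 * l]], dEnc)
    grads[[widx(2 * l)[1]]] <- r2$dW; grads[[widx(2 * l)[2]]] <- r2$db
    r1 <- conv_b(caches[[2 * l - 1]], r2$dX)
    grads[[widx(2 * l - 1)[1]]] <- r1$dW; grads[[widx(2 * l - 1)[2]]] <- r1$db
    dX <- r1$dX
  }
  grads
}
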