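# Batched forward pass with cached intermediates, and the hand-derived
# backward pass.  Token matrices for a batch of B stacks are stored
# stacked row-wise as a (B*N) x D matrix (image b owns rows
# (b-1)*N + 1 .. b*N); attention is computed per image and head on
# slices of that matrix.  Gradient correctness is pinned against central
# finite differences in the test suite.

lnFwd <- function(X, g, b) {
  mu <- rowMeans(X)
  xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(xc^2) + LN_EPS)
  xhat <- xc * invstd
  list(Y = addBias(xhat * rep(g, each = nrow(X)), b),
       xhat = xhat, invstd = invstd)
}

lnBwd <- function(dY, cache, g) {
  n <- nrow(dY)
  dxhat <- dY * rep(g, each = n)
  dg <- colSums(dY * cache$xhat)
  db <- colSums(dY)
  dX <- cache$invstd *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dX = dX, dg = dg, db = db)
}

geluBwd <- function(dY, x) dY * (stats::pnorm(x) + x * stats::dnorm(x))

dropoutFwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(Y = X, mask = NULL))
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(X)), nrow(X), ncol(X)) < keep) / keep
  list(Y = X * mask, mask = mask)
}

dropoutBwd <- function(dY, mask) if (is.null(mask)) dY else dY * mask

attnScale <- function(config) {
  dHead <- config@embedDim %/% config@nHeads
  if (config@scaleConvention == "paper") sqrt(dHead / config@nHeads)
  else sqrt(dHead)
}

# Forward pass over a list of patch matrices.  In train mode dropout
# masks are drawn from the current RNG stream and cached.
vitForwardBatch <- function(model, patchList, train = FALSE) {
  cfg <- model@config; par <- model@params
  B <- length(patchList)
  N <- nPatches(cfg); D <- cfg@embedDim
  h <- cfg@nHeads; dHead <- D %/% h
  scl <- attnScale(cfg)

  Xp <- do.call(rbind, patchList)
  pos <- positionsOf(model)
  X <- addBias(Xp %*% par$embed_W, par$embed_b) + pos[rep(seq_len(N), B), ]

  blocks <- vector("list", cfg@nBlocks)
  for (l in seq_len(cfg@nBlocks)) {
    p <- blockParamList(par, l)
    cacheB <- list(Xin = X)
    ln1 <- lnFwd(X, p$ln1_g, p$ln1_b)
    Q <- addBias(ln1$Y %*% p$Wq, p$bq)
    K <- addBias(ln1$Y %*% p$Wk, p$bk)
    V <- addBias(ln1$Y %*% p$Wv, p$bv)
    A <- array(0, c(N, N, h, B))
    Amask <- if (train && cfg@encoderDropout > 0) array(0, c(N, N, h, B))
    Z <- matrix(0, B * N, D)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * N + 1L):(b * N)
      for (i in seq_len(h)) {
        ci <- ((i - 1L) * dHead + 1L):(i * dHead)
        Ab <- rowSoftmax(Q[rb, ci, drop = FALSE] %*%
                           t(K[rb, ci, drop = FALSE]) / scl)
        A[, , i, b] <- Ab
        if (!is.null(Amask)) {
          dp <- dropoutFwd(Ab, cfg@encoderDropout, TRUE)
          Amask[, , i, b] <- dp$mask
          Ab <- dp$Y
        }
        Z[rb, ci] <- Ab %*% V[rb, ci, drop = FALSE]
      }
    }
    attnOut <- addBias(Z %*% p$Wo, p$bo)
    U <- X + attnOut
    ln2 <- lnFwd(U, p$ln2_g, p$ln2_b)
    H <- ln2$Y
    mlp <- list()
    for (j in seq_along(cfg@encoderMlpUnits)) {
      lin <- addBias(H %*% p[[paste0("mlpW", j)]], p[[paste0("mlpb", j)]])
      act <- gelu(lin)
      dp <- dropoutFwd(act, cfg@encoderDropout, train)
      mlp[[j]] <- list(Hin = H, lin = lin, mask = dp$mask)
      H <- dp$Y
    }
    blocks[[l]] <- c(cacheB, list(ln1 = ln1, Q = Q, K = K, V = V, A = A,
                                  Amask = Amask, Z = Z, U = U, ln2 = ln2,
                                  mlp = mlp))
    X <- U + H
  }

  fln <- lnFwd(X, par$final_ln_g, par$final_ln_b)
  Ftok <- matrix(0, B, N * D)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * N + 1L):(b * N)
    Ftok[b, ] <- as.vector(t(fln$Y[rb, , drop = FALSE]))
  }
  dp0 <- dropoutFwd(Ftok, cfg@headDropout, train)
  H <- dp0$Y
  nHidden <- length(cfg@headMlpUnits)
  head <- list()
  for (j in seq_len(nHidden)) {
    lin <- addBias(H %*% par[[paste0("head_W", j)]], par[[paste0("head_b", j)]])
    act <- gelu(lin)
    dp <- dropoutFwd(act, cfg@headDropout, train)
    head[[j]] <- list(Hin = H, lin = lin, mask = dp$mask)
    H <- dp$Y
  }
  jOut <- nHidden + 1L
  out <- addBias(H %*% par[[paste0("head_W", jOut)]],
                 par[[paste0("head_b", jOut)]])
  head[[jOut]] <- list(Hin = H)

  list(out = out, Xp = Xp, blocks = blocks, fln = fln, flnX = X,
       Ftok = Ftok, headDrop0 = dp0$mask, head = head, B = B)
}

# Backward pass: dOut is the (B x 4) gradient of the scalar loss with
# respect to the raw head outputs.  Returns a gradient list parallel to
# the parameter list.
vitBackwardBatch <- function(model, cache, dOut) {
  cfg <- model@config; par <- model@params
  B <- cache$B
  N <- nPatches(cfg); D <- cfg@embedDim
  h <- cfg@nHeads; dHead <- D %/% h
  scl <- attnScale(cfg)
  g <- list()

  # regression head
  nHidden <- length(cfg@headMlpUnits)
  jOut <- nHidden + 1L
  dH <- dOut
  for (j in rev(seq_len(jOut))) {
    wNm <- paste0("head_W", j); bNm <- paste0("head_b", j)
    hc <- cache$head[[j]]
    dLin <- if (j == jOut) dH else geluBwd(dropoutBwd(dH, hc$mask), hc$lin)
    g[[wNm]] <- t(hc$Hin) %*% dLin
    g[[bNm]] <- colSums(dLin)
    dH <- dLin %*% t(par[[wNm]])
  }
  dF <- dropoutBwd(dH, cache$headDrop0)

  # un-flatten: row b of F is the token-major flattening of image b
  dX <- matrix(0, B * N, D)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * N + 1L):(b * N)
    dX[rb, ] <- t(matrix(dF[b, ], D, N))
  }
  fb <- lnBwd(dX, cache$fln, par$final_ln_g)
  g$final_ln_g <- fb$dg; g$final_ln_b <- fb$db
  dX <- fb$dX

  for (l in rev(seq_len(cfg@nBlocks))) {
    p <- blockParamList(par, l)
    ck <- cache$blocks[[l]]
    pre <- function(nm) paste0("blk", l, "_", nm)

    # X_out = U + MLP-chain(H0);  H0 = LN2(U)
    dU <- dX
    dH <- dX
    for (j in rev(seq_along(cfg@encoderMlpUnits))) {
      mc <- ck$mlp[[j]]
      dLin <- geluBwd(dropoutBwd(dH, mc$mask), mc$lin)
      g[[pre(paste0("mlpW", j))]] <- t(mc$Hin) %*% dLin
      g[[pre(paste0("mlpb", j))]] <- colSums(dLin)
      dH <- dLin %*% t(p[[paste0("mlpW", j)]])
    }
    l2 <- lnBwd(dH, ck$ln2, p$ln2_g)
    g[[pre("ln2_g")]] <- l2$dg; g[[pre("ln2_b")]] <- l2$db
    dU <- dU + l2$dX

    # U = Xin + Z Wo + bo
    dAttnOut <- dU
    g[[pre("Wo")]] <- t(ck$Z) %*% dAttnOut
    g[[pre("bo")]] <- colSums(dAttnOut)
    dZ <- dAttnOut %*% t(p$Wo)

    dQ <- matrix(0, B * N, D); dK <- matrix(0, B * N, D)
    dV <- matrix(0, B * N, D)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * N + 1L):(b * N)
      for (i in seq_len(h)) {
        ci <- ((i - 1L) * dHead + 1L):(i * dHead)
        Ab <- ck$A[, , i, b]
        mask <- if (!is.null(ck$Amask)) ck$Amask[, , i, b]
        Ad <- if (is.null(mask)) Ab else Ab * mask
        dZh <- dZ[rb, ci, drop = FALSE]
        Vh <- ck$V[rb, ci, drop = FALSE]
        dAd <- dZh %*% t(Vh)
        dV[rb, ci] <- t(Ad) %*% dZh
        dA <- if (is.null(mask)) dAd else dAd * mask
        dS <- Ab * (dA - rowSums(dA * Ab))
        dQ[rb, ci] <- dS %*% ck$K[rb, ci, drop = FALSE] / scl
        dK[rb, ci] <- t(dS) %*% ck$Q[rb, ci, drop = FALSE] / scl
      }
    }
    Xln <- ck$ln1$Y
    g[[pre("Wq")]] <- t(Xln) %*% dQ; g[[pre("bq")]] <- colSums(dQ)
    g[[pre("Wk")]] <- t(Xln) %*% dK; g[[pre("bk")]] <- colSums(dK)
    g[[pre("Wv")]] <- t(Xln) %*% dV; g[[pre("bv")]] <- colSums(dV)
    dXln <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    l1 <- lnBwd(dXln, ck$ln1, p$ln1_g)
    g[[pre("ln1_g")]] <- l1$dg; g[[pre("ln1_b")]] <- l1$db
    dX <- dU + l1$dX
  }

  g$embed_W <- t(cache$Xp) %*% dX
  g$embed_b <- colSums(dX)
  if (cfg@positional == "learned")
    g$pos <- rowsum(dX, group = rep(seq_len(N), B), reorder = TRUE)
  g[names(par)]
}
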