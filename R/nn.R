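## Internal numerical core of the two-branch CNN + BLSTM classifier:
## batched forward pass, exact analytic backpropagation and the Adam
## optimiser, in plain vectorised R.  Layouts:
##   - one-hot batches are B x (4 L) matrices, position-major blocks of 4
##     rows (A, T, C, G) per nucleotide;
##   - convolution kernels are K x (4 kernel_len) in the same layout;
##   - intermediate tensors are (B, channels, positions) arrays;
##   - the flattened BLSTM output is position-major: column
##     (t - 1) * 2U + f for feature f at position t.
## Gradients are verified against finite differences in the test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

## numerically stable binary cross-entropy from the pre-sigmoid logit
.bce_from_logit <- function(z, y) {
    mean(pmax(z, 0) - y * z + log1p(exp(-abs(z))))
}

.glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
}

## recurrent weights: one orthogonal U x U block per gate
.orthogonal_recurrent <- function(U) {
    blocks <- lapply(1:4, function(i)
        qr.Q(qr(matrix(rnorm(U * U), U, U))))
    do.call(cbind, blocks)
}

## L1 penalty and subgradient, averaged over each penalized matrix so the
## printed weight applies commensurately to layers of very different size.
.l1_terms <- function(params, cfg) {
    mats <- c("conv_m_W", "conv_s_W", "dense_W")
    sum(vapply(mats, function(nm) mean(abs(params[[nm]])), numeric(1))) *
        cfg@l1_penalty
}
.l1_grad <- function(W, cfg) cfg@l1_penalty * sign(W) / length(W)

## Parameter initialisation (seeded by the caller).
nn_init_params <- function(cfg) {
    K <- cfg@n_kernels; kl <- cfg@kernel_len
    U <- cfg@lstm_units; D <- cfg@dense_units
    flat <- nn_shapes(cfg)$flatten
    p <- list(
        conv_m_W = .glorot(K, 4L * kl), conv_m_b = numeric(K),
        conv_s_W = .glorot(K, 4L * kl), conv_s_b = numeric(K),
        lstm_f_Wx = .glorot(K, 4L * U),
        lstm_f_Wh = .orthogonal_recurrent(U),
        lstm_f_b = rep(c(0, 1, 0, 0), each = U),   # forget bias 1
        lstm_b_Wx = .glorot(K, 4L * U),
        lstm_b_Wh = .orthogonal_recurrent(U),
        lstm_b_b = rep(c(0, 1, 0, 0), each = U),
        dense_W = .glorot(flat, D), dense_b = numeric(D),
        out_W = .glorot(D, 1L), out_b = 0)
    if (cfg@batchnorm_after_conv) {
        p$bn_m_gamma <- rep(1, K); p$bn_m_beta <- numeric(K)
        p$bn_s_gamma <- rep(1, K); p$bn_s_beta <- numeric(K)
    }
    p
}

## Deterministic shape chain for a configuration.
nn_shapes <- function(cfg) {
    conv_m <- cfg@mirna_len - cfg@kernel_len + 1L
    conv_s <- cfg@site_len - cfg@kernel_len + 1L
    pool_m <- conv_m - cfg@pool_size + 1L
    pool_s <- conv_s - cfg@pool_size + 1L
    merged <- pool_m + pool_s
    list(conv_mirna = c(cfg@n_kernels, conv_m),
         conv_site = c(cfg@n_kernels, conv_s),
         pool_mirna = c(cfg@n_kernels, pool_m),
         pool_site = c(cfg@n_kernels, pool_s),
         merged = c(cfg@n_kernels, merged),
         blstm = c(2L * cfg@lstm_units, merged),
         flatten = 2L * cfg@lstm_units * merged)
}

## ---- layer primitives -----------------------------------------------------

## X: B x (4 L); W: K x (4 kl).  Returns (B, K, T) pre-activations.
.conv_forward <- function(X, W, b, kl) {
    B <- nrow(X); K <- nrow(W)
    L <- ncol(X) %/% 4L
    T_ <- L - kl + 1L
    Z <- array(0, c(B, K, T_))
    Wt <- t(W)
    for (t in seq_len(T_)) {
        cols <- ((t - 1L) * 4L + 1L):((t - 1L) * 4L + 4L * kl)
        Z[, , t] <- X[, cols, drop = FALSE] %*% Wt +
            rep(b, each = B)
    }
    Z
}

## dZ: (B, K, T).  Returns list(dW, db).
.conv_backward <- function(X, dZ, kl, K) {
    B <- nrow(X)
    T_ <- dim(dZ)[3]
    dW <- matrix(0, K, 4L * kl); db <- numeric(K)
    for (t in seq_len(T_)) {
        cols <- ((t - 1L) * 4L + 1L):((t - 1L) * 4L + 4L * kl)
        dZt <- dZ[, , t, drop = FALSE]; dim(dZt) <- c(B, K)
        dW <- dW + t(dZt) %*% X[, cols, drop = FALSE]
        db <- db + colSums(dZt)
    }
    list(dW = dW, db = db)
}

## Batch normalisation over batch x positions, per channel.
.bn_forward <- function(Z, gamma, beta, eps = 1e-5) {
    d <- dim(Z); B <- d[1]; K <- d[2]; T_ <- d[3]
    mu <- apply(Z, 2, mean)
    v <- apply(Z, 2, function(x) mean((x - mean(x))^2))
    sd_ <- sqrt(v + eps)
    Zhat <- sweep(sweep(Z, 2, mu, "-"), 2, sd_, "/")
    out <- sweep(sweep(Zhat, 2, gamma, "*"), 2, beta, "+")
    list(out = out, Zhat = Zhat, mu = mu, sd = sd_)
}

.bn_backward <- function(cache, dOut, gamma) {
    d <- dim(dOut); N <- d[1] * d[3]
    Zhat <- cache$Zhat
    dgamma <- apply(dOut * Zhat, 2, sum)
    dbeta <- apply(dOut, 2, sum)
    dZhat <- sweep(dOut, 2, gamma, "*")
    s1 <- apply(dZhat, 2, sum)
    s2 <- apply(dZhat * Zhat, 2, sum)
    dZ <- sweep(dZhat -
                sweep(array(rep(1, prod(d)), d), 2, s1 / N, "*") -
                sweep(Zhat, 2, s2 / N, "*"),
                2, cache$sd, "/")
    list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

## BN inference using running statistics.
.bn_infer <- function(Z, gamma, beta, r_mu, r_var, eps = 1e-5) {
    Zhat <- sweep(sweep(Z, 2, r_mu, "-"), 2, sqrt(r_var + eps), "/")
    sweep(sweep(Zhat, 2, gamma, "*"), 2, beta, "+")
}

## Max pooling (window ps, stride 1) with first-winner tie-break.
.pool_forward <- function(A, ps) {
    d <- dim(A); B <- d[1]; K <- d[2]; T_ <- d[3]
    Tp <- T_ - ps + 1L
    P <- array(-Inf, c(B, K, Tp))
    for (j in seq_len(ps))
        P <- pmax(P, A[, , j:(j + Tp - 1L), drop = FALSE])
    winner <- array(0L, c(B, K, Tp))
    for (j in ps:1) {
        eq <- A[, , j:(j + Tp - 1L), drop = FALSE] == P
        winner[eq] <- j
    }
    list(P = P, winner = winner)
}

.pool_backward <- function(cache, dP, ps, T_) {
    d <- dim(dP); B <- d[1]; K <- d[2]; Tp <- d[3]
    dA <- array(0, c(B, K, T_))
    for (j in seq_len(ps)) {
        sel <- (cache$winner == j) * dP
        dA[, , j:(j + Tp - 1L)] <- dA[, , j:(j + Tp - 1L), drop = FALSE] + sel
    }
    dA
}

## One LSTM direction over a (B, K, T) input; steps taken in `ord`.
.lstm_forward <- function(M, Wx, Wh, b, ord) {
    d <- dim(M); B <- d[1]; K <- d[2]
    U <- ncol(Wh) %/% 4L
    T_ <- length(ord)
    H <- array(0, c(B, U, T_))     # indexed by original position
    cache <- vector("list", T_)
    h <- matrix(0, B, U); cc <- matrix(0, B, U)
    for (k in seq_len(T_)) {
        t <- ord[k]
        x <- M[, , t, drop = FALSE]; dim(x) <- c(B, K)
        z <- x %*% Wx + h %*% Wh + rep(b, each = B)
        i <- .sigmoid(z[, 1:U, drop = FALSE])
        f <- .sigmoid(z[, (U + 1):(2 * U), drop = FALSE])
        o <- .sigmoid(z[, (2 * U + 1):(3 * U), drop = FALSE])
        g <- tanh(z[, (3 * U + 1):(4 * U), drop = FALSE])
        c_prev <- cc
        cc <- f * c_prev + i * g
        tc <- tanh(cc)
        h_prev <- h
        h <- o * tc
        H[, , t] <- h
        cache[[k]] <- list(x = x, i = i, f = f, o = o, g = g,
                           c = cc, c_prev = c_prev, tc = tc,
                           h_prev = h_prev)
    }
    list(H = H, cache = cache)
}

## dH indexed by original position; returns input grad and param grads.
.lstm_backward <- function(fw, dH, Wx, Wh, ord) {
    B <- dim(dH)[1]; U <- dim(dH)[2]; T_ <- length(ord)
    K <- nrow(Wx)
    dM <- array(0, c(B, K, T_))
    dWx <- matrix(0, nrow(Wx), ncol(Wx))
    dWh <- matrix(0, nrow(Wh), ncol(Wh))
    db <- numeric(ncol(Wx))
    dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
    for (k in T_:1) {
        t <- ord[k]
        cc <- fw$cache[[k]]
        dh <- dH[, , t, drop = FALSE]; dim(dh) <- c(B, U)
        dh <- dh + dh_next
        do_ <- dh * cc$tc
        dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
        di <- dc * cc$g
        dg <- dc * cc$i
        df <- dc * cc$c_prev
        dz <- cbind(di * cc$i * (1 - cc$i),
                    df * cc$f * (1 - cc$f),
                    do_ * cc$o * (1 - cc$o),
                    dg * (1 - cc$g^2))
        dWx <- dWx + t(cc$x) %*% dz
        dWh <- dWh + t(cc$h_prev) %*% dz
        db <- db + colSums(dz)
        dM[, , t] <- dz %*% t(Wx)
        dh_next <- dz %*% t(Wh)
        dc_next <- dc * cc$f
    }
    list(dM = dM, dWx = dWx, dWh = dWh, db = db)
}

## Inverted-dropout mask (or 1 when rate is 0 / inference).
.drop_mask <- function(dims, rate, training) {
    if (!training || rate <= 0) return(1)
    array((runif(prod(dims)) >= rate) / (1 - rate), dims)
}

## ---- full network ---------------------------------------------------------

## Forward pass.  Xm: B x (4 mirna_len); Xs: B x (4 site_len).
## Returns list(p = probabilities, z = logits, cache = everything the
## backward pass needs).  Dropout masks are drawn from the current RNG
## when training = TRUE.
nn_forward <- function(params, cfg, Xm, Xs, training = FALSE,
                       keep_cache = training) {
    B <- nrow(Xm)
    K <- cfg@n_kernels; kl <- cfg@kernel_len; ps <- cfg@pool_size
    U <- cfg@lstm_units
    Zm <- .conv_forward(Xm, params$conv_m_W, params$conv_m_b, kl)
    Zs <- .conv_forward(Xs, params$conv_s_W, params$conv_s_b, kl)
    bn_m <- bn_s <- NULL
    if (cfg@batchnorm_after_conv) {
        if (training) {
            bn_m <- .bn_forward(Zm, params$bn_m_gamma, params$bn_m_beta)
            bn_s <- .bn_forward(Zs, params$bn_s_gamma, params$bn_s_beta)
            Zm_a <- bn_m$out; Zs_a <- bn_s$out
        } else {
            Zm_a <- .bn_infer(Zm, params$bn_m_gamma, params$bn_m_beta,
                              params$bn_m_rmu, params$bn_m_rvar)
            Zs_a <- .bn_infer(Zs, params$bn_s_gamma, params$bn_s_beta,
                              params$bn_s_rmu, params$bn_s_rvar)
        }
    } else {
        Zm_a <- Zm; Zs_a <- Zs
    }
    Am <- pmax(Zm_a, 0); As <- pmax(Zs_a, 0)
    pm <- .pool_forward(Am, ps); psite <- .pool_forward(As, ps)
    Tm <- dim(pm$P)[3]; Ts <- dim(psite$P)[3]
    T_ <- Tm + Ts
    M <- array(0, c(B, K, T_))
    M[, , seq_len(Tm)] <- pm$P
    M[, , Tm + seq_len(Ts)] <- psite$P
    mask_merge <- .drop_mask(dim(M), cfg@dropout_merge, training)
    Md <- M * mask_merge
    ord_f <- seq_len(T_); ord_b <- rev(ord_f)
    lf <- .lstm_forward(Md, params$lstm_f_Wx, params$lstm_f_Wh,
                        params$lstm_f_b, ord_f)
    lb <- .lstm_forward(Md, params$lstm_b_Wx, params$lstm_b_Wh,
                        params$lstm_b_b, ord_b)
    O <- array(0, c(B, 2L * U, T_))
    O[, seq_len(U), ] <- lf$H
    O[, U + seq_len(U), ] <- lb$H
    mask_lstm <- .drop_mask(dim(O), cfg@dropout_lstm, training)
    Od <- O * mask_lstm
    Fl <- Od; dim(Fl) <- c(B, 2L * U * T_)
    Zd <- Fl %*% params$dense_W + rep(params$dense_b, each = B)
    Ad <- pmax(Zd, 0)
    mask_dense <- .drop_mask(dim(Ad), cfg@dropout_dense, training)
    Add <- Ad * mask_dense
    z <- drop(Add %*% params$out_W) + params$out_b
    p <- .sigmoid(z)
    cache <- NULL
    if (keep_cache)
        cache <- list(Xm = Xm, Xs = Xs, Zm = Zm, Zs = Zs,
                      bn_m = bn_m, bn_s = bn_s, Zm_a = Zm_a, Zs_a = Zs_a,
                      pm = pm, ps_ = psite, Tm = Tm, Ts = Ts,
                      mask_merge = mask_merge, Md = Md,
                      lf = lf, lb = lb, ord_f = ord_f, ord_b = ord_b,
                      mask_lstm = mask_lstm, Fl = Fl, Zd = Zd,
                      mask_dense = mask_dense, Add = Add)
    list(p = p, z = z, cache = cache)
}

## Backward pass from logits; returns gradients named like the params.
## Includes the L1 subgradient on convolution kernels and the dense
## weight matrix.
nn_backward <- function(params, cfg, fw, y) {
    cache <- fw$cache
    B <- nrow(cache$Xm)
    K <- cfg@n_kernels; kl <- cfg@kernel_len; ps <- cfg@pool_size
    U <- cfg@lstm_units
    Tm <- cache$Tm; Ts <- cache$Ts; T_ <- Tm + Ts
    dz <- (fw$p - y) / B
    g <- list()
    g$out_W <- t(cache$Add) %*% matrix(dz, ncol = 1)
    g$out_b <- sum(dz)
    dAdd <- matrix(dz, ncol = 1) %*% t(params$out_W)
    dAd <- dAdd * cache$mask_dense
    dZd <- dAd * (cache$Zd > 0)
    g$dense_W <- t(cache$Fl) %*% dZd
    g$dense_b <- colSums(dZd)
    dFl <- dZd %*% t(params$dense_W)
    dOd <- dFl; dim(dOd) <- c(B, 2L * U, T_)
    dO <- dOd * cache$mask_lstm
    dHf <- dO[, seq_len(U), , drop = FALSE]
    dHb <- dO[, U + seq_len(U), , drop = FALSE]
    bf <- .lstm_backward(cache$lf, dHf, params$lstm_f_Wx,
                         params$lstm_f_Wh, cache$ord_f)
    bb <- .lstm_backward(cache$lb, dHb, params$lstm_b_Wx,
                         params$lstm_b_Wh, cache$ord_b)
    g$lstm_f_Wx <- bf$dWx; g$lstm_f_Wh <- bf$dWh; g$lstm_f_b <- bf$db
    g$lstm_b_Wx <- bb$dWx; g$lstm_b_Wh <- bb$dWh; g$lstm_b_b <- bb$db
    dMd <- bf$dM + bb$dM
    dM <- dMd * cache$mask_merge
    dPm <- dM[, , seq_len(Tm), drop = FALSE]
    dPs <- dM[, , Tm + seq_len(Ts), drop = FALSE]
    dAm <- .pool_backward(cache$pm, dPm, ps, dim(cache$Zm)[3])
    dAs <- .pool_backward(cache$ps_, dPs, ps, dim(cache$Zs)[3])
    dZm_a <- dAm * (cache$Zm_a > 0)
    dZs_a <- dAs * (cache$Zs_a > 0)
    if (cfg@batchnorm_after_conv) {
        bm <- .bn_backward(cache$bn_m, dZm_a, params$bn_m_gamma)
        bs <- .bn_backward(cache$bn_s, dZs_a, params$bn_s_gamma)
        g$bn_m_gamma <- bm$dgamma; g$bn_m_beta <- bm$dbeta
        g$bn_s_gamma <- bs$dgamma; g$bn_s_beta <- bs$dbeta
        dZm <- bm$dZ; dZs <- bs$dZ
    } else {
        dZm <- dZm_a; dZs <- dZs_a
    }
    cm <- .conv_backward(cache$Xm, dZm, kl, K)
    cs <- .conv_backward(cache$Xs, dZs, kl, K)
    g$conv_m_W <- cm$dW + .l1_grad(params$conv_m_W, cfg)
    g$conv_m_b <- cm$db
    g$conv_s_W <- cs$dW + .l1_grad(params$conv_s_W, cfg)
    g$conv_s_b <- cs$db
    g$dense_W <- g$dense_W + .l1_grad(params$dense_W, cfg)
    g
}

## Total loss (data BCE + L1 penalty) for monitoring / gradient checks.
nn_loss <- function(params, cfg, z, y) {
    .bce_from_logit(z, y) + .l1_terms(params, cfg)
}

## ---- Adam -----------------------------------------------------------------

nn_adam_init <- function(params) {
    list(m = lapply(params, function(p) p * 0),
         v = lapply(params, function(p) p * 0),
         t = 0L)
}

nn_adam_step <- function(params, grads, state, lr,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
    state$t <- state$t + 1L
    b1t <- 1 - beta1^state$t
    b2t <- 1 - beta2^state$t
    for (nm in names(grads)) {
        gmat <- grads[[nm]]
        state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
        state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
        mhat <- state$m[[nm]] / b1t
        vhat <- state$v[[nm]] / b2t
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(params = params, state = state)
}
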