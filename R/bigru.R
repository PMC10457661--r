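# Bidirectional GRU over token-embedding sequences. Minibatches are laid out
# time-major: block t of a flat (m*B) x d matrix holds rows
# (t-1)*B + 1 .. t*B, i.e. position t of every molecule. A {0,1} mask marks
# valid positions; at padded positions the hidden state is carried through
# unchanged, so arbitrary-length molecules batch together. The hidden state
# of position t is the concatenation of the forward recurrence state at t
# and the backward recurrence state at t (d2 = 2 * hidden size).
#
# Gate equations (per direction, hidden size h):
#   r_t = sigmoid(x_t Wr + h_{t-1} Ur + br)
#   u_t = sigmoid(x_t Wu + h_{t-1} Uu + bu)          (update gate)
#   n_t = tanh(x_t Wn + bn + r_t * (h_{t-1} Un + bhn))
#   h_t = (1 - u_t) * n_t + u_t * h_{t-1}
#
# The three input projections are fused into a single matmul over all
# positions at once and the per-gate weight gradients accumulate into one
# crossprod over stacked pre-activations; only the recurrent product stays
# inside the time loop.

gru_dir_init <- function(d_in, d_h) {
  list(Wr = glorot(d_in, d_h), Wu = glorot(d_in, d_h), Wn = glorot(d_in, d_h),
       Ur = glorot(d_h, d_h), Uu = glorot(d_h, d_h), Un = glorot(d_h, d_h),
       br = rep(0, d_h), bu = rep(0, d_h), bn = rep(0, d_h),
       bhn = rep(0, d_h))
}

bigru_init <- function(d_in, d_h) {
  list(fwd = gru_dir_init(d_in, d_h), bwd = gru_dir_init(d_in, d_h))
}

# one direction. Xbig: (m*B) x d_in flat time-major input; mask: B x m.
gru_dir_fwd <- function(Xbig, mask, p, B, m) {
  d_h <- ncol(p$Ur)
  U_all <- cbind(p$Ur, p$Uu, p$Un)
  XP <- Xbig %*% cbind(p$Wr, p$Wu, p$Wn) +
    rep(c(p$br, p$bu, p$bn), each = nrow(Xbig))
  h <- matrix(0, B, d_h)
  i12 <- seq_len(2L * d_h); i3 <- 2L * d_h + seq_len(d_h)
  i1 <- seq_len(d_h); i2 <- d_h + i1
  H <- vector("list", m); Hprev <- vector("list", m)
  R <- vector("list", m); U <- vector("list", m)
  N <- vector("list", m); HU <- vector("list", m)
  bhn_rep <- rep(p$bhn, each = B)
  for (t in seq_len(m)) {
    rows <- (t - 1L) * B + seq_len(B)
    HUt <- h %*% U_all
    ru <- sigmoid(XP[rows, i12, drop = FALSE] + HUt[, i12, drop = FALSE])
    r <- ru[, i1, drop = FALSE]
    u <- ru[, i2, drop = FALSE]
    hu <- HUt[, i3, drop = FALSE] + bhn_rep
    n <- tanh(XP[rows, i3, drop = FALSE] + r * hu)
    h_new <- (1 - u) * n + u * h
    mk <- mask[, t]
    Hprev[[t]] <- h
    h <- if (all(mk == 1)) h_new else mk * h_new + (1 - mk) * h
    H[[t]] <- h
    R[[t]] <- r; U[[t]] <- u; N[[t]] <- n; HU[[t]] <- hu
  }
  list(H = H,
       cache = list(Xbig = Xbig, Hprev = Hprev, R = R, U = U, N = N,
                    HU = HU, mask = mask, B = B, m = m))
}

# backward through one direction; dH: (m*B) x d_h gradient of the output
# state at every position. Token embeddings are frozen inputs, so dX is not
# produced.
gru_dir_bwd <- function(cache, dH, p) {
  B <- cache$B; m <- cache$m
  d_h <- ncol(p$Ur)
  U_all_t <- t(cbind(p$Ur, p$Uu, p$Un))
  Dpre <- vector("list", m)
  dh_next <- matrix(0, B, d_h)
  dbhn <- rep(0, d_h)
  for (t in rev(seq_len(m))) {
    rows <- (t - 1L) * B + seq_len(B)
    r <- cache$R[[t]]; u <- cache$U[[t]]; n <- cache$N[[t]]
    hu <- cache$HU[[t]]; h_prev <- cache$Hprev[[t]]
    mk <- cache$mask[, t]
    dh <- dH[rows, , drop = FALSE] + dh_next
    if (all(mk == 1)) {
      dh_upd <- dh
      dh_carry <- 0
    } else {
      dh_upd <- dh * mk
      dh_carry <- dh * (1 - mk)
    }
    du <- dh_upd * (h_prev - n)
    dn_pre <- dh_upd * (1 - u) * (1 - n^2)
    dhu <- dn_pre * r
    dr_pre <- dn_pre * hu * r * (1 - r)
    du_pre <- du * u * (1 - u)
    dbhn <- dbhn + colSums(dhu)
    D3 <- cbind(dr_pre, du_pre, dhu)
    Dpre[[t]] <- cbind(dr_pre, du_pre, dn_pre)
    # recurrent gradient: through Ur/Uu and through Un inside the n gate
    dh_next <- dh_upd * u + dh_carry + D3 %*% U_all_t
  }
  Dbig <- do.call(rbind, Dpre)
  Hprev_big <- do.call(rbind, cache$Hprev)
  i1 <- seq_len(d_h); i2 <- d_h + i1; i3 <- 2L * d_h + i1
  gW <- crossprod(cache$Xbig, Dbig)
  Rbig <- do.call(rbind, cache$R)
  # Un's input gradient is dhu = dn_pre * r
  gU <- crossprod(Hprev_big,
                  cbind(Dbig[, i1, drop = FALSE], Dbig[, i2, drop = FALSE],
                        Dbig[, i3, drop = FALSE] * Rbig))
  gb <- colSums(Dbig)
  list(Wr = gW[, i1], Wu = gW[, i2], Wn = gW[, i3],
       Ur = gU[, i1], Uu = gU[, i2], Un = gU[, i3],
       br = gb[i1], bu = gb[i2], bn = gb[i3], bhn = dbhn)
}

# row permutation that reverses each molecule's valid prefix in the flat
# time-major layout (an involution)
reverse_perm <- function(lengths, B, m) {
  rp <- seq_len(m * B)
  for (i in seq_len(B)) {
    li <- lengths[i]
    if (li > 1L) {
      pos <- (seq_len(li) - 1L) * B + i
      rp[pos] <- rev(pos)
    }
  }
  rp
}

# full bidirectional pass: Hbig is (m*B) x 2h
bigru_fwd <- function(Xbig, mask, params, B, m) {
  lengths <- as.integer(rowSums(mask))
  f <- gru_dir_fwd(Xbig, mask, params$fwd, B, m)
  rp <- reverse_perm(lengths, B, m)
  b <- gru_dir_fwd(Xbig[rp, , drop = FALSE], mask, params$bwd, B, m)
  Hb <- do.call(rbind, b$H)
  H <- cbind(do.call(rbind, f$H), Hb[rp, , drop = FALSE])
  list(H = H, cache = list(f = f$cache, b = b$cache, rp = rp, B = B, m = m))
}

bigru_bwd <- function(cache, dH, params) {
  d_h <- ncol(params$fwd$Ur)
  gf <- gru_dir_bwd(cache$f, dH[, seq_len(d_h), drop = FALSE], params$fwd)
  dHb <- dH[, d_h + seq_len(d_h), drop = FALSE][cache$rp, , drop = FALSE]
  gb <- gru_dir_bwd(cache$b, dHb, params$bwd)
  list(fwd = gf, bwd = gb)
}

#' Encode one token-embedding matrix with a bidirectional GRU
#'
#' Runs a forward and a backward GRU recurrence over the rows of `Z` and
#' concatenates their states per position, giving a hidden matrix of width
#' twice the per-direction hidden size (200 under the package defaults).
#'
#' @param Z Numeric matrix, one row per token (m x d1).
#' @param params BiGRU parameter list as created inside [cmms_fit()]; for
#'   standalone use create one with `cmms:::bigru_init(d1, d2/2)`.
#' @return Numeric matrix m x d2 of per-token hidden states.
#' @export
bigru_encode <- function(Z, params) {
  Z <- as.matrix(Z)
  if (nrow(params$fwd$Wr) != ncol(Z)) {
    stop(sprintf("embedding width %d does not match GRU input width %d",
                 ncol(Z), nrow(params$fwd$Wr)), call. = FALSE)
  }
  m <- nrow(Z)
  bigru_fwd(Z, matrix(1, 1, m), params, B = 1L, m = m)$H
}
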