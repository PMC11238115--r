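# Analytic backpropagation through the encoder and the variant losses, plus
# the Adam optimizer. Gradients mirror the forward pass in encoder.R; every
# formula here is checked against finite differences in the test suite.

.encoder_backward <- function(params, config, fwd, dHout) {
  H <- config$hidden; heads <- config$heads; dh <- H %/% heads
  cache <- fwd$cache
  cm <- cache$cm; M <- cm$M; n <- cm$n
  scale <- 1 / sqrt(dh)
  g <- list()
  add <- function(nm, val) {
    g[[nm]] <<- if (is.null(g[[nm]])) val else g[[nm]] + val
  }
  # final projection
  add("W_fc", crossprod(cache$Xlast, dHout))
  add("b_fc", colSums(dHout))
  dX <- dHout %*% t(params$W_fc)
  dC <- matrix(0, M, M)
  hop_vec <- as.vector(cm$hopb)
  for (l in rev(seq_len(config$layers))) {
    lc <- cache$layers[[l]]
    pl <- function(nm) params[[paste0("l", l, ".", nm)]]
    nm_l <- function(nm) paste0("l", l, ".", nm)
    # FFN block: Xout = Xmid + gelu(LN2(Xmid) W1 + b1) W2 + b2
    dZ2 <- dX
    add(nm_l("W2"), crossprod(lc$A1, dZ2))
    add(nm_l("b2"), colSums(dZ2))
    dA1 <- dZ2 %*% t(pl("W2"))
    dZ1 <- dA1 * .dgelu(lc$Z1)
    add(nm_l("W1"), crossprod(lc$ln2$y, dZ1))
    add(nm_l("b1"), colSums(dZ1))
    dXn2 <- dZ1 %*% t(pl("W1"))
    ln2b <- .layernorm_bwd(dXn2, lc$ln2, pl("ln2_g"))
    add(nm_l("ln2_g"), ln2b$dg); add(nm_l("ln2_b"), ln2b$db)
    dXmid <- dX + ln2b$dX
    # attention block: Xmid = X + (concat_h P_h V_h) Wo + bo
    dOp <- dXmid
    add(nm_l("Wo"), crossprod(lc$O, dOp))
    add(nm_l("bo"), colSums(dOp))
    dO <- dOp %*% t(pl("Wo"))
    dQ <- matrix(0, M, H); dK <- matrix(0, M, H); dV <- matrix(0, M, H)
    db_phi <- matrix(0, heads, ncol(params$b_phi))
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      P <- lc$Ps[[h]]
      dOh <- dO[, idx, drop = FALSE]
      dP <- tcrossprod(dOh, lc$V[, idx, drop = FALSE])
      dV[, idx] <- crossprod(P, dOh)
      dS <- (dP - rowSums(dP * P)) * P
      dC <- dC + dS
      agg <- rowsum(as.vector(dS), hop_vec)
      db_phi[h, as.integer(rownames(agg))] <-
        db_phi[h, as.integer(rownames(agg))] + agg
      dQ[, idx] <- (dS %*% lc$K[, idx, drop = FALSE]) * scale
      dK[, idx] <- (crossprod(dS, lc$Q[, idx, drop = FALSE])) * scale
    }
    add("b_phi", db_phi)
    Xn <- lc$ln1$y
    add(nm_l("Wq"), crossprod(Xn, dQ)); add(nm_l("bq"), colSums(dQ))
    add(nm_l("Wk"), crossprod(Xn, dK)); add(nm_l("bk"), colSums(dK))
    add(nm_l("Wv"), crossprod(Xn, dV)); add(nm_l("bv"), colSums(dV))
    dXn <- dQ %*% t(pl("Wq")) + dK %*% t(pl("Wk")) + dV %*% t(pl("Wv"))
    ln1b <- .layernorm_bwd(dXn, lc$ln1, pl("ln1_g"))
    add(nm_l("ln1_g"), ln1b$dg); add(nm_l("ln1_b"), ln1b$db)
    dX <- dXmid + ln1b$dX
  }
  # initial states
  dH0a <- dX[seq_len(n), , drop = FALSE]
  add("h_super", dX[M, ])
  add("W_in", crossprod(cm$atoms, dH0a))
  add("b_in", colSums(dH0a))
  dz <- matrix(0, nrow(params$z_deg), H)
  agg <- rowsum(dH0a, cm$degb)
  dz[as.integer(rownames(agg)), ] <- agg
  add("z_deg", dz)
  # edge encoding: C was shared by all heads and layers
  dwe <- matrix(0, config$max_hop_cap, .n_bond_features)
  if (!is.null(cm$ep)) {
    contrib <- dC[cm$ep$pair] * cm$ep$invlen
    tmp <- contrib * cm$bonds[cm$ep$edge, , drop = FALSE]
    agg <- rowsum(tmp, cm$ep$pos)
    dwe[as.integer(rownames(agg)), ] <- agg
  }
  add("w_edge", dwe)
  g
}

.mlp_head_bwd <- function(params, prefix, fw, dz2) {
  W1 <- params[[paste0(prefix, ".W1")]]
  W2 <- params[[paste0(prefix, ".W2")]]
  g <- list()
  g[[paste0(prefix, ".W2")]] <- crossprod(fw$A1, matrix(dz2, ncol = 1L))
  g[[paste0(prefix, ".b2")]] <- sum(dz2)
  dA1 <- matrix(dz2, ncol = 1L) %*% t(W2)
  dZ1 <- dA1 * .dgelu(fw$Z1)
  g[[paste0(prefix, ".W1")]] <- crossprod(fw$X, dZ1)
  g[[paste0(prefix, ".b1")]] <- colSums(dZ1)
  list(dX = dZ1 %*% t(W1), grads = g)
}

# Forward + loss + full gradient for one molecule under one variant.
# Returns loss terms and the flat gradient list.
.molecule_loss_grad <- function(params, config, cm, tg, variant, weights,
                                angle_squared = TRUE, noise = NULL,
                                with_grad = TRUE) {
  fw <- .encoder_forward(params, cm, config, noise = noise,
                         keep_cache = with_grad)
  n <- cm$n; H <- config$hidden
  A <- fw$h; s <- fw$super
  dA <- matrix(0, n, H); ds <- numeric(H)
  grads <- list()
  addg <- function(gl) {
    for (nm in names(gl)) {
      grads[[nm]] <<- if (is.null(grads[[nm]])) gl[[nm]] else grads[[nm]] + gl[[nm]]
    }
  }
  terms <- list()

  if (variant %in% c("a", "b")) {
    Dhat <- as.matrix(stats::dist(A)); dimnames(Dhat) <- NULL
    R <- Dhat - unclass(tg$D)
    w <- weights[["distance"]]
    terms$distance <- w * mean(R^2)
    if (with_grad) {
      Wm <- R / pmax(Dhat, 1e-12); diag(Wm) <- 0
      dA <- dA + w * (4 / n^2) * (rowSums(Wm) * A - Wm %*% A)
    }
  }
  if (variant == "b") {
    X <- cbind(matrix(s, n, H, byrow = TRUE), A)
    fwh <- .mlp_head_fwd(params, "d0", X)
    d0hat <- .softplus(fwh$z2)
    r <- d0hat - attr(tg$D, "origin_distances")
    w <- weights[["origin"]]
    terms$origin_distance <- w * mean(r^2)
    if (with_grad) {
      dz2 <- w * (2 / n) * r * .sigmoid(fwh$z2)
      hb <- .mlp_head_bwd(params, "d0", fwh, dz2)
      addg(hb$grads)
      ds <- ds + colSums(hb$dX[, seq_len(H), drop = FALSE])
      dA <- dA + hb$dX[, H + seq_len(H), drop = FALSE]
    }
  }
  if (variant %in% c("c", "d")) {
    R <- tcrossprod(A) - unclass(tg$G)
    w <- weights[["gram"]]
    terms$gram <- w * mean(R^2)
    if (with_grad) dA <- dA + w * (4 / n^2) * (R %*% A)
  }
  if (variant == "d") {
    bonds <- tg$bonds
    if (nrow(bonds) > 0L) {
      X <- cbind(A[bonds$u, , drop = FALSE], A[bonds$v, , drop = FALSE])
      fwh <- .mlp_head_fwd(params, "len", X)
      lhat <- .softplus(fwh$z2)
      r <- lhat - bonds$length
      w <- weights[["length"]]
      terms$bond_length <- w * mean(r^2)
      if (with_grad) {
        dz2 <- w * (2 / nrow(bonds)) * r * .sigmoid(fwh$z2)
        hb <- .mlp_head_bwd(params, "len", fwh, dz2)
        addg(hb$grads)
        for (b in seq_len(nrow(bonds))) {
          dA[bonds$u[b], ] <- dA[bonds$u[b], ] + hb$dX[b, seq_len(H)]
          dA[bonds$v[b], ] <- dA[bonds$v[b], ] + hb$dX[b, H + seq_len(H)]
        }
      }
    }
    ang <- tg$angles
    if (!is.null(ang) && nrow(ang) > 0L) {
      X <- cbind(A[ang$i, , drop = FALSE], A[ang$j, , drop = FALSE],
                 A[ang$k, , drop = FALSE])
      fwh <- .mlp_head_fwd(params, "ang", X)
      sig <- .sigmoid(fwh$z2)
      ahat <- pi * sig
      w <- weights[["angle"]]
      if (angle_squared) {
        r <- ahat - ang$angle
        terms$bond_angle <- w * mean(r^2)
        dz2 <- w * (2 / nrow(ang)) * r * pi * sig * (1 - sig)
      } else {
        # literal linear form of the printed angle term
        terms$bond_angle <- w * mean(ang$angle - ahat)
        dz2 <- -w * (1 / nrow(ang)) * pi * sig * (1 - sig)
      }
      if (with_grad) {
        hb <- .mlp_head_bwd(params, "ang", fwh, dz2)
        addg(hb$grads)
        for (b in seq_len(nrow(ang))) {
          dA[ang$i[b], ] <- dA[ang$i[b], ] + hb$dX[b, seq_len(H)]
          dA[ang$j[b], ] <- dA[ang$j[b], ] + hb$dX[b, H + seq_len(H)]
          dA[ang$k[b], ] <- dA[ang$k[b], ] + hb$dX[b, 2L * H + seq_len(H)]
        }
      }
    }
  }
  total <- sum(unlist(terms))
  if (!with_grad) {
    return(list(terms = terms, total = total, grads = NULL))
  }
  dHout <- rbind(dA, ds)
  addg(.encoder_backward(params, config, fw, dHout))
  list(terms = terms, total = total, grads = grads)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.99, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    if (!identical(dim(gr), dim(params[[nm]])) && length(gr) == length(params[[nm]])) {
      dim(gr) <- dim(params[[nm]])
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' One training step on a batch of molecules
#'
#' Computes the variant loss and its gradient over the batch (unweighted
#' mean across molecules of per-molecule losses), applies one Adam update,
#' and returns the updated model together with the loss breakdown. Aborts if
#' the loss is non-finite, naming the molecules in the batch.
#'
#' @param model List with `params`, `config`, `opt` (Adam state), as carried
#'   inside [pregtm()]; also accepts a `"gram_encoder"` (an Adam state is
#'   created on the fly).
#' @param batch List of prepared molecules: each element a list with `cm`
#'   (from the internal preprocessor), `targets` (from [build_targets()]),
#'   optional `noise`.
#' @param variant One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param lr Learning rate.
#' @param loss_weights Named weights for the active terms.
#' @param angle_squared Use squared angle error (the default); `FALSE`
#'   restores the literal linear angle term.
#' @param clip_norm Global gradient-norm clip (`Inf` disables).
#' @return List with updated `model` and `loss` (a loss breakdown: `total`
#'   plus active per-term values).
#' @export
training_step <- function(model, batch, variant = "d", lr = 1e-3,
                          loss_weights = NULL, angle_squared = TRUE,
                          clip_norm = 5) {
  if (inherits(model, "gram_encoder")) {
    model <- list(params = model$params, config = model$config,
                  opt = .adam_init(model$params))
  }
  weights <- .full_weights(loss_weights)
  acc <- NULL; terms_acc <- list(); total <- 0
  for (b in batch) {
    r <- .molecule_loss_grad(model$params, model$config, b$cm, b$targets,
                             variant, weights, angle_squared, b$noise)
    if (!is.finite(r$total)) {
      ids <- vapply(batch, function(x) x$cm$graph$id, character(1))
      stop("non-finite loss in batch containing: ", paste(ids, collapse = ", "))
    }
    total <- total + r$total
    for (nm in names(r$terms)) {
      terms_acc[[nm]] <- (terms_acc[[nm]] %||% 0) + r$terms[[nm]]
    }
    if (is.null(acc)) acc <- r$grads
    else for (nm in names(r$grads)) {
      acc[[nm]] <- (acc[[nm]] %||% 0) + r$grads[[nm]]
    }
  }
  nb <- length(batch)
  acc <- lapply(acc, function(gv) gv / nb)
  if (is.finite(clip_norm)) {
    gnorm <- sqrt(sum(vapply(acc, function(gv) sum(gv^2), numeric(1))))
    if (gnorm > clip_norm) {
      acc <- lapply(acc, function(gv) gv * (clip_norm / gnorm))
    }
  }
  if (lr > 0) {
    upd <- .adam_step(model$params, acc, model$opt, lr = lr)
    model$params <- upd$params; model$opt <- upd$state
  }
  loss <- c(list(total = total / nb), lapply(terms_acc, function(x) x / nb))
  list(model = model, loss = loss)
}

.full_weights <- function(loss_weights) {
  w <- c(gram = 1, distance = 1, origin = 1, length = 1, angle = 1)
  if (!is.null(loss_weights)) w[names(loss_weights)] <- unlist(loss_weights)
  as.list(w)
}
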