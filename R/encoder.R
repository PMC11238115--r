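# Graphormer-style graph transformer encoder, written directly in base R
# matrix algebra with analytic backpropagation (see backprop.R). The encoder
# maps a featurized 2D molecular graph to per-atom embeddings h_u and a
# super-node embedding; all geometric predictions (Gram matrix, origin
# distances, bond lengths and angles) are heads on these embeddings.

#' Encoder configuration
#'
#' @param layers Number of transformer blocks.
#' @param hidden Hidden width H (must be divisible by `heads`).
#' @param heads Number of attention heads.
#' @param ffn_width Width of the feed-forward block.
#' @param max_hop_cap Shortest-path hops are bucketed at this cap; one extra
#'   sentinel bucket serves disconnected pairs and one more the super node.
#' @param max_degree_cap Degree values are bucketed at this cap.
#' @param noise_mu,noise_sigma Mean and standard deviation of the Gaussian
#'   noise added to initial atom states (Eq.-style symmetry breaking between
#'   atoms in identical chemical environments); `noise_sigma = 0` disables.
#' @param dropout Dropout rate (0 disables; kept for config completeness).
#' @param seed Integer seed for parameter initialization.
#' @return An `"encoder_config"` list.
#' @export
encoder_config <- function(layers = 3L, hidden = 64L, heads = 4L,
                           ffn_width = 2L * hidden, max_hop_cap = 8L,
                           max_degree_cap = 8L, noise_mu = 0,
                           noise_sigma = 0.02, dropout = 0, seed = 1L) {
  if (hidden %% heads != 0L) stop("hidden must be divisible by heads")
  if (max_hop_cap < 1L || max_degree_cap < 1L) stop("caps must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(layers = as.integer(layers), hidden = as.integer(hidden),
                 heads = as.integer(heads), ffn_width = as.integer(ffn_width),
                 max_hop_cap = as.integer(max_hop_cap),
                 max_degree_cap = as.integer(max_degree_cap),
                 noise_mu = noise_mu, noise_sigma = noise_sigma,
                 dropout = dropout, seed = as.integer(seed)),
            class = "encoder_config")
}

.n_atom_features <- 17L
.n_bond_features <- 7L

.glorot <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
}

.n_hop_buckets <- function(config) config$max_hop_cap + 3L

# hop value -> bucket index: hop 0..cap -> 1..cap+1; disconnected -> cap+2;
# super-node pairs -> cap+3
.hop_bucket <- function(hops, config) {
  cap <- config$max_hop_cap
  b <- pmin(hops, cap) + 1L
  b[hops < 0L] <- cap + 2L
  b
}

#' Initialize an encoder
#'
#' Creates all learnable parameters (input projection, degree/centrality
#' embeddings, per-head spatial-bias table, per-position edge-encoding
#' weights, transformer blocks, final projection, and the three MLP heads
#' for origin distances, bond lengths and bond angles) with seeded Glorot
#' initialization.
#'
#' @param config An [encoder_config()].
#' @return A `"gram_encoder"` object (list with `params`, `config`).
#' @export
init_encoder <- function(config = encoder_config()) {
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(config$seed)
  H <- config$hidden
  p <- list(
    W_in = .glorot(.n_atom_features, H),
    b_in = numeric(H),
    z_deg = .glorot(config$max_degree_cap + 1L, H) * 0.1,
    h_super = stats::rnorm(H, 0, 0.02),
    b_phi = matrix(0, config$heads, .n_hop_buckets(config)),
    w_edge = .glorot(config$max_hop_cap, .n_bond_features) * 0.1,
    W_fc = .glorot(H, H),
    b_fc = numeric(H)
  )
  for (l in seq_len(config$layers)) {
    p[[paste0("l", l, ".ln1_g")]] <- rep(1, H)
    p[[paste0("l", l, ".ln1_b")]] <- numeric(H)
    p[[paste0("l", l, ".Wq")]] <- .glorot(H, H)
    p[[paste0("l", l, ".bq")]] <- numeric(H)
    p[[paste0("l", l, ".Wk")]] <- .glorot(H, H)
    p[[paste0("l", l, ".bk")]] <- numeric(H)
    p[[paste0("l", l, ".Wv")]] <- .glorot(H, H)
    p[[paste0("l", l, ".bv")]] <- numeric(H)
    p[[paste0("l", l, ".Wo")]] <- .glorot(H, H)
    p[[paste0("l", l, ".bo")]] <- numeric(H)
    p[[paste0("l", l, ".ln2_g")]] <- rep(1, H)
    p[[paste0("l", l, ".ln2_b")]] <- numeric(H)
    p[[paste0("l", l, ".W1")]] <- .glorot(H, config$ffn_width)
    p[[paste0("l", l, ".b1")]] <- numeric(config$ffn_width)
    p[[paste0("l", l, ".W2")]] <- .glorot(config$ffn_width, H)
    p[[paste0("l", l, ".b2")]] <- numeric(H)
  }
  for (hd in c("d0", "len")) {
    p[[paste0(hd, ".W1")]] <- .glorot(2L * H, H)
    p[[paste0(hd, ".b1")]] <- numeric(H)
    p[[paste0(hd, ".W2")]] <- .glorot(H, 1L)
    p[[paste0(hd, ".b2")]] <- 0
  }
  p[["ang.W1"]] <- .glorot(3L * H, H)
  p[["ang.b1"]] <- numeric(H)
  p[["ang.W2"]] <- .glorot(H, 1L)
  p[["ang.b2"]] <- 0
  structure(list(params = p, config = config), class = "gram_encoder")
}

#' @export
print.gram_encoder <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<gram_encoder: L=%d H=%d heads=%d, %d parameters>\n",
              x$config$layers, x$config$hidden, x$config$heads, np))
  invisible(x)
}

# Precompute everything about a molecule the encoder needs: feature
# matrices, hop-bucket matrix including the super node (last row/column),
# degree buckets, and the flattened shortest-path/edge table driving the
# edge encoding.
prep_molecule <- function(graph, config) {
  ft <- featurize(graph)
  topo <- topology_tables(graph)
  n <- n_atoms(graph); M <- n + 1L
  hopb <- matrix(config$max_hop_cap + 3L, M, M)
  hopb[seq_len(n), seq_len(n)] <- .hop_bucket(topo$shortest_hops, config)
  hopb[M, M] <- 1L
  degb <- pmin(topo$degrees, config$max_degree_cap) + 1L
  # flattened edge-path table for pairs with 1 <= hop <= cap
  ii <- integer(0); jj <- integer(0); pos <- integer(0); edge <- integer(0)
  invlen <- numeric(0)
  cap <- config$max_hop_cap
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      hp <- topo$shortest_hops[i, j]
      if (hp < 1L || hp > cap) next
      pe <- topo$path_edges[[i]][[j]]
      ii <- c(ii, rep.int(i, hp)); jj <- c(jj, rep.int(j, hp))
      pos <- c(pos, seq_len(hp)); edge <- c(edge, pe)
      invlen <- c(invlen, rep.int(1 / hp, hp))
    }
  }
  ep <- if (length(ii)) {
    data.frame(i = ii, j = jj, pos = pos, edge = edge, invlen = invlen,
               pair = (jj - 1L) * M + ii)
  } else NULL
  list(graph = graph, n = n, M = M, atoms = ft$atoms, bonds = ft$bonds,
       hopb = hopb, degb = degb, ep = ep, topo = topo)
}

.gelu <- function(x) x * stats::pnorm(x)
.dgelu <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
.sigmoid <- function(x) 1 / (1 + exp(-x))

.layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, `*`) + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

.layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat; inv <- cache$inv
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxh <- sweep(dY, 2L, g, `*`)
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * xhat)
  dX <- (dxh - m1 - xhat * m2) * inv
  list(dX = dX, dg = dg, db = db)
}

.softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

# Edge-encoding matrix C (M x M): for each atom pair within the hop cap, the
# mean over the shortest path's edges of <bond features, per-position weight>.
.edge_encoding <- function(params, cm) {
  C <- matrix(0, cm$M, cm$M)
  if (!is.null(cm$ep)) {
    val <- rowSums(cm$bonds[cm$ep$edge, , drop = FALSE] *
                     params$w_edge[cm$ep$pos, , drop = FALSE]) * cm$ep$invlen
    agg <- rowsum(val, cm$ep$pair)
    C[as.integer(rownames(agg))] <- agg
  }
  C
}

# Full forward pass. `noise` is an optional n x H matrix added to the
# initial atom states (Eq.-9-style Gaussian perturbation). With
# keep_cache = TRUE all intermediates needed for backprop are retained.
.encoder_forward <- function(params, cm, config, noise = NULL,
                             keep_cache = FALSE) {
  H <- config$hidden; heads <- config$heads; dh <- H %/% heads
  n <- cm$n; M <- cm$M
  h0_atoms <- cm$atoms %*% params$W_in +
    rep(params$b_in, each = n) + params$z_deg[cm$degb, , drop = FALSE]
  X <- rbind(h0_atoms, params$h_super)
  if (!is.null(noise)) X[seq_len(n), ] <- X[seq_len(n), ] + noise
  X0 <- X
  C <- .edge_encoding(params, cm)
  scale <- 1 / sqrt(dh)
  caches <- if (keep_cache) vector("list", config$layers) else NULL
  for (l in seq_len(config$layers)) {
    pl <- function(nm) params[[paste0("l", l, ".", nm)]]
    ln1 <- .layernorm_fwd(X, pl("ln1_g"), pl("ln1_b"))
    Xn <- ln1$y
    Q <- Xn %*% pl("Wq") + rep(pl("bq"), each = M)
    K <- Xn %*% pl("Wk") + rep(pl("bk"), each = M)
    V <- Xn %*% pl("Wv") + rep(pl("bv"), each = M)
    O <- matrix(0, M, H)
    Ps <- if (keep_cache) vector("list", heads) else NULL
    for (h in seq_len(heads)) {
      idx <- ((h - 1L) * dh + 1L):(h * dh)
      B <- matrix(params$b_phi[h, cm$hopb], M, M) + C
      S <- tcrossprod(Q[, idx, drop = FALSE], K[, idx, drop = FALSE]) * scale + B
      P <- .softmax_rows(S)
      O[, idx] <- P %*% V[, idx, drop = FALSE]
      if (keep_cache) Ps[[h]] <- P
    }
    Op <- O %*% pl("Wo") + rep(pl("bo"), each = M)
    Xmid <- X + Op
    ln2 <- .layernorm_fwd(Xmid, pl("ln2_g"), pl("ln2_b"))
    Z1 <- ln2$y %*% pl("W1") + rep(pl("b1"), each = M)
    A1 <- .gelu(Z1)
    Z2 <- A1 %*% pl("W2") + rep(pl("b2"), each = M)
    Xout <- Xmid + Z2
    if (keep_cache) {
      caches[[l]] <- list(X = X, ln1 = ln1, Q = Q, K = K, V = V, Ps = Ps,
                          O = O, Xmid = Xmid, ln2 = ln2, Z1 = Z1, A1 = A1)
    }
    X <- Xout
  }
  Hout <- X %*% params$W_fc + rep(params$b_fc, each = M)
  res <- list(h = Hout[seq_len(n), , drop = FALSE], super = Hout[M, ],
              h0 = X0[seq_len(n), , drop = FALSE])
  if (keep_cache) {
    res$cache <- list(layers = caches, Xlast = X, C = C, cm = cm)
  }
  res
}

#' Encode a molecule
#'
#' Runs the full forward pass: initial states (feature projection plus
#' centrality embedding, dedicated super-node vector), optional Gaussian
#' noise on the initial atom states, `layers` pre-norm transformer blocks
#' whose attention logits carry the per-head spatial (shortest-hop) bias and
#' the shared edge encoding, and a final linear projection.
#'
#' @param encoder A `"gram_encoder"` (from [init_encoder()]) or a fitted
#'   [pregtm()] model.
#' @param graph A [molecular_graph()].
#' @param noise_seed Optional integer; when given and `noise_sigma > 0`, the
#'   Gaussian initial-state noise is drawn deterministically from this seed.
#'   `NULL` disables noise.
#' @return List with `h` (N x H final atom embeddings), `h0` (initial
#'   states), `super` (length-H super-node embedding).
#' @export
encode <- function(encoder, graph, noise_seed = NULL) {
  enc <- .as_encoder(encoder)
  cm <- prep_molecule(graph, enc$config)
  noise <- NULL
  if (!is.null(noise_seed) && enc$config$noise_sigma > 0) {
    noise <- make_state_noise(cm$n, enc$config, noise_seed)
  }
  .encoder_forward(enc$params, cm, enc$config, noise = noise)
}

.as_encoder <- function(x) {
  if (inherits(x, "gram_encoder")) return(x)
  if (inherits(x, "pregtm")) return(x$encoder)
  stop("expected a gram_encoder or pregtm object")
}

#' Initial atom states
#'
#' The pre-transformer states: each atom's feature vector is linearly
#' projected into the hidden width and the centrality (capped-degree)
#' embedding is added; the super node starts from its dedicated learned
#' vector. No noise is applied here.
#'
#' @param encoder A `"gram_encoder"` or fitted [pregtm()] model.
#' @param graph A [molecular_graph()].
#' @return (N+1) x H matrix; the last row is the super node.
#' @export
initialize_states <- function(encoder, graph) {
  enc <- .as_encoder(encoder)
  cm <- prep_molecule(graph, enc$config)
  n <- cm$n
  h0 <- cm$atoms %*% enc$params$W_in +
    rep(enc$params$b_in, each = n) +
    enc$params$z_deg[cm$degb, , drop = FALSE]
  rbind(h0, enc$params$h_super)
}

#' Gaussian initial-state noise
#'
#' Draws the n x H perturbation matrix Z with i.i.d. entries from
#' N(`noise_mu`, `noise_sigma`^2), deterministically under `seed`. Injected
#' into the initial atom states to break ties between atoms in identical
#' chemical environments; the same draw can be replayed at inference.
#'
#' @param n Number of atoms.
#' @param config An [encoder_config()].
#' @param seed Integer seed.
#' @return n x H numeric matrix.
#' @export
make_state_noise <- function(n, config, seed) {
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed))
  matrix(stats::rnorm(n * config$hidden, config$noise_mu, config$noise_sigma),
         n, config$hidden)
}

#' Inject Gaussian noise into initial states
#'
#' @param h0 N x H matrix of initial atom states.
#' @param config An [encoder_config()] supplying `noise_mu`, `noise_sigma`.
#' @param seed Integer seed; the perturbation is deterministic given the
#'   seed.
#' @return Perturbed matrix of the same shape.
#' @export
inject_noise <- function(h0, config, seed) {
  if (config$noise_sigma == 0 && config$noise_mu == 0) return(h0)
  h0 + make_state_noise(nrow(h0), config, seed)
}

#' Predicted Gram matrix from embeddings
#'
#' The inner-product head: Ghat_uv = h_u . h_v over real atoms (super node
#' excluded). Symmetric and positive semidefinite by construction for any
#' parameter values, with rank at most H.
#'
#' @param embeddings Result of [encode()] (or an N x H matrix).
#' @return A `"gram_matrix"`.
#' @export
predict_gram <- function(embeddings) {
  h <- if (is.list(embeddings)) embeddings$h else embeddings
  structure(tcrossprod(h), class = "gram_matrix")
}

.mlp_head_fwd <- function(params, prefix, X) {
  W1 <- params[[paste0(prefix, ".W1")]]; b1 <- params[[paste0(prefix, ".b1")]]
  W2 <- params[[paste0(prefix, ".W2")]]; b2 <- params[[paste0(prefix, ".b2")]]
  Z1 <- X %*% W1 + rep(b1, each = nrow(X))
  A1 <- .gelu(Z1)
  Z2 <- drop(A1 %*% W2) + b2
  list(z2 = Z2, Z1 = Z1, A1 = A1, X = X)
}

#' Predict atom-to-origin distances
#'
#' A fully connected head on the concatenation of the super-node embedding
#' and each atom embedding, mapped positive through softplus.
#'
#' @param encoder A `"gram_encoder"` or fitted [pregtm()] model.
#' @param embeddings Result of [encode()].
#' @return Numeric vector of length N (Angstrom), non-negative.
#' @export
predict_origin_distances <- function(encoder, embeddings) {
  enc <- .as_encoder(encoder)
  n <- nrow(embeddings$h)
  X <- cbind(matrix(embeddings$super, n, length(embeddings$super),
                    byrow = TRUE), embeddings$h)
  .softplus(.mlp_head_fwd(enc$params, "d0", X)$z2)
}

.canon_bond <- function(u, v) if (u <= v) c(u, v) else c(v, u)

#' Predict bond lengths with the MLP head
#'
#' MLP on the concatenation of the two endpoint embeddings (canonicalized
#' with the smaller index first), softplus-mapped to a positive length.
#'
#' @param encoder A `"gram_encoder"` or fitted [pregtm()] model.
#' @param embeddings Result of [encode()].
#' @param bonds Two-column matrix (or data frame with `u`, `v`) of bonded
#'   atom index pairs.
#' @return Numeric vector of lengths (Angstrom).
#' @export
predict_bond_lengths <- function(encoder, embeddings, bonds) {
  enc <- .as_encoder(encoder)
  bonds <- .as_pair_matrix(bonds)
  u <- pmin(bonds[, 1], bonds[, 2]); v <- pmax(bonds[, 1], bonds[, 2])
  X <- cbind(embeddings$h[u, , drop = FALSE], embeddings$h[v, , drop = FALSE])
  .softplus(.mlp_head_fwd(enc$params, "len", X)$z2)
}

#' Predict bond angles with the MLP head
#'
#' MLP on the concatenation of the three atom embeddings of an angle triple
#' (i, j, k) with vertex j, canonicalized so that (i, j, k) and (k, j, i)
#' give the same value, mapped into (0, pi) by a scaled sigmoid.
#'
#' @param encoder A `"gram_encoder"` or fitted [pregtm()] model.
#' @param embeddings Result of [encode()].
#' @param angles Three-column matrix (or data frame with `i`, `j`, `k`) of
#'   angle triples; `j` is the vertex.
#' @return Numeric vector of angles in radians, in (0, pi).
#' @export
predict_bond_angles <- function(encoder, embeddings, angles) {
  enc <- .as_encoder(encoder)
  angles <- .as_triple_matrix(angles)
  i <- pmin(angles[, 1], angles[, 3]); k <- pmax(angles[, 1], angles[, 3])
  j <- angles[, 2]
  X <- cbind(embeddings$h[i, , drop = FALSE], embeddings$h[j, , drop = FALSE],
             embeddings$h[k, , drop = FALSE])
  pi * .sigmoid(.mlp_head_fwd(enc$params, "ang", X)$z2)
}

.as_pair_matrix <- function(bonds) {
  if (is.data.frame(bonds)) bonds <- cbind(bonds$u, bonds$v)
  m <- as.matrix(bonds)
  if (ncol(m) != 2L) stop("bonds must have two columns")
  storage.mode(m) <- "integer"
  m
}

.as_triple_matrix <- function(angles) {
  if (is.data.frame(angles)) angles <- cbind(angles$i, angles$j, angles$k)
  m <- as.matrix(angles)
  if (ncol(m) != 3L) stop("angles must have three columns")
  storage.mode(m) <- "integer"
  m
}

#' Derive bond lengths and angle cosines from a (predicted) Gram matrix
#'
#' The alternative supervision pathway: lengths from the Gram-to-distance
#' identity on bonded pairs, angle cosines from the Gram angle formula on
#' bonded triples. Degenerate radicands are clamped to zero and flagged.
#'
#' @param g A `"gram_matrix"` (true or predicted).
#' @param bonds Two-column matrix of bonded pairs.
#' @param angles Three-column matrix of angle triples (vertex second).
#' @return List with `lengths` (Angstrom), `cosines`, and `clamped` (logical
#'   flag vector marking degenerate entries).
#' @export
derive_geometry_from_gram <- function(g, bonds, angles = NULL) {
  if (!inherits(g, "gram_matrix")) g <- gram_matrix(g)
  bonds <- .as_pair_matrix(bonds)
  dg <- diag(g)
  sq <- dg[bonds[, 1]] + dg[bonds[, 2]] -
    2 * g[cbind(bonds[, 1], bonds[, 2])]
  clamped <- sq < 0
  lengths <- sqrt(pmax(sq, 0))
  cosines <- NULL
  if (!is.null(angles) && nrow(.as_triple_matrix(angles)) > 0L) {
    angles <- .as_triple_matrix(angles)
    cosines <- apply(angles, 1L, function(t) {
      tryCatch(angle_cosine_from_gram(g, t[1], t[2], t[3]),
               error = function(e) NA_real_)
    })
  }
  list(lengths = lengths, cosines = cosines, clamped = clamped)
}
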