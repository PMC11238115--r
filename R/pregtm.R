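# Stage-1 geometric pretraining: fit a graph-transformer encoder to predict
# the Gram matrix (and, depending on the variant, distances, origin
# distances, bond lengths and angles) of training conformers.

#' Geometric pretraining of the Gram-matrix encoder
#'
#' Trains the graph-transformer encoder on molecules with known 3D
#' conformers under one of four supervision variants: `"a"` distance matrix;
#' `"b"` distance matrix plus atom-to-origin distances; `"c"` Gram matrix;
#' `"d"` Gram matrix plus bond-length and bond-angle auxiliary heads.
#' Optimization is full-batch (or minibatch) Adam on the per-molecule mean
#' losses. When `noise_sigma > 0` each training molecule receives one fixed
#' Gaussian initial-state perturbation, drawn from the run seed and replayed
#' at every step (and at prediction time for that molecule), so that atoms
#' in identical chemical environments become distinguishable.
#'
#' @param molecules List of [molecular_graph()] objects with conformers.
#' @param variant Supervision variant, `"a"`, `"b"`, `"c"` or `"d"`.
#' @param config An [encoder_config()].
#' @param steps Number of Adam steps.
#' @param lr Initial learning rate.
#' @param lr_final Final learning rate; when smaller than `lr` the rate
#'   follows a cosine decay from `lr` to `lr_final` over `steps`.
#' @param batch_size Molecules per step (`NULL` = full batch).
#' @param seed Integer seed driving initialization, noise draws and batch
#'   order.
#' @param val_molecules Optional validation molecules (with conformers);
#'   validation loss is tracked and the best parameters kept.
#' @param eval_every Evaluate/record every this many steps.
#' @param patience Early-stopping patience in evaluations (`Inf` disables).
#' @param stop_loss Stop as soon as the tracked loss (validation if
#'   available, else training) falls below this value (0 disables).
#' @param loss_weights Named term weights (default 1 each).
#' @param angle_squared Squared angle error (default) or the literal linear
#'   term.
#' @param verbose Print progress.
#' @return An object of class `"pregtm"` with the trained `encoder`,
#'   training `history` (data frame), per-molecule `noise` draws, `variant`
#'   and settings. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`.
#' @seealso [predict.pregtm()], [pregtm_embeddings()], [pregtm_property()]
#' @export
pregtm <- function(molecules, variant = c("d", "a", "b", "c"),
                   config = encoder_config(), steps = 500L, lr = 2e-3,
                   lr_final = lr, batch_size = NULL, seed = 1L,
                   val_molecules = NULL,
                   eval_every = 25L, patience = Inf, stop_loss = 0,
                   loss_weights = NULL, angle_squared = TRUE,
                   verbose = FALSE) {
  variant <- match.arg(variant)
  no_conf <- vapply(molecules, function(g) is.null(g$conformer), logical(1))
  if (any(no_conf)) {
    ids <- vapply(molecules[no_conf], function(g) g$id, character(1))
    stop("molecules lack conformers: ", paste(ids, collapse = ", "))
  }
  config$seed <- as.integer(seed)
  enc <- init_encoder(config)
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed) + 1L)
  prep <- lapply(molecules, function(g) {
    cm <- prep_molecule(g, config)
    list(cm = cm, targets = build_targets(g),
         noise = if (config$noise_sigma > 0) {
           matrix(stats::rnorm(cm$n * config$hidden, config$noise_mu,
                               config$noise_sigma), cm$n, config$hidden)
         } else NULL)
  })
  names(prep) <- vapply(molecules, function(g) g$id, character(1))
  vprep <- if (!is.null(val_molecules)) {
    lapply(val_molecules, function(g) {
      cm <- prep_molecule(g, config)
      list(cm = cm, targets = build_targets(g), noise = NULL)
    })
  } else NULL
  weights <- .full_weights(loss_weights)
  model <- list(params = enc$params, config = config,
                opt = .adam_init(enc$params))
  nmol <- length(prep)
  bs <- min(batch_size %||% nmol, nmol)
  hist_rows <- list()
  best <- list(loss = Inf, params = model$params, step = 0L)
  since_best <- 0L
  eval_loss <- function(pp, params) {
    tot <- 0
    for (b in pp) {
      r <- .molecule_loss_grad(params, config, b$cm, b$targets, variant,
                               weights, angle_squared, b$noise,
                               with_grad = FALSE)
      tot <- tot + r$total
    }
    tot / length(pp)
  }
  for (step in seq_len(steps)) {
    batch <- if (bs < nmol) prep[sample.int(nmol, bs)] else prep
    lr_t <- lr_final + (lr - lr_final) *
      (1 + cos(pi * (step - 1L) / max(1L, steps))) / 2
    st <- training_step(model, batch, variant = variant, lr = lr_t,
                        loss_weights = weights, angle_squared = angle_squared)
    model <- st$model
    if (step %% eval_every == 0L || step == steps) {
      row <- data.frame(step = step, train_loss = st$loss$total)
      for (nm in setdiff(names(st$loss), "total")) row[[nm]] <- st$loss[[nm]]
      track <- st$loss$total
      if (!is.null(vprep)) {
        row$val_loss <- eval_loss(vprep, model$params)
        track <- row$val_loss
      }
      hist_rows[[length(hist_rows) + 1L]] <- row
      if (track < best$loss) {
        best <- list(loss = track, params = model$params, step = step)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) {
          if (verbose) message("early stop at step ", step)
          break
        }
      }
      if (verbose) {
        message(sprintf("step %d: loss %.5g%s", step, st$loss$total,
                        if (!is.null(row$val_loss))
                          sprintf(" (val %.5g)", row$val_loss) else ""))
      }
      if (stop_loss > 0 && track < stop_loss) break
    }
  }
  history <- do.call(rbind, lapply(hist_rows, function(r) {
    r[setdiff(names(hist_rows[[length(hist_rows)]]), names(r))] <- NA
    r
  }))
  enc$params <- if (is.finite(best$loss)) best$params else model$params
  structure(list(
    encoder = enc, variant = variant, history = history,
    noise = lapply(prep, function(b) b$noise),
    molecule_ids = names(prep), loss_weights = weights,
    angle_squared = angle_squared, seed = as.integer(seed),
    best_step = best$step, call = match.call()
  ), class = "pregtm")
}

#' @export
print.pregtm <- function(x, ...) {
  cat(sprintf("Pre-GTM geometric pretraining (variant %s)\n", x$variant))
  print(x$encoder)
  if (!is.null(x$history) && nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained %d molecules, final loss %.5g at step %d\n",
                length(x$molecule_ids), last$train_loss, last$step))
  }
  invisible(x)
}

#' @export
summary.pregtm <- function(object, ...) {
  cat(sprintf("Pre-GTM variant %s: supervision on %s\n", object$variant,
              paste(.variant_terms[[object$variant]], collapse = " + ")))
  print(object$encoder)
  cat(sprintf("  molecules: %d; seed %d; best step %d\n",
              length(object$molecule_ids), object$seed, object$best_step))
  if (!is.null(object$history)) {
    cat("  loss history (tail):\n")
    print(utils::tail(object$history, 3L), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.pregtm <- function(object, ...) object$encoder$params

#' @export
plot.pregtm <- function(x, ...) {
  h <- x$history
  plot(h$step, h$train_loss, type = "l", log = "y", xlab = "step",
       ylab = "loss", main = sprintf("Pre-GTM variant %s", x$variant), ...)
  if (!is.null(h$val_loss)) {
    graphics::lines(h$step, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2,
                     bty = "n")
  }
  invisible(x)
}

.stored_noise <- function(object, graph, use_stored_noise) {
  if (!use_stored_noise) return(NULL)
  object$noise[[graph$id]]
}

#' Predict geometric quantities for a molecule
#'
#' Runs the trained encoder on a (2D) molecular graph and returns the
#' requested quantity: the predicted Gram matrix (inner products of the
#' final atom embeddings), the conformer reconstructed from it by
#' eigendecomposition, bond lengths/angles (MLP heads for variant `"d"`
#' models, Gram-derived otherwise), origin distances, the full distance
#' matrix derived from the embeddings, or the raw embeddings.
#'
#' @param object A fitted [pregtm()] model.
#' @param graph A [molecular_graph()] (no conformer required).
#' @param type One of `"gram"`, `"conformer"`, `"distance"`, `"lengths"`,
#'   `"angles"`, `"origin"`, `"embeddings"`.
#' @param use_stored_noise Replay the training-time noise draw when `graph`
#'   was a training molecule (default `TRUE`; unseen molecules are encoded
#'   without noise).
#' @param ... Unused.
#' @return The requested prediction.
#' @export
predict.pregtm <- function(object, graph,
                           type = c("gram", "conformer", "distance",
                                    "lengths", "angles", "origin",
                                    "embeddings"),
                           use_stored_noise = TRUE, ...) {
  type <- match.arg(type)
  cfg <- object$encoder$config
  cm <- prep_molecule(graph, cfg)
  noise <- .stored_noise(object, graph, use_stored_noise)
  emb <- .encoder_forward(object$encoder$params, cm, cfg, noise = noise)
  if (type == "embeddings") return(emb)
  if (type == "origin") return(predict_origin_distances(object, emb))
  G <- predict_gram(emb)
  if (type == "gram") return(G)
  if (type == "conformer") return(mds_reconstruct(G, elements = graph$elements))
  if (type == "distance") {
    d <- as.matrix(stats::dist(emb$h)); dimnames(d) <- NULL
    return(dist_matrix(d, origin_distances = sqrt(pmax(diag(G), 0))))
  }
  if (type == "lengths") {
    if (object$variant == "d") {
      return(predict_bond_lengths(object, emb, graph$bonds))
    }
    return(derive_geometry_from_gram(G, graph$bonds)$lengths)
  }
  # angles
  tri <- .angle_triples(graph)
  if (nrow(tri) == 0L) return(numeric(0))
  if (object$variant == "d") {
    return(predict_bond_angles(object, emb, tri))
  }
  dg <- derive_geometry_from_gram(G, graph$bonds, tri)
  acos(pmax(-1, pmin(1, dg$cosines)))
}

.angle_triples <- function(graph) {
  adj <- .adjacency_list(graph)
  tri <- list()
  for (j in seq_len(n_atoms(graph))) {
    nbr <- adj[[j]][, 1]
    if (length(nbr) < 2L) next
    cmb <- utils::combn(sort(nbr), 2L)
    for (cc in seq_len(ncol(cmb))) {
      tri[[length(tri) + 1L]] <- c(cmb[1, cc], j, cmb[2, cc])
    }
  }
  if (!length(tri)) {
    return(data.frame(i = integer(), j = integer(), k = integer()))
  }
  m <- do.call(rbind, tri)
  data.frame(i = m[, 1], j = m[, 2], k = m[, 3])
}

#' @export
residuals.pregtm <- function(object, molecules, ...) {
  lapply(molecules, function(g) {
    tg <- build_targets(g)
    unclass(predict(object, g, type = "gram")) - unclass(tg$G)
  })
}

#' Frozen per-atom embeddings for downstream use
#'
#' Extracts the final atom embeddings h_u (and the super-node embedding) for
#' each molecule from a trained model. Downstream molecules need topology
#' only; by default no noise is applied, so repeated calls are bit-identical.
#'
#' @param object A fitted [pregtm()] model.
#' @param molecules List of [molecular_graph()] (conformers not required).
#' @param use_stored_noise Replay training noise for training molecules.
#' @return Named list (by molecule id) of lists with `h` (N x H) and
#'   `super`.
#' @export
pregtm_embeddings <- function(object, molecules, use_stored_noise = FALSE) {
  out <- lapply(molecules, function(g) {
    emb <- predict(object, g, type = "embeddings",
                   use_stored_noise = use_stored_noise)
    list(h = emb$h, super = emb$super)
  })
  names(out) <- vapply(molecules, function(g) g$id, character(1))
  out
}
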