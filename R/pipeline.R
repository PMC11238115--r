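# Stage-2 property prediction on frozen embeddings, end-to-end
# orchestration, checkpoints and the Gram-matrix archive format.

#' Checksum of a parameter set
#'
#' Order-stable fingerprint of all parameter arrays, used to assert that
#' stage-1 parameters are untouched by stage-2 training.
#'
#' @param params Flat named list of numeric arrays (e.g. `coef(fit)`).
#' @return Character scalar.
#' @export
param_checksum <- function(params) {
  parts <- vapply(names(params), function(nm) {
    p <- as.numeric(params[[nm]])
    sprintf("%s:%.17g:%.17g:%.17g", nm, sum(p), sum(p * p),
            sum(p * seq_along(p)))
  }, character(1))
  paste(parts, collapse = "|")
}

#' Property prediction on frozen pretrained embeddings
#'
#' Stage 2 of the pipeline: a fresh encoder (same architecture family,
#' fresh parameters) produces embeddings h'_u which are concatenated
#' per-atom with the frozen embeddings h_u from the pretrained stage-1
#' model; a readout (mean over real atoms by default) pools them into a
#' molecule vector, and a fully connected head predicts the property.
#' Squared-error loss for regression, logistic cross-entropy for binary
#' classification. Stage-1 parameters are checksummed before and after
#' training and asserted unchanged. Downstream molecules need topology only
#' (no conformers anywhere in this stage).
#'
#' @param pretrained A fitted [pregtm()] model (the frozen source).
#' @param molecules List of [molecular_graph()] (conformers not needed).
#' @param labels Numeric vector (regression) or 0/1 vector (classification),
#'   one per molecule; `NA` labels are masked out of the loss.
#' @param task `"regression"` or `"classification"`.
#' @param config [encoder_config()] for the fresh encoder (default: a copy
#'   of the stage-1 config with noise disabled).
#' @param steps,lr Adam steps and learning rate.
#' @param seed Integer seed.
#' @param readout `"mean"`, `"sum"`, or `"super"` (the fresh encoder's super
#'   node).
#' @param verbose Print progress.
#' @return A `"pregtm_property"` object with `predict`, `print` methods.
#' @export
pregtm_property <- function(pretrained, molecules, labels,
                            task = c("regression", "classification"),
                            config = NULL, steps = 300L, lr = 5e-3,
                            seed = 1L, readout = c("mean", "sum", "super"),
                            verbose = FALSE) {
  task <- match.arg(task)
  readout <- match.arg(readout)
  stopifnot(length(labels) == length(molecules))
  if (is.null(config)) {
    config <- pretrained$encoder$config
    config$noise_sigma <- 0
  }
  config$seed <- as.integer(seed)
  frozen_before <- param_checksum(pretrained$encoder$params)
  frozen <- pregtm_embeddings(pretrained, molecules, use_stored_noise = FALSE)
  H1 <- ncol(frozen[[1]]$h)
  enc <- init_encoder(config)
  H2 <- config$hidden
  old <- .save_rng_state(); on.exit(.restore_rng_state(old))
  set.seed(as.integer(seed) + 7L)
  p <- enc$params
  hw <- max(32L, (H1 + H2) %/% 2L)
  p[["prop.W1"]] <- .glorot(H1 + H2, hw)
  p[["prop.b1"]] <- numeric(hw)
  p[["prop.W2"]] <- .glorot(hw, 1L)
  p[["prop.b2"]] <- 0
  cms <- lapply(molecules, function(g) prep_molecule(g, config))
  keep <- which(!is.na(labels))
  model <- list(params = p, config = config, opt = .adam_init(p))
  history <- numeric(0)
  forward_mol <- function(params, m, with_cache = FALSE) {
    fw <- .encoder_forward(params, cms[[m]], config, keep_cache = with_cache)
    n <- cms[[m]]$n
    Z <- cbind(frozen[[m]]$h, fw$h)          # N x (H1 + H2)
    z <- switch(readout,
                mean = colMeans(Z),
                sum = colSums(Z),
                super = c(colMeans(Z[, seq_len(H1), drop = FALSE]), fw$super))
    z1 <- drop(z %*% params[["prop.W1"]]) + params[["prop.b1"]]
    a1 <- .gelu(z1)
    yhat <- sum(a1 * params[["prop.W2"]]) + params[["prop.b2"]]
    list(fw = fw, Z = Z, z = z, z1 = z1, a1 = a1, yhat = yhat, n = n)
  }
  for (step in seq_len(steps)) {
    grads <- list(); total <- 0
    addg <- function(nm, v) {
      grads[[nm]] <<- if (is.null(grads[[nm]])) v else grads[[nm]] + v
    }
    for (m in keep) {
      fwm <- forward_mol(model$params, m, with_cache = TRUE)
      y <- labels[m]
      if (task == "regression") {
        r <- fwm$yhat - y
        total <- total + r^2
        dy <- 2 * r
      } else {
        pr <- .sigmoid(fwm$yhat)
        total <- total - (y * log(max(pr, 1e-12)) +
                            (1 - y) * log(max(1 - pr, 1e-12)))
        dy <- pr - y
      }
      addg("prop.W2", matrix(dy * fwm$a1, ncol = 1L))
      addg("prop.b2", dy)
      da1 <- dy * drop(model$params[["prop.W2"]])
      dz1 <- da1 * .dgelu(fwm$z1)
      addg("prop.W1", outer(fwm$z, dz1))
      addg("prop.b1", dz1)
      dz <- drop(model$params[["prop.W1"]] %*% dz1)
      n <- fwm$n
      H <- H2
      if (readout == "super") {
        dHfresh <- matrix(0, n, H)
        dsuper <- dz[H1 + seq_len(H)]
      } else {
        scalef <- if (readout == "mean") 1 / n else 1
        dZ <- matrix(dz, n, H1 + H2, byrow = TRUE) * scalef
        dHfresh <- dZ[, H1 + seq_len(H2), drop = FALSE]
        dsuper <- numeric(H2)
      }
      dHout <- rbind(dHfresh, dsuper)
      eg <- .encoder_backward(model$params, config, fwm$fw, dHout)
      for (nm in names(eg)) addg(nm, eg[[nm]])
    }
    grads <- lapply(grads, function(gv) gv / length(keep))
    upd <- .adam_step(model$params, grads, model$opt, lr = lr)
    model$params <- upd$params; model$opt <- upd$state
    history <- c(history, total / length(keep))
    if (verbose && step %% 50L == 0L) {
      message(sprintf("property step %d: loss %.5g", step,
                      total / length(keep)))
    }
  }
  frozen_after <- param_checksum(pretrained$encoder$params)
  stopifnot(identical(frozen_before, frozen_after))
  structure(list(
    params = model$params, config = config, task = task, readout = readout,
    frozen_source = pretrained, frozen_checksum = frozen_before,
    history = history, seed = as.integer(seed), H1 = H1, H2 = H2
  ), class = "pregtm_property")
}

#' @export
print.pregtm_property <- function(x, ...) {
  cat(sprintf("<pregtm_property: %s, readout %s, frozen H=%d + fresh H=%d>\n",
              x$task, x$readout, x$H1, x$H2))
  if (length(x$history)) {
    cat(sprintf("  final training loss %.5g after %d steps\n",
                x$history[length(x$history)], length(x$history)))
  }
  invisible(x)
}

#' @export
predict.pregtm_property <- function(object, molecules, type = c("response",
                                                                "link"), ...) {
  type <- match.arg(type)
  if (inherits(molecules, "molecular_graph")) molecules <- list(molecules)
  frozen <- pregtm_embeddings(object$frozen_source, molecules,
                              use_stored_noise = FALSE)
  vapply(seq_along(molecules), function(m) {
    cm <- prep_molecule(molecules[[m]], object$config)
    fw <- .encoder_forward(object$params, cm, object$config)
    H1 <- object$H1
    Z <- cbind(frozen[[m]]$h, fw$h)
    z <- switch(object$readout,
                mean = colMeans(Z),
                sum = colSums(Z),
                super = c(colMeans(Z[, seq_len(H1), drop = FALSE]), fw$super))
    z1 <- drop(z %*% object$params[["prop.W1"]]) + object$params[["prop.b1"]]
    yhat <- sum(.gelu(z1) * object$params[["prop.W2"]]) +
      object$params[["prop.b2"]]
    if (object$task == "classification" && type == "response") {
      .sigmoid(yhat)
    } else yhat
  }, numeric(1))
}

# --- checkpoints and archives --------------------------------------------

#' Save / load a model checkpoint
#'
#' Single-file archive holding the config, all parameter arrays by name, the
#' seed, variant, training history and a format version field.
#'
#' @param object A [pregtm()] fit or `"gram_encoder"`.
#' @param path Destination file.
#' @return `path` invisibly; `load_checkpoint` returns the restored object.
#' @export
save_checkpoint <- function(object, path) {
  payload <- list(format = "gramconf-checkpoint", version = 1L,
                  object = object)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  payload <- tryCatch(readRDS(path), error = function(e) NULL)
  if (!identical(payload$format, "gramconf-checkpoint")) {
    stop("not a gramconf checkpoint: ", path)
  }
  payload$object
}

#' Write / read a Gram-matrix archive
#'
#' A self-describing hierarchical JSON container with one record per
#' molecule: `{id, n, elements, gram}` where `gram` is the row-major
#' flattened N x N Gram matrix (Angstrom^2). Layout is documented so other
#' tools can read it.
#'
#' @param graphs List of [molecular_graph()] with conformers, list of
#'   conformers, or named list of `"gram_matrix"` objects.
#' @param path Destination `.json` file.
#' @return `path` invisibly; `read_gram_archive` returns a named list of
#'   `"gram_matrix"` objects.
#' @export
write_gram_archive <- function(graphs, path) {
  recs <- lapply(seq_along(graphs), function(i) {
    g <- graphs[[i]]
    if (inherits(g, "gram_matrix")) {
      list(id = names(graphs)[i] %||% sprintf("mol_%d", i), n = nrow(g),
           elements = attr(g, "elements") %||% rep("C", nrow(g)),
           gram = as.numeric(t(unclass(g))))
    } else {
      conf <- if (inherits(g, "conformer")) g else g$conformer
      if (is.null(conf)) stop("molecule has no conformer")
      gm <- gram_from_coords(conf)
      list(id = if (inherits(g, "conformer")) sprintf("mol_%d", i) else g$id,
           n = nrow(gm), elements = conf$elements,
           gram = as.numeric(t(unclass(gm))))
    }
  })
  jsonlite::write_json(
    list(format = "gramconf-archive", version = 1L, molecules = recs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gram_archive
#' @export
read_gram_archive <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  if (!identical(j$format, "gramconf-archive")) {
    stop("not a gramconf archive: ", path)
  }
  recs <- j$molecules
  if (is.data.frame(recs)) recs <- split(recs, seq_len(nrow(recs)))
  out <- lapply(seq_along(recs), function(i) {
    r <- as.list(recs[[i]])
    n <- as.integer(r$n)
    g <- matrix(unlist(r$gram), n, n, byrow = TRUE)
    structure((g + t(g)) / 2, class = "gram_matrix",
              elements = unlist(r$elements))
  })
  names(out) <- vapply(seq_along(recs), function(i)
    as.character(as.list(recs[[i]])$id), character(1))
  out
}

# --- end-to-end orchestration --------------------------------------------

#' Default small run configuration
#'
#' The fixture-scale configuration used by the package's own tests and
#' examples: a handful of toy molecules, a compact encoder, short training.
#' Noise is off so runs are bit-reproducible.
#'
#' @param seed Integer seed.
#' @return A run-config list accepted by [pregtm_end_to_end()].
#' @export
fixture_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    data = list(source = "toy", n = 10L, max_heavy = 6L),
    split = list(mode = "random", ratios = c(0.6, 0.2, 0.2)),
    stage1 = list(variant = "d",
                  encoder = list(layers = 2L, hidden = 32L, heads = 4L,
                                 noise_sigma = 0),
                  steps = 60L, lr = 3e-3),
    stage2 = list(label = "n_atoms", task = "regression", steps = 60L,
                  lr = 5e-3, readout = "mean",
                  encoder = list(layers = 2L, hidden = 32L, heads = 4L,
                                 noise_sigma = 0))
  )
}

.resolve_encoder_config <- function(lst, seed) {
  base <- encoder_config()
  if (!is.null(lst)) for (nm in names(lst)) base[[nm]] <- lst[[nm]]
  base$seed <- as.integer(seed)
  structure(base, class = "encoder_config")
}

.run_labels <- function(molecules, label_spec) {
  if (is.numeric(label_spec)) return(label_spec)
  if (identical(label_spec, "n_atoms")) {
    return(vapply(molecules, n_atoms, numeric(1)))
  }
  if (identical(label_spec, "n_heavy")) {
    return(vapply(molecules, function(g) sum(g$elements != "H"), numeric(1)))
  }
  stop("unknown label spec: ", label_spec)
}

#' Run the full two-stage pipeline
#'
#' Orchestrates: data (load an SDF or generate toy fixtures) -> split ->
#' stage-1 geometric pretraining -> frozen-embedding extraction -> stage-2
#' property training -> evaluation. Writes checkpoints, metrics and a
#' manifest (seeds, config hash, parameter checksums) into `out_dir` so the
#' run can be reproduced exactly; with `noise_sigma = 0` a rerun is
#' bit-identical.
#'
#' @param config Run-config list (see [fixture_run_config()]) or a YAML file
#'   path with the same structure.
#' @param out_dir Output directory (default: temporary).
#' @return List with `stage1` fit, `property` fit, `report` (stage-1 metric
#'   panel on the test split), `stage2_metric`, `manifest`, `splits`,
#'   `molecules`.
#' @export
pregtm_end_to_end <- function(config = fixture_run_config(),
                              out_dir = tempfile("gramconf_run_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  stage <- "data"
  res <- tryCatch({
    molecules <- if (identical(config$data$source, "sdf")) {
      read_sdf(config$data$path)
    } else {
      generate_toy_molecules(config$data$n %||% 10L,
                             max_heavy = config$data$max_heavy %||% 7L,
                             seed = seed)
    }
    stage <- "split"
    sp <- if (identical(config$split$mode, "scaffold")) {
      scaffold_split(molecules, config$split$ratios %||% c(0.8, 0.1, 0.1))
    } else {
      random_split(molecules, config$split$ratios %||% c(0.8, 0.1, 0.1),
                   seed = seed)
    }
    stage <- "pretrain"
    cfg1 <- .resolve_encoder_config(config$stage1$encoder, seed)
    fit1 <- pregtm(molecules[sp$train],
                   variant = config$stage1$variant %||% "d",
                   config = cfg1, steps = config$stage1$steps %||% 100L,
                   lr = config$stage1$lr %||% 3e-3, seed = seed,
                   val_molecules = if (length(sp$val)) molecules[sp$val])
    stage <- "embed"
    emb <- pregtm_embeddings(fit1, molecules)
    stage <- "property"
    labels <- .run_labels(molecules, config$stage2$label %||% "n_atoms")
    cfg2 <- .resolve_encoder_config(config$stage2$encoder, seed + 1L)
    fit2 <- pregtm_property(fit1, molecules[sp$train], labels[sp$train],
                            task = config$stage2$task %||% "regression",
                            config = cfg2,
                            steps = config$stage2$steps %||% 100L,
                            lr = config$stage2$lr %||% 5e-3, seed = seed,
                            readout = config$stage2$readout %||% "mean")
    stage <- "evaluate"
    test_idx <- if (length(sp$test)) sp$test else sp$train
    report <- evaluation_report(fit1, molecules[test_idx])
    pred2 <- predict(fit2, molecules[test_idx])
    stage2_metric <- if (identical(config$stage2$task %||% "regression",
                                   "regression")) {
      list(metric = "RMSE", value = rmse(labels[test_idx], pred2),
           R2 = tryCatch(r_squared(labels[test_idx], pred2),
                         error = function(e) NA_real_))
    } else {
      list(metric = "AUC-ROC", value = auc_roc(labels[test_idx], pred2))
    }
    list(molecules = molecules, splits = sp, stage1 = fit1, embeddings = emb,
         property = fit2, report = report, stage2_metric = stage2_metric)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)))
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("gramconf")),
    seed = seed,
    config = config,
    stage1_checksum = param_checksum(res$stage1$encoder$params),
    stage2_checksum = param_checksum(res$property$params),
    stage1_final_loss = res$stage1$history$train_loss[
      nrow(res$stage1$history)],
    stage2_metric = res$stage2_metric,
    gram_mae = res$report$summary$gram$MAE,
    mean_rmsd = res$report$summary$rmsd$mean
  )
  manifest$manifest_hash <- param_checksum(list(
    h = c(seed, manifest$stage1_final_loss, manifest$gram_mae,
          manifest$mean_rmsd, manifest$stage2_metric$value)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  save_checkpoint(res$stage1, file.path(out_dir, "stage1.ckpt"))
  write_metric_report(res$report, file.path(out_dir, "report"))
  res$manifest <- manifest
  res$out_dir <- out_dir
  res
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC for binary labels.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) stop("need both classes for AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
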