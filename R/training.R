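#' @title Losses, metrics, splits, and training loops
#' @description Desk-scale training and evaluation for the three tasks:
#'   binary cross-entropy for occurrence, focal loss for the imbalanced
#'   residue-level site task, mean-squared error on p-affinity for
#'   affinity regression; plus the standard classification/regression
#'   metric panel and reproducible dataset splitting.
#' @name training
NULL

#' Transform a molar affinity to a p-affinity score
#'
#' \code{-log10(value / 1 M)}: 1 µM becomes 6, 1 nM becomes 9. Ki, Kd and
#' IC50 measurements are pooled on this common scale.
#'
#' @param value molar concentration(s), must be positive.
#' @return numeric p-affinity (dimensionless).
#' @examples
#' paffinity(1e-6) # 6
#' @export
paffinity <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("affinity values must be positive molar concentrations")
  }
  -log10(value)
}

#' Focal loss for imbalanced binary classification
#'
#' Mean over elements of \code{-w (1 - p_t)^gamma log(p_t)} where
#' \code{p_t} is the probability assigned to the true class and
#' \code{w = alpha} for positives, \code{1 - alpha} for negatives. With
#' \code{gamma = 0, alpha = 0.5} this is half the binary cross-entropy.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels binary labels (0/1), same length.
#' @param alpha positive-class weight in \[0, 1\].
#' @param gamma focusing exponent (>= 0); larger down-weights easy examples.
#' @return scalar loss.
#' @export
focal_loss <- function(probs, labels, alpha = 0.25, gamma = 2) {
  if (length(probs) != length(labels)) {
    stop("probs and labels must have equal length")
  }
  if (any(probs <= 0 | probs >= 1)) {
    warning("probabilities outside (0, 1) clipped at 1e-7")
    probs <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  }
  pt <- ifelse(labels == 1, probs, 1 - probs)
  w <- ifelse(labels == 1, alpha, 1 - alpha)
  mean(-w * (1 - pt)^gamma * log(pt))
}

#' Binary cross-entropy
#' @inheritParams focal_loss
#' @export
bce_loss <- function(probs, labels) {
  probs <- pmin(pmax(probs, 1e-7), 1 - 1e-7)
  mean(-(labels * log(probs) + (1 - labels) * log(1 - probs)))
}

## tape-side losses -------------------------------------------------------

bce_loss_f <- function(p, y) {
  yc <- ad_leaf(matrix(y, ncol = 1L), track = FALSE)
  pc <- ad_clip(p, 1e-7, 1 - 1e-7)
  term <- ad_add(ad_mul(yc, ad_log(pc)),
                 ad_mul(ad_one_minus(yc), ad_log(ad_one_minus(pc))))
  ad_smul(ad_mean_all(term), -1)
}

focal_loss_f <- function(p, y, alpha, gamma) {
  w <- ifelse(y == 1, alpha, 1 - alpha)
  wc <- ad_leaf(matrix(w, ncol = 1L), track = FALSE)
  yc <- ad_leaf(matrix(y, ncol = 1L), track = FALSE)
  pc <- ad_clip(p, 1e-7, 1 - 1e-7)
  pt <- ad_add(ad_mul(yc, pc), ad_mul(ad_one_minus(yc), ad_one_minus(pc)))
  mod <- ad_pow_const(ad_one_minus(pt), gamma)
  ad_smul(ad_mean_all(ad_mul(wc, ad_mul(mod, ad_log(pt)))), -1)
}

mse_loss_f <- function(pred, target) {
  tc <- ad_leaf(matrix(target, nrow(pred$value), ncol(pred$value)),
                track = FALSE)
  ad_mean_all(ad_pow_const(ad_sub(pred, tc), 2))
}

## ---- metrics ------------------------------------------------------------

#' Rank-based area under the ROC curve
#' @param scores predicted scores.
#' @param labels binary labels.
#' @return AUROC in \[0,1\], or NA if only one class is present.
#' @export
auroc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise integration over distinct score thresholds, processing tied
#' scores as blocks.
#' @inheritParams auroc
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0L || n1 == length(labels)) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(1 - y)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Compute the evaluation metric panel for a task
#'
#' Classification (occurrence, site): MCC, F1, Accuracy, Specificity at a
#' 0.5 threshold, plus threshold-free AUROC and AUPRC. Regression
#' (affinity): RMSE, MAE, Pearson and Spearman correlation.
#'
#' @param predictions predicted probabilities or values.
#' @param labels observed labels / values.
#' @param task "occurrence", "site" or "affinity".
#' @return a \code{tribind_metrics} list.
#' @export
compute_metrics <- function(predictions, labels,
                            task = c("occurrence", "site", "affinity")) {
  task <- match.arg(task)
  if (!length(predictions) || length(predictions) != length(labels)) {
    stop("predictions and labels must be nonempty and aligned")
  }
  if (task == "affinity") {
    res <- sqrt(mean((predictions - labels)^2))
    out <- list(task = task,
                RMSE = res,
                MAE = mean(abs(predictions - labels)),
                Pearson = suppressWarnings(stats::cor(predictions, labels)),
                Spearman = suppressWarnings(
                  stats::cor(predictions, labels, method = "spearman")),
                n = length(labels))
  } else {
    hard <- as.integer(predictions >= 0.5)
    tp <- sum(hard == 1 & labels == 1)
    tn <- sum(hard == 0 & labels == 0)
    fp <- sum(hard == 1 & labels == 0)
    fn <- sum(hard == 0 & labels == 1)
    denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    out <- list(task = task,
                MCC = mcc, F1 = f1,
                Accuracy = (tp + tn) / length(labels),
                Specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
                AUROC = auroc(predictions, labels),
                AUPRC = auprc(predictions, labels),
                n = length(labels))
  }
  structure(out, class = "tribind_metrics")
}

#' @export
print.tribind_metrics <- function(x, ...) {
  cat("metrics (", x$task, ", n = ", x$n, "):\n", sep = "")
  for (nm in setdiff(names(x), c("task", "n"))) {
    cat(sprintf("  %-12s %.4f\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Split records into train/validation/test sets
#'
#' Random, disjoint and exhaustive split at the given ratios (default
#' 7:1:2), reproducible for a given seed; set sizes are within one of the
#' exact proportions.
#'
#' @param records a list (or vector) of records.
#' @param ratios length-3 positive weights.
#' @param seed integer RNG seed.
#' @return list with \code{train}, \code{val}, \code{test} index vectors.
#' @export
split_dataset <- function(records, ratios = c(7, 1, 2), seed = 1L) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n < 3L) stop("need at least 3 records to split")
  w <- ratios / sum(ratios)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  idx <- sample.int(n)
  n_tr <- round(n * w[1])
  n_val <- round(n * w[2])
  if (n_tr + n_val >= n) {
    n_val <- max(0L, n - n_tr - 1L)
  }
  list(train = sort(idx[seq_len(n_tr)]),
       val = sort(idx[n_tr + seq_len(n_val)]),
       test = sort(idx[(n_tr + n_val + 1L):n]))
}

#' Read per-residue binding-site labels
#'
#' Label files list binding residues one per line as
#' \code{<chain>:<resnum><icode?>}; every listed residue gets label 1,
#' all others 0.
#'
#' @param path label file (may be empty).
#' @param structure the matching \code{tribind_structure}.
#' @param strict if TRUE, a listed residue absent from the structure is an
#'   error; if FALSE it is skipped with a warning.
#' @return integer 0/1 vector aligned with residue order.
#' @export
read_site_labels <- function(path, structure, strict = TRUE) {
  n <- n_residues(structure)
  lab <- integer(n)
  ln <- readLines(path, warn = FALSE)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  if (!length(ln)) return(lab)
  sel <- as_residue_selection(ln)
  rkey <- paste(structure$residues$chain, structure$residues$resno,
                structure$residues$insert, sep = "|")
  skey <- paste(sel$chain, sel$resno, sel$insert, sep = "|")
  idx <- match(skey, rkey)
  if (anyNA(idx)) {
    missing <- skey[is.na(idx)]
    if (strict) {
      stop("label file lists residue(s) absent from the structure: ",
           paste(missing, collapse = ", "))
    }
    warning("skipping ", length(missing),
            " label residue(s) absent from the structure")
    idx <- idx[!is.na(idx)]
  }
  lab[idx] <- 1L
  lab
}

## ---- training -----------------------------------------------------------

## forward pass + loss for one featurized sample; returns list(loss, pred)
sample_forward <- function(sample, P, config, task, loss_type,
                           train = FALSE) {
  Hd <- encode_drug_f(sample$dgraph, P, config)
  if (task == "affinity") {
    Hp <- encode_protein_f(sample$pgraph, P, config)
    pred <- predict_affinity_f(Hp, Hd, sample$hetero, P, config, train)
    return(list(loss = mse_loss_f(pred, sample$label), pred = pred))
  }
  Hp <- encode_protein_f(sample$pgraph, P, config)
  if (task == "occurrence") {
    out <- predict_occurrence_f(Hp, Hd, P, config, train)
    list(loss = bce_loss_f(out$prob, sample$label), pred = out$prob)
  } else {
    p <- predict_sites_f(Hp, Hd, P, config, train)
    loss <- if (loss_type == "bce") bce_loss_f(p, sample$label)
            else focal_loss_f(p, sample$label, config$focal_alpha,
                              config$focal_gamma)
    list(loss = loss, pred = p)
  }
}

#' Initialize the full parameter set for a task
#'
#' Protein and drug encoder parameters plus the task head.
#' @param task "occurrence", "site" or "affinity".
#' @param config a [model_config()].
#' @param in_dim protein node feature width.
#' @export
init_task_params <- function(task, config, in_dim = 1024L) {
  head <- switch(task,
                 occurrence = init_occurrence_params(config),
                 site = init_site_params(config),
                 affinity = init_affinity_params(config),
                 stop("unknown task: ", task))
  c(init_protein_encoder_params(config, in_dim),
    init_drug_encoder_params(config), head)
}

#' Train a task model
#'
#' Full-batch-of-minibatches Adam training over featurized samples (see
#' [featurize_complex()] / [make_task_dataset()]). Losses: binary
#' cross-entropy (occurrence), focal loss (site; plain cross-entropy
#' available for comparison), mean-squared error on p-affinity (affinity).
#' With a validation set, the best-validation parameters are retained and
#' training stops early after \code{config$patience} epochs without
#' improvement.
#'
#' @param task "occurrence", "site" or "affinity".
#' @param dataset list of featurized samples (each with \code{pgraph},
#'   \code{dgraph}, \code{label}, and \code{hetero} for affinity).
#' @param config a [model_config()].
#' @param val_dataset optional validation samples.
#' @param site_loss "focal" (default) or "bce", site task only.
#' @param verbose print the loss every 25 epochs.
#' @return a \code{tribind_model}: list with \code{params}, \code{config},
#'   \code{task}, \code{history} (per-epoch training loss), and
#'   \code{metrics} (training-set metric panel).
#' @export
train_task <- function(task, dataset, config = model_config(),
                       val_dataset = NULL, site_loss = "focal",
                       verbose = FALSE) {
  task <- match.arg(task, c("occurrence", "site", "affinity"))
  if (!length(dataset)) stop("empty training dataset")
  set.seed(config$seed)
  in_dim <- ncol(dataset[[1]]$pgraph$node_features)
  params <- init_task_params(task, config, in_dim)
  state <- adam_init(params)
  history <- numeric(config$epochs)
  best_val <- Inf; best_params <- params; wait <- 0L
  nb <- max(1L, ceiling(length(dataset) / config$batch_size))
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(length(dataset))
    ep_loss <- 0
    for (b in seq_len(nb)) {
      ids <- ord[seq.int(b, length(ord), by = nb)]
      acc <- NULL
      for (s in ids) {
        ad_reset()
        P <- ad_wrap_params(params)
        fw <- sample_forward(dataset[[s]], P, config, task, site_loss,
                             train = TRUE)
        lv <- as.numeric(fw$loss$value)
        if (!is.finite(lv)) {
          stop("non-finite loss at epoch ", epoch, ", sample ", s,
               "; aborting (task=", task, ", lr=", config$lr, ")")
        }
        ep_loss <- ep_loss + lv
        ad_backward(fw$loss)
        g <- ad_grads(P)
        acc <- if (is.null(acc)) g else Map(`+`, acc, g)
      }
      acc <- lapply(acc, function(m) m / length(ids))
      upd <- adam_step(params, acc, state, lr = config$lr)
      params <- upd$params; state <- upd$state
    }
    history[epoch] <- ep_loss / length(dataset)
    if (verbose && (epoch %% 25L == 0L || epoch == 1L)) {
      message(sprintf("epoch %4d  loss %.5f", epoch, history[epoch]))
    }
    if (!is.null(val_dataset)) {
      vl <- evaluate_loss(task, val_dataset, params, config, site_loss)
      if (vl < best_val - 1e-8) {
        best_val <- vl; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          history <- history[seq_len(epoch)]
          break
        }
      }
    }
  }
  if (!is.null(val_dataset)) params <- best_params
  preds <- predict_dataset(task, dataset, params, config)
  labels <- unlist(lapply(dataset, `[[`, "label"))
  model <- structure(list(params = params, config = config, task = task,
                          history = history,
                          metrics = compute_metrics(preds, labels, task)),
                     class = "tribind_model")
  ad_reset()
  model
}

evaluate_loss <- function(task, dataset, params, config, site_loss) {
  tot <- 0
  for (s in dataset) {
    ad_reset()
    P <- ad_wrap_params(params)
    fw <- sample_forward(s, P, config, task, site_loss, train = FALSE)
    tot <- tot + as.numeric(fw$loss$value)
  }
  ad_reset()
  tot / length(dataset)
}

#' Predict over a featurized dataset
#'
#' @param task task name.
#' @param dataset list of featurized samples.
#' @param params trained parameter list (or a \code{tribind_model}).
#' @param config a [model_config()].
#' @return numeric vector of predictions (site predictions concatenated in
#'   sample order).
#' @export
predict_dataset <- function(task, dataset, params, config = model_config()) {
  if (inherits(params, "tribind_model")) {
    config <- params$config
    params <- params$params
  }
  out <- lapply(dataset, function(s) {
    ad_reset()
    P <- ad_wrap_params(params)
    fw <- sample_forward(s, P, config, task, "focal", train = FALSE)
    as.numeric(fw$pred$value)
  })
  ad_reset()
  unlist(out)
}

#' @export
print.tribind_model <- function(x, ...) {
  cat("tribind_model (", x$task, "), trained ", length(x$history),
      " epochs, final loss ", sprintf("%.5f", utils::tail(x$history, 1)),
      "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' @param model a \code{tribind_model}.
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "tribind-checkpoint-v1",
               task = model$task,
               params = model$params,
               config = unclass(model$config),
               history = model$history), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "tribind-checkpoint-v1")) {
    stop("not a tribind checkpoint: ", path)
  }
  structure(list(params = x$params,
                 config = do.call(model_config, x$config),
                 task = x$task, history = x$history, metrics = NULL),
            class = "tribind_model")
}
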