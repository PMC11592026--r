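#' Network architecture specification
#'
#' Five sequential one-dimensional convolutional layers mapping the K x 37
#' feature matrix to K x 2 (sine, cosine) outputs for any chain length, with
#' zero-padded same-length convolutions. The default is the method's reference
#' architecture (1024 kernels of sizes 11, 9, 5, 3 and a final pair of
#' 1-kernels); \code{n_kernels} scales the hidden width for CPU-sized
#' experiments without changing depth or kernel sizes.
#'
#' @param n_kernels Hidden-layer width (number of kernels per hidden layer).
#' @param kernel_sizes Odd kernel sizes of the five layers.
#' @param activation Hidden nonlinearity (only \code{"relu"} implemented);
#'   the final layer is linear.
#' @return List of class \code{network_spec} with per-layer
#'   \code{(n_kernels, kernel_size)} and the activation.
#' @export
network_spec <- function(n_kernels = 1024,
                         kernel_sizes = c(11, 9, 5, 3, 1),
                         activation = "relu") {
  stopifnot(length(kernel_sizes) == 5, all(kernel_sizes %% 2 == 1))
  layers <- lapply(seq_len(5), function(i) {
    list(n_kernels = if (i < 5) n_kernels else 2L,
         kernel_size = as.integer(kernel_sizes[i]))
  })
  structure(list(layers = layers, activation = activation, n_features = 37L),
            class = "network_spec")
}

#' Build an untrained lambda-prediction network
#'
#' Weights use He-style initialization; a fixed seed gives a bitwise
#' reproducible model.
#'
#' @param spec A \code{\link{network_spec}}.
#' @param seed Integer RNG seed for the initialization.
#' @return Object of class \code{lambda_net}: the spec plus a list of layer
#'   weights \code{W} ((kernel_size * c_in) x c_out) and biases \code{b}.
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  if (!identical(spec$activation, "relu"))
    stop("configuration error: unsupported activation '", spec$activation, "'")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  c_in <- spec$n_features
  layers <- lapply(spec$layers, function(ly) {
    fan_in <- ly$kernel_size * c_in
    W <- matrix(stats::rnorm(fan_in * ly$n_kernels, sd = sqrt(2 / fan_in)),
                fan_in, ly$n_kernels)
    b <- rep(0, ly$n_kernels)
    c_in <<- ly$n_kernels
    list(W = W, b = b, k = ly$kernel_size)
  })
  structure(list(spec = spec, layers = layers, seed = seed,
                 trained = FALSE, provenance = NULL),
            class = "lambda_net")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.lambda_net <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), numeric(1)))
  cat("lambda_net: 5 conv layers,",
    paste(vapply(x$spec$layers, function(l)
      sprintf("%dx%d", l$n_kernels, l$kernel_size), character(1)),
      collapse = " -> "),
    sprintf("(%d parameters)%s\n", np, if (x$trained) ", trained" else ""))
  invisible(x)
}

# Zero-padded patch matrix: row i holds the length-k window of X centred on
# position i, flattened (offset-major). X is K x C.
im2col <- function(X, k) {
  K <- nrow(X); C <- ncol(X)
  pad <- (k - 1L) %/% 2L
  P <- matrix(0, K, k * C)
  for (t in seq_len(k)) {
    off <- t - 1L - pad
    src <- seq_len(K) + off
    ok <- src >= 1L & src <= K
    P[ok, ((t - 1L) * C + 1L):(t * C)] <- X[src[ok], , drop = FALSE]
  }
  P
}

# Scatter gradient of the patch matrix back onto X.
col2im <- function(dP, k, K, C) {
  pad <- (k - 1L) %/% 2L
  dX <- matrix(0, K, C)
  for (t in seq_len(k)) {
    off <- t - 1L - pad
    src <- seq_len(K) + off
    ok <- src >= 1L & src <= K
    dX[src[ok], ] <- dX[src[ok], ] +
      dP[ok, ((t - 1L) * C + 1L):(t * C), drop = FALSE]
  }
  dX
}

# Forward pass; with cache = TRUE also returns per-layer patch matrices and
# pre-activations for backprop.
net_forward <- function(model, X, cache = FALSE) {
  A <- X
  caches <- if (cache) vector("list", length(model$layers)) else NULL
  nl <- length(model$layers)
  for (li in seq_len(nl)) {
    ly <- model$layers[[li]]
    P <- im2col(A, ly$k)
    Z <- P %*% ly$W
    Z <- sweep(Z, 2, ly$b, "+")
    A_next <- if (li < nl) pmax(Z, 0) else Z
    if (cache) caches[[li]] <- list(P = P, Z = Z, c_in = ncol(A))
    A <- A_next
  }
  if (cache) list(out = A, caches = caches) else A
}

# Backward pass: returns per-layer gradients, given dOut = dLoss/dOutput.
net_backward <- function(model, caches, dOut) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  dA <- dOut
  for (li in rev(seq_len(nl))) {
    ly <- model$layers[[li]]
    cc <- caches[[li]]
    dZ <- if (li < nl) dA * (cc$Z > 0) else dA
    grads[[li]] <- list(dW = crossprod(cc$P, dZ), db = colSums(dZ))
    if (li > 1) {
      dP <- dZ %*% t(ly$W)
      dA <- col2im(dP, ly$k, nrow(dZ), cc$c_in)
    }
  }
  grads
}

#' Recover lambda angles from (sine, cosine) channel pairs
#'
#' Quadrant-aware arctangent of the two network output channels; invariant
#' to positive rescaling of a pair, so the outputs need not lie on the unit
#' circle. Pairs with both components (numerically) zero are undefined.
#'
#' @param pairs K x 2 matrix, columns (sin, cos).
#' @return A \code{\link{lambda_series}} of length K with the undefined mask
#'   set for degenerate pairs.
#' @export
angles_from_sincos <- function(pairs) {
  pairs <- matrix(pairs, ncol = 2)
  if (!all(is.finite(pairs))) stop("sin/cos estimates must be finite")
  degen <- rowSums(pairs^2) < 1e-24
  v <- wrap_angle(atan2(pairs[, 1], pairs[, 2]))
  v[degen] <- NA_real_
  lambda_series(v, defined = !degen)
}

#' Build training pairs from full-atom chains
#'
#' For each accepted chain: the K x 37 feature matrix computed from the CA
#' trace, and K x 2 targets (sin, cos) of the true lambda extracted from the
#' experimental backbone. Network output row i corresponds to plate i-1
#' (between CA(i-1) and CA(i)), so row 1 is always masked; the mask is also
#' false wherever lambda is undefined.
#'
#' @param chains List whose elements are either atom-record data frames from
#'   \code{\link{read_structure}} or \code{synthetic_chain} objects.
#' @param constants Geometry table from \code{\link{ideal_geometry}}.
#' @param quality_filter Apply \code{\link{chain_quality_filter}} to
#'   atom-record chains and skip rejected ones (with a message).
#' @return List of class \code{training_set}; each element has \code{X}
#'   (K x 37), \code{Y} (K x 2 sin/cos), \code{mask} (logical K).
#' @export
make_training_pairs <- function(chains, constants = ideal_geometry(),
                                quality_filter = TRUE) {
  out <- list()
  for (ch in chains) {
    if (inherits(ch, "synthetic_chain")) {
      trace <- ch$trace
      lam <- ch$lambda
    } else if (inherits(ch, "backbone_structure")) {
      trace <- backbone_to_trace(ch)
      lam <- lambda_from_backbone(ch, constants)
    } else {
      if (quality_filter) {
        rep_q <- chain_quality_filter(ch, constants)
        if (!rep_q$accepted) {
          message("skipping chain ", attr(ch, "chain_id") %||% "?", ": ",
                  paste(rep_q$reasons, collapse = ", "))
          next
        }
      }
      bb <- as_backbone(ch)
      trace <- backbone_to_trace(bb)
      lam <- lambda_from_backbone(bb, constants)
    }
    K <- nrow(trace$xyz)
    X <- unclass(build_feature_matrix(trace))
    Y <- matrix(0, K, 2)
    mask <- rep(FALSE, K)
    def <- lam$defined
    Y[which(def) + 1L, ] <- cbind(sin(lam$values[def]), cos(lam$values[def]))
    mask[which(def) + 1L] <- TRUE
    out[[length(out) + 1L]] <- list(X = X, Y = Y, mask = mask)
  }
  if (!length(out)) stop("no accepted chains: empty training set")
  structure(out, class = "training_set")
}

backbone_to_trace <- function(bb) {
  ca_trace(bb$sequence, bb$ca, chain_id = bb$chain_id, resno = bb$resno)
}

#' Training configuration
#'
#' @param seed RNG seed controlling shuffling (and nothing else).
#' @param epochs Maximum passes over the training chains.
#' @param lr Adam learning rate.
#' @param validation_fraction Fraction of chains held out for validation /
#'   early stopping.
#' @param patience Early-stopping patience in epochs (0 disables).
#' @param log_file Optional TSV path receiving per-epoch losses.
#' @return List of class \code{training_config}.
#' @export
training_config <- function(seed = 1, epochs = 50, lr = 1e-3,
                            validation_fraction = 0.1, patience = 10,
                            log_file = NULL) {
  structure(list(seed = seed, epochs = epochs, lr = lr,
                 validation_fraction = validation_fraction,
                 patience = patience, log_file = log_file),
            class = "training_config")
}

masked_mse <- function(pred, Y, mask) {
  n <- sum(mask)
  if (n == 0) return(NA_real_)
  sum((pred[mask, , drop = FALSE] - Y[mask, , drop = FALSE])^2) / (2 * n)
}

#' Train the lambda network
#'
#' Minimizes the mean squared error of the (sin, cos) channels over masked
#' residues with Adam, one chain per step (chains have variable length).
#' Keeps the weights with the best validation loss; with a fixed seed the
#' run is reproducible.
#'
#' @param model A \code{\link{build_network}} model.
#' @param dataset A \code{training_set} from \code{\link{make_training_pairs}}.
#' @param config A \code{\link{training_config}}.
#' @return The trained \code{lambda_net} (best-validation weights) with a
#'   \code{history} data frame of per-epoch train/validation losses.
#' @export
train_network <- function(model, dataset, config = training_config()) {
  stopifnot(inherits(model, "lambda_net"), length(dataset) > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  n <- length(dataset)
  n_val <- if (n >= 5 && config$validation_fraction > 0)
    max(1L, round(config$validation_fraction * n)) else 0L
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)
  adam <- lapply(model$layers, function(ly) {
    list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
  })
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0L
  best <- list(loss = Inf, layers = model$layers)
  history <- data.frame(epoch = integer(0), train = numeric(0),
                        val = numeric(0))
  stale <- 0L
  for (ep in seq_len(config$epochs)) {
    ep_loss <- 0; ep_n <- 0
    for (i in sample(tr_idx)) {
      d <- dataset[[i]]
      if (!any(d$mask)) next
      fw <- net_forward(model, d$X, cache = TRUE)
      nm <- sum(d$mask)
      resid <- (fw$out - d$Y)
      resid[!d$mask, ] <- 0
      loss <- sum(resid^2) / (2 * nm)
      if (!is.finite(loss)) stop("training error: non-finite loss at epoch ",
                                 ep, ", chain ", i)
      dOut <- resid / nm
      grads <- net_backward(model, fw$caches, dOut)
      t <- t + 1L
      for (li in seq_along(model$layers)) {
        g <- grads[[li]]
        a <- adam[[li]]
        a$mW <- b1 * a$mW + (1 - b1) * g$dW
        a$vW <- b2 * a$vW + (1 - b2) * g$dW^2
        a$mb <- b1 * a$mb + (1 - b1) * g$db
        a$vb <- b2 * a$vb + (1 - b2) * g$db^2
        adam[[li]] <- a
        corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
        model$layers[[li]]$W <- model$layers[[li]]$W -
          config$lr * (a$mW / corr1) / (sqrt(a$vW / corr2) + eps)
        model$layers[[li]]$b <- model$layers[[li]]$b -
          config$lr * (a$mb / corr1) / (sqrt(a$vb / corr2) + eps)
      }
      ep_loss <- ep_loss + loss; ep_n <- ep_n + 1L
    }
    train_loss <- ep_loss / max(1L, ep_n)
    val_loss <- if (length(val_idx)) {
      mean(vapply(val_idx, function(i) {
        d <- dataset[[i]]
        masked_mse(net_forward(model, d$X), d$Y, d$mask)
      }, numeric(1)), na.rm = TRUE)
    } else train_loss
    history <- rbind(history,
                     data.frame(epoch = ep, train = train_loss, val = val_loss))
    if (is.finite(val_loss) && val_loss < best$loss - 1e-7) {
      best <- list(loss = val_loss, layers = model$layers)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (config$patience > 0 && stale >= config$patience) break
    }
  }
  model$layers <- best$layers
  model$trained <- TRUE
  model$provenance <- list(config = config[c("seed", "epochs", "lr",
                                             "validation_fraction", "patience")],
                           n_chains = n, best_val_loss = best$loss)
  model$history <- history
  if (!is.null(config$log_file))
    utils::write.table(history, config$log_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  model
}

#' Predict the lambda series for a CA trace or feature matrix
#'
#' Runs the network forward pass and converts the (sin, cos) channels to
#' angles. Output rows 2..K map to plates 1..K-1 (plate p between CA(p) and
#' CA(p+1) is predicted at residue p+1); row 1 has no plate.
#'
#' @param model A trained \code{lambda_net}.
#' @param x A \code{\link{ca_trace}} or a K x 37 feature matrix.
#' @return A \code{\link{lambda_series}} of length K-1 (with isomers from
#'   the trace when a trace is supplied).
#' @export
predict_lambda <- function(model, x) {
  stopifnot(inherits(model, "lambda_net"))
  isomers <- NULL
  if (inherits(x, "ca_trace")) {
    trace <- x
    X <- unclass(build_feature_matrix(trace))
    K <- nrow(X)
    d <- sqrt(rowSums((trace$xyz[-1, , drop = FALSE] -
                       trace$xyz[-K, , drop = FALSE])^2))
    isomers <- classify_isomer(d)
  } else {
    X <- unclass(x)
  }
  if (ncol(X) != model$spec$n_features)
    stop("configuration error: feature layout (", ncol(X),
         " columns) does not match the network (",
         model$spec$n_features, ")")
  out <- net_forward(model, X)
  ang <- angles_from_sincos(out)
  lambda_series(ang$values[-1], ang$defined[-1], isomers)
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint carrying a version header, the architecture spec
#' and the weights; \code{load_model} refuses files with a different format
#' version and reproduces predictions exactly.
#'
#' @param model A \code{lambda_net}.
#' @param path Checkpoint path.
#' @return \code{save_model}: invisibly the path; \code{load_model}: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "lambda_net"))
  obj <- list(format = "replate-checkpoint", version = 1L,
              n_features = model$spec$n_features, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("cannot read checkpoint: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "replate-checkpoint") || !identical(obj$version, 1L))
    stop("configuration error: not a recognized checkpoint file: ", path)
  obj$model
}
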