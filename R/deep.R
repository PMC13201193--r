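# Residual-network embedding streams. Convolutions are evaluated with
# im2col + BLAS matrix products; weights use seeded He initialization.
# Desk-scale regime: the convolutional trunk stays at its (seeded) random
# initialization acting as a deep structured projection, normalization
# layers are identity at unit running statistics, and the 2-way
# classification head is trained by gradient descent on the pooled
# embeddings. Embedding width is fixed by depth: 512 (depth 18) or 2048
# (depths 50/101) from the global average pool before the head.

#' Residual network specification
#'
#' @param depth one of 18, 50, 101.
#' @param mode input mode: "2D", "2.5D" (3-channel planar) or "3D"
#'   (single-channel volumetric convolutions).
#' @param input_side input side length (default 224 planar / 64 cube).
#' @return object of class `net_spec` with `embedding_dim` (512 for depth
#'   18, 2048 for depths 50 and 101).
#' @export
net_spec <- function(depth = 50, mode = c("2.5D", "2D", "3D"), input_side = NULL) {
  mode <- match.arg(mode)
  assert_that(depth %in% c(18, 50, 101), "unsupported depth")
  if (is.null(input_side)) input_side <- if (mode == "3D") 64L else 224L
  structure(list(depth = depth, mode = mode,
                 input_side = as.integer(input_side),
                 channels = if (mode == "3D") 1L else 3L,
                 embedding_dim = if (depth == 18) 512L else 2048L),
            class = "net_spec")
}

he_weights <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

make_conv <- function(k, c_in, c_out, stride, pad, nd) {
  dims <- if (nd == 2) c(k, k, c_in, c_out) else c(k, k, k, c_in, c_out)
  fan_in <- k^nd * c_in
  list(w = he_weights(dims, fan_in), stride = stride, pad = pad)
}

#' Build a residual network
#'
#' Standard residual architecture of the requested depth (basic blocks for
#' depth 18; bottleneck blocks for 50/101) with a 2-way classifier head.
#' The penultimate layer is a global average pool producing
#' `spec$embedding_dim` features. Weights are seeded He draws so the model
#' is fully reproducible from (spec, seed).
#'
#' @param spec a [net_spec()].
#' @param seed integer seed for initialization.
#' @return object of class `resnet`.
#' @export
build_network <- function(spec, seed = 1L) {
  assert_that(inherits(spec, "net_spec"), "spec must be a net_spec")
  nd <- if (spec$mode == "3D") 3L else 2L
  cfg <- switch(as.character(spec$depth),
                `18` = list(block = "basic", reps = c(2, 2, 2, 2)),
                `50` = list(block = "bottleneck", reps = c(3, 4, 6, 3)),
                `101` = list(block = "bottleneck", reps = c(3, 4, 23, 3)))
  expansion <- if (cfg$block == "basic") 1L else 4L
  planes <- c(64, 128, 256, 512)
  with_seed(seed, {
    stem <- make_conv(7, spec$channels, 64L, stride = 2, pad = 3, nd = nd)
    in_ch <- 64L
    stages <- list()
    for (s in 1:4) {
      blocks <- list()
      for (b in seq_len(cfg$reps[s])) {
        stride <- if (b == 1 && s > 1) 2L else 1L
        out_ch <- planes[s] * expansion
        convs <- if (cfg$block == "basic") {
          list(make_conv(3, in_ch, planes[s], stride, 1, nd),
               make_conv(3, planes[s], planes[s], 1, 1, nd))
        } else {
          list(make_conv(1, in_ch, planes[s], 1, 0, nd),
               make_conv(3, planes[s], planes[s], stride, 1, nd),
               make_conv(1, planes[s], out_ch, 1, 0, nd))
        }
        down <- if (stride != 1 || in_ch != out_ch) {
          make_conv(1, in_ch, out_ch, stride, 0, nd)
        } else NULL
        blocks[[b]] <- list(convs = convs, down = down)
        in_ch <- out_ch
      }
      stages[[s]] <- blocks
    }
    head_w <- matrix(stats::rnorm(in_ch * 2, sd = sqrt(1 / in_ch)), in_ch, 2)
    structure(list(spec = spec, nd = nd, stem = stem, stages = stages,
                   head_w = head_w, head_b = c(0, 0), seed = seed),
              class = "resnet")
  })
}

pad_nd <- function(x, pad, nd) {
  if (pad == 0) return(x)
  d <- dim(x)
  if (nd == 2) {
    out <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3]))
    out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  } else {
    out <- array(0, dim = c(d[1] + 2 * pad, d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
    out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  }
  out
}

conv_forward <- function(x, conv, nd) {
  x <- pad_nd(x, conv$pad, nd)
  d <- dim(x)
  wd <- dim(conv$w)
  k <- wd[1]
  s <- conv$stride
  if (nd == 2) {
    C <- wd[3]; K <- wd[4]
    ho <- (d[1] - k) %/% s + 1; wo <- (d[2] - k) %/% s + 1
    cols <- matrix(0, ho * wo, k * k * C)
    ci <- 1L
    for (c in seq_len(C)) for (j in seq_len(k)) for (i in seq_len(k)) {
      cols[, ci] <- x[seq(i, by = s, length.out = ho),
                      seq(j, by = s, length.out = wo), c]
      ci <- ci + 1L
    }
    out <- cols %*% matrix(conv$w, k * k * C, K)
    array(out, dim = c(ho, wo, K))
  } else {
    C <- wd[4]; K <- wd[5]
    o1 <- (d[1] - k) %/% s + 1; o2 <- (d[2] - k) %/% s + 1; o3 <- (d[3] - k) %/% s + 1
    cols <- matrix(0, o1 * o2 * o3, k^3 * C)
    ci <- 1L
    for (c in seq_len(C)) for (l in seq_len(k)) for (j in seq_len(k)) for (i in seq_len(k)) {
      cols[, ci] <- x[seq(i, by = s, length.out = o1),
                      seq(j, by = s, length.out = o2),
                      seq(l, by = s, length.out = o3), c]
      ci <- ci + 1L
    }
    out <- cols %*% matrix(conv$w, k^3 * C, K)
    array(out, dim = c(o1, o2, o3, K))
  }
}

maxpool_forward <- function(x, nd, k = 3, s = 2, pad = 1) {
  x <- pad_nd(x, pad, nd)
  d <- dim(x)
  if (nd == 2) {
    ho <- (d[1] - k) %/% s + 1; wo <- (d[2] - k) %/% s + 1
    out <- array(-Inf, dim = c(ho, wo, d[3]))
    for (j in seq_len(k)) for (i in seq_len(k)) {
      out <- pmax(out, x[seq(i, by = s, length.out = ho),
                         seq(j, by = s, length.out = wo), , drop = FALSE])
    }
  } else {
    o1 <- (d[1] - k) %/% s + 1; o2 <- (d[2] - k) %/% s + 1; o3 <- (d[3] - k) %/% s + 1
    out <- array(-Inf, dim = c(o1, o2, o3, d[4]))
    for (l in seq_len(k)) for (j in seq_len(k)) for (i in seq_len(k)) {
      out <- pmax(out, x[seq(i, by = s, length.out = o1),
                         seq(j, by = s, length.out = o2),
                         seq(l, by = s, length.out = o3), , drop = FALSE])
    }
  }
  out
}

relu <- function(x) pmax(x, 0)

block_forward <- function(x, block, nd) {
  out <- x
  nconv <- length(block$convs)
  for (i in seq_len(nconv)) {
    out <- conv_forward(out, block$convs[[i]], nd)
    if (i < nconv) out <- relu(out)
  }
  idn <- if (is.null(block$down)) x else conv_forward(x, block$down, nd)
  relu(out + idn)
}

#' Forward pass through a residual network
#'
#' @param net a [build_network()] result.
#' @param x input array: (side, side, channels) for 2D/2.5D or
#'   (side, side, side, 1) for 3D.
#' @param output "embedding" (global-average-pool features) or "logits".
#' @return numeric vector of length `embedding_dim` or 2.
#' @export
forward_network <- function(net, x, output = c("embedding", "logits")) {
  output <- match.arg(output)
  nd <- net$nd
  assert_that(length(dim(x)) == nd + 1, "input rank mismatch with network mode")
  assert_that(dim(x)[nd + 1] == net$spec$channels, "channel mismatch")
  h <- relu(conv_forward(x, net$stem, nd))
  h <- maxpool_forward(h, nd)
  for (stage in net$stages) {
    for (blk in stage) h <- block_forward(h, blk, nd)
  }
  emb <- apply(h, nd + 1, mean) # global average pool
  if (output == "embedding") return(emb)
  as.numeric(emb %*% net$head_w + net$head_b)
}

#' Deep-learning training configuration
#'
#' Desk-scale defaults: the trunk stays frozen at its seeded random
#' initialization and only the classifier head learns.
#'
#' @param epochs training epochs (<= 20 by design).
#' @param lr learning rate for the head.
#' @param class_weighting logical; weight classes inversely to frequency.
#' @param seed integer seed.
#' @param patience early-stop patience on validation loss.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, lr = 0.5, class_weighting = TRUE,
                         seed = 1L, patience = 5L) {
  assert_that(epochs <= 20, "desk-scale limit: epochs <= 20")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 class_weighting = class_weighting, seed = as.integer(seed),
                 patience = as.integer(patience)),
            class = "train_config")
}

softmax2 <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train the classification head of a residual network
#'
#' Embeds every patch through the frozen trunk, standardizes the pooled
#' embeddings, and trains the 2-way linear head by full-batch gradient
#' descent on class-weighted cross-entropy. The checkpoint with the best
#' validation loss (training loss when no validation set is given) is
#' returned together with per-epoch loss curves.
#'
#' @param net a [build_network()] result.
#' @param patches list of input arrays (training).
#' @param labels binary labels (0/1) for the patches.
#' @param config a [train_config()].
#' @param val_patches,val_labels optional validation set.
#' @return object of class `trained_resnet`: the network, frozen embedding
#'   standardization, trained head, and `loss_curves` (data.frame epoch /
#'   train_loss / val_loss).
#' @export
train_classifier <- function(net, patches, labels, config = train_config(),
                             val_patches = NULL, val_labels = NULL) {
  assert_that(length(unique(labels)) == 2, "degenerate single-class patch stream")
  E <- t(vapply(patches, function(p) forward_network(net, p, "embedding"),
                numeric(net$spec$embedding_dim)))
  mu <- colMeans(E); sdv <- apply(E, 2, stats::sd); sdv[sdv < 1e-12] <- 1
  Es <- sweep(sweep(E, 2, mu), 2, sdv, `/`)
  Ev <- if (!is.null(val_patches)) {
    Vt <- t(vapply(val_patches, function(p) forward_network(net, p, "embedding"),
                   numeric(net$spec$embedding_dim)))
    sweep(sweep(Vt, 2, mu), 2, sdv, `/`)
  } else NULL

  y <- as.integer(labels)
  Y <- cbind(1 - y, y)
  wts <- if (config$class_weighting) {
    length(y) / (2 * table(factor(y, levels = 0:1)))[y + 1]
  } else rep(1, length(y))
  wts <- as.numeric(wts / mean(wts))

  D <- ncol(Es)
  W <- matrix(0, D, 2); b <- c(0, 0)
  bestW <- W; bestb <- b; best_loss <- Inf; bad <- 0
  curves <- data.frame(epoch = integer(0), train_loss = numeric(0),
                       val_loss = numeric(0))
  xent <- function(P, Yl, w) -mean(w * log(pmax(rowSums(P * Yl), 1e-12)))
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      P <- softmax2(Es %*% W + rep(1, nrow(Es)) %o% b)
      G <- (P - Y) * wts / nrow(Es)
      W <- W - config$lr * t(Es) %*% G
      b <- b - config$lr * colSums(G)
      P <- softmax2(Es %*% W + rep(1, nrow(Es)) %o% b)
      tl <- xent(P, Y, wts)
      vl <- if (!is.null(Ev)) {
        Pv <- softmax2(Ev %*% W + rep(1, nrow(Ev)) %o% b)
        xent(Pv, cbind(1 - val_labels, val_labels), rep(1, nrow(Ev)))
      } else NA_real_
      curves <- rbind(curves, data.frame(epoch = ep, train_loss = tl, val_loss = vl))
      mon <- if (is.na(vl)) tl else vl
      if (mon < best_loss - 1e-9) {
        best_loss <- mon; bestW <- W; bestb <- b; bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= config$patience) break
      }
    }
  } else {
    bestW <- W; bestb <- b
  }
  structure(list(net = net, emb_center = mu, emb_scale = sdv,
                 head_w = bestW, head_b = bestb, loss_curves = curves,
                 config = config),
            class = "trained_resnet")
}

#' Predict class-1 probability from a trained network
#'
#' @param object a `trained_resnet`.
#' @param patches list of input arrays.
#' @param ... unused.
#' @return numeric probability vector.
#' @export
predict_resnet <- function(object, patches, ...) {
  E <- t(vapply(patches, function(p) forward_network(object$net, p, "embedding"),
                numeric(object$net$spec$embedding_dim)))
  Es <- sweep(sweep(E, 2, object$emb_center), 2, object$emb_scale, `/`)
  P <- softmax2(Es %*% object$head_w + rep(1, nrow(Es)) %o% object$head_b)
  P[, 2]
}

#' Extract penultimate-pool embeddings as a feature table
#'
#' One row per patch (patient), `embedding_dim` columns named
#' `<mode>_DL_0001` onward. Deterministic for fixed weights; downstream
#' these columns run through the harmonize/select chain and an SVM head.
#'
#' @param net a [build_network()] result (or the `net` of a
#'   `trained_resnet`).
#' @param patches list of input arrays.
#' @return numeric matrix (patients x embedding_dim).
#' @export
extract_embeddings <- function(net, patches) {
  if (inherits(net, "trained_resnet")) net <- net$net
  E <- t(vapply(patches, function(p) forward_network(net, p, "embedding"),
                numeric(net$spec$embedding_dim)))
  colnames(E) <- sprintf("%s_DL_%04d", net$spec$mode, seq_len(ncol(E)))
  E
}

#' Choose the best deep stream by validation AUC
#'
#' Ties break toward the shallower depth, then the lower-dimensional input
#' mode (2D < 2.5D < 3D).
#'
#' @param specs list of [net_spec()] candidates.
#' @param validation_aucs numeric AUCs, same order as `specs`.
#' @return the chosen `net_spec`.
#' @export
select_best_stream <- function(specs, validation_aucs) {
  assert_that(length(specs) > 0, "empty candidate list")
  assert_that(length(specs) == length(validation_aucs), "length mismatch")
  mode_rank <- vapply(specs, function(s) match(s$mode, c("2D", "2.5D", "3D")), 0)
  depth <- vapply(specs, function(s) s$depth, 0)
  ord <- order(-validation_aucs, depth, mode_rank)
  specs[[ord[1]]]
}
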