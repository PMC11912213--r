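# Backward pass for one graph; returns gradients matching the parameter list.
gcn_backward <- function(graph, model, fw, y) {
  d2 <- model$dims$hidden[2]
  heads <- model$dims$heads
  g <- 2 * (fw$score - y) * fw$score * (1 - fw$score) # d loss / d logit
  grad <- list(W0 = NULL, W1 = NULL, Wa = NULL, V = NULL,
               w = g * fw$r, b = g)
  W <- matrix(model$w, nrow = d2)            # d2 x heads
  dR <- g * W                                # d loss / d r_h, columns
  dH2 <- fw$alpha %*% t(dR)                  # pooling path, n x d2
  dAlpha <- fw$H2 %*% dR                     # n x heads
  dS <- fw$alpha * sweep(dAlpha, 2, colSums(fw$alpha * dAlpha))
  grad$V <- t(fw$Tn) %*% dS
  dZ <- (dS %*% t(model$V)) * (1 - fw$Tn^2)
  grad$Wa <- t(fw$H2) %*% dZ
  dH2 <- dH2 + dZ %*% t(model$Wa)
  dM1 <- dH2 * (fw$M1 > 0)
  grad$W1 <- t(fw$AH1) %*% dM1
  dH1 <- t(graph$Ahat) %*% (dM1 %*% t(model$W1))
  dM0 <- dH1 * (fw$M0 > 0)
  grad$W0 <- t(fw$AH0) %*% dM0
  grad
}

#' Train the solubility GCN on labelled graphs
#'
#' Minimizes squared error with mini-batch Adam. Training is deterministic
#' given `seed` (which controls the weight initialization and the shuffling).
#'
#' @param graphs list of `protein_graph`
#' @param labels numeric solubilities in `[0, 1]`, one per graph
#' @param epochs passes over the data
#' @param lr Adam step size
#' @param batch_size mini-batch size
#' @param hidden,d_att,heads architecture (see [init_solubility_model()])
#' @param seed RNG seed
#' @param model optionally continue training an existing model
#' @param verbose print the loss every 10 epochs
#' @return the trained `solubility_model` with a `training_curve` field
#'   (mean squared error per epoch)
#' @export
train_solubility <- function(graphs, labels, epochs = 80, lr = 2e-3,
                             batch_size = 16, hidden = c(32, 32), d_att = 16,
                             heads = 4, seed = 1, model = NULL,
                             verbose = FALSE) {
  stopifnot(length(graphs) == length(labels), length(graphs) >= 50,
            all(labels >= 0 & labels <= 1))
  width <- ncol(graphs[[1]]$H0)
  if (is.null(model))
    model <- init_solubility_model(width, hidden, d_att, heads, seed)
  set.seed(seed + 1)
  pn <- c("W0", "W1", "Wa", "V", "w", "b")
  mom <- lapply(model[pn], function(p) p * 0)
  vel <- lapply(model[pn], function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  curve <- numeric(epochs)
  n <- length(graphs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      acc <- NULL
      for (i in idx) {
        fw <- gcn_forward(graphs[[i]], model)
        ep_loss <- ep_loss + (fw$score - labels[i])^2
        gr <- gcn_backward(graphs[[i]], model, fw, labels[i])
        acc <- if (is.null(acc)) gr else Map("+", acc, gr)
      }
      acc <- lapply(acc, function(g) g / length(idx))
      step <- step + 1
      for (p in pn) {
        mom[[p]] <- beta1 * mom[[p]] + (1 - beta1) * acc[[p]]
        vel[[p]] <- beta2 * vel[[p]] + (1 - beta2) * acc[[p]]^2
        mhat <- mom[[p]] / (1 - beta1^step)
        vhat <- vel[[p]] / (1 - beta2^step)
        model[[p]] <- model[[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    curve[ep] <- ep_loss / n
    if (!is.finite(curve[ep]))
      stop("training diverged (loss is not finite); lower the learning rate")
    if (verbose && ep %% 10 == 0)
      message(sprintf("epoch %d  mse %.5f", ep, curve[ep]))
  }
  model$training_curve <- curve
  model
}

#' Coefficient of determination
#' @param predicted,observed numeric vectors
#' @return R-squared of `predicted` against `observed`
#' @export
r_squared <- function(predicted, observed) {
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}
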