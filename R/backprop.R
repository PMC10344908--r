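# Reverse-mode gradients through the ontology-structured encoder, the drug
# encoder and the head. Training-mode batch-norm statistics are part of the
# differentiated graph (population-variance formulation).

.loss_and_grad_out <- function(stage, pred, O, y) {
  B <- length(y)
  if (stage == "stage1") {
    eps <- 1e-12
    loss <- -mean(y * log(pred + eps) + (1 - y) * log(1 - pred + eps))
    dO <- (pred - y) / B # sigmoid + BCE
  } else {
    loss <- mean((O - y)^2)
    dO <- 2 * (O - y) / B
  }
  list(loss = loss, dO = dO)
}

# Returns list(loss, grads) where grads is a flat list parallel to
# model$par (absent entries mean zero gradient).
vnn_backward <- function(model, fw, y) {
  p <- model$par
  k <- model$config$k_term_neurons
  B <- nrow(fw$head$U)
  lg <- .loss_and_grad_out(model$stage, fw$head$pred, fw$head$O, y)
  grads <- list()
  # ---- head ----
  dO <- matrix(lg$dO, ncol = 1L)
  Hh <- fw$head$Hh
  grads[["head.Wo"]] <- t(Hh) %*% dO
  grads[["head.bo"]] <- sum(dO)
  dHh <- dO %*% t(p[["head.Wo"]])
  dpre <- dHh * (Hh > 0)
  grads[["head.Wh"]] <- t(fw$head$U) %*% dpre
  grads[["head.bh"]] <- colSums(dpre)
  dU <- dpre %*% t(p[["head.Wh"]])
  dEmb <- dU[, seq_len(k), drop = FALSE]
  dE <- dU[, k + seq_len(ncol(dU) - k), drop = FALSE]
  # ---- drug encoder ----
  acts <- fw$drug$acts
  n_layers <- length(model$config$drug_layer_sizes)
  dZ <- dE
  for (i in rev(seq_len(n_layers))) {
    if (i < n_layers) dZ <- dZ * (acts[[i + 1L]] > 0)
    grads[[paste0("drug.W", i)]] <- t(acts[[i]]) %*% dZ
    grads[[paste0("drug.b", i)]] <- colSums(dZ)
    if (i > 1L) dZ <- dZ %*% t(p[[paste0("drug.W", i)]])
  }
  # ---- encoder, parents before children ----
  G <- list()
  G[[model$dag$root]] <- dEmb
  for (t in rev(model$dag$topo_order)) {
    if (is.null(G[[t]])) next
    lo <- model$layout[[t]]
    pre <- function(x) paste0("term.", t, ".", x)
    ca <- fw$enc$caches[[t]]
    H_t <- fw$enc$H[[t]]
    G_Y <- G[[t]] * (1 - H_t^2)
    gamma <- p[[pre("gamma")]]
    grads[[pre("gamma")]] <- colSums(G_Y * ca$Ahat)
    grads[[pre("beta")]] <- colSums(G_Y)
    ghat <- G_Y * rep(gamma, each = B)
    m1 <- colMeans(ghat)
    m2 <- colMeans(ghat * ca$Ahat)
    dA <- (ghat - rep(m1, each = B) - ca$Ahat * rep(m2, each = B)) /
      rep(ca$sd_b, each = B)
    grads[[pre("W")]] <- t(ca$Xcat) %*% dA
    grads[[pre("b")]] <- colSums(dA)
    G_X <- dA %*% t(p[[pre("W")]])
    dAw <- matrix(0, B, lo$m + lo$p)
    if (lo$m > 0L) {
      for (j in seq_len(lo$m)) {
        cols <- (j - 1L) * k + seq_len(k)
        G_Bj <- G_X[, cols, drop = FALSE]
        Hc <- fw$enc$H[[lo$child_terms[j]]]
        dAw[, j] <- rowSums(G_Bj * Hc)
        contrib <- G_Bj * ca$A_w[, j]
        ch <- lo$child_terms[j]
        G[[ch]] <- if (is.null(G[[ch]])) contrib else G[[ch]] + contrib
      }
    }
    if (lo$p > 0L) {
      gcols <- lo$m * k + seq_len(lo$p)
      G_Bg <- G_X[, gcols, drop = FALSE]
      dAw[, lo$m + seq_len(lo$p)] <- G_Bg * ca$Xg
      # gene inputs are data; no gradient propagated further
    }
    # softmax backward
    dS <- ca$A_w * (dAw - rowSums(ca$A_w * dAw))
    v <- p[[pre("v")]]
    grads[[pre("v")]] <- sum(dS * ca$Q)
    dQpre <- (v * dS) * (1 - ca$Q^2)
    if (lo$m > 0L) {
      dU_terms <- matrix(0, k, lo$m)
      db_terms <- numeric(lo$m)
      for (j in seq_len(lo$m)) {
        Hc <- fw$enc$H[[lo$child_terms[j]]]
        dU_terms[, j] <- drop(t(Hc) %*% dQpre[, j])
        db_terms[j] <- sum(dQpre[, j])
        contrib <- dQpre[, j] %*% t(p[[pre("U_terms")]][, j, drop = FALSE])
        ch <- lo$child_terms[j]
        G[[ch]] <- G[[ch]] + contrib
      }
      grads[[pre("U_terms")]] <- dU_terms
      grads[[pre("b_terms")]] <- db_terms
    }
    if (lo$p > 0L) {
      dQg <- dQpre[, lo$m + seq_len(lo$p), drop = FALSE]
      grads[[pre("u_genes")]] <- colSums(ca$Xg * dQg)
      grads[[pre("b_genes")]] <- colSums(dQg)
    }
  }
  list(loss = lg$loss, grads = grads)
}

# ---- Adam optimizer ----

adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0),
       v = lapply(par, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decoupled decay on weight matrices only
    if (weight_decay > 0 && grepl("\\.(W[0-9]*|Wh|Wo|U_terms|u_genes)$", nm)) {
      par[[nm]] <- par[[nm]] * (1 - lr * weight_decay)
    }
  }
  list(par = par, state = state)
}
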