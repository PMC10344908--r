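#' @title The ontology-guided visible neural network
#' @name vnn
#' @description The expression encoder is compiled from the pruned ontology
#'   DAG: each term is a small layer (linear + batch normalization + tanh)
#'   over the concatenation of its children's states, with an additive
#'   attention mechanism weighting each child before concatenation. Gene
#'   leaves enter as single standardized expression values. A plain
#'   multilayer perceptron encodes the drug fingerprint, and a two-layer
#'   head combines both embeddings.
NULL

#' Network configuration
#'
#' @param k_term_neurons Hidden state width per ontology term (default 6).
#' @param drug_layer_sizes Drug encoder layer widths (default 64, 32, 4;
#'   the last is the drug embedding size).
#' @param n_bits Fingerprint length (default 2048).
#' @param head_hidden Hidden width of the prediction head (default 16).
#' @param seed Integer seed for weight initialization.
#' @return A \code{vnn_config} list.
#' @export
vnn_config <- function(k_term_neurons = 6L, drug_layer_sizes = c(64L, 32L, 4L),
                       n_bits = 2048L, head_hidden = 16L, seed = 1L) {
  stopifnot(k_term_neurons > 0, all(drug_layer_sizes > 0), n_bits > 0,
            head_hidden > 0)
  structure(list(k_term_neurons = as.integer(k_term_neurons),
                 drug_layer_sizes = as.integer(drug_layer_sizes),
                 n_bits = as.integer(n_bits),
                 head_hidden = as.integer(head_hidden),
                 attention = "softmax_additive",
                 seed = as.integer(seed)),
            class = "vnn_config")
}

.glorot <- function(n_in, n_out) {
  s <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -s, s), n_in, n_out)
}

#' Compile the network from a pruned ontology
#'
#' For each term the linear layer input dimension is
#' (number of child terms) * k + (number of directly annotated genes); the
#' output is k units through batch normalization and tanh. Weight shapes
#' are therefore a pure function of the DAG and the configuration, and
#' initialization is deterministic given the seed.
#'
#' @param dag A pruned, annotated \code{ontology_dag}.
#' @param config A [vnn_config()].
#' @param stage \code{"stage1"} (classification head) or \code{"stage2"}
#'   (regression head).
#' @return A \code{vnn_model}.
#' @export
build_model <- function(dag, config, stage = "stage1") {
  stopifnot(inherits(dag, "ontology_dag"), inherits(config, "vnn_config"),
            stage %in% c("stage1", "stage2"))
  if (!length(dag$genes)) stop("DAG carries no annotated genes; prune first")
  k <- config$k_term_neurons
  gene_order <- dag$genes
  layout <- list()
  for (t in dag$topo_order) {
    child_terms <- dag$child_edges[[t]] # already sorted; terms before genes
    genes <- dag$gene_annotations[[t]]
    m <- length(child_terms)
    p <- length(genes)
    if (m + p == 0L) {
      stop("term ", t, " has no children and no annotated genes")
    }
    layout[[t]] <- list(term = t, child_terms = child_terms, genes = genes,
                        gene_idx = match(genes, gene_order),
                        m = m, p = p, D = m * k + p)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  par <- list()
  buf <- list()
  for (t in dag$topo_order) {
    lo <- layout[[t]]
    pre <- function(x) paste0("term.", t, ".", x)
    if (lo$m > 0L) {
      par[[pre("U_terms")]] <- matrix(stats::runif(k * lo$m, -0.1, 0.1),
                                      k, lo$m)
      par[[pre("b_terms")]] <- numeric(lo$m)
    }
    if (lo$p > 0L) {
      par[[pre("u_genes")]] <- stats::runif(lo$p, -0.1, 0.1)
      par[[pre("b_genes")]] <- numeric(lo$p)
    }
    par[[pre("v")]] <- 1
    par[[pre("W")]] <- .glorot(lo$D, k)
    par[[pre("b")]] <- numeric(k)
    par[[pre("gamma")]] <- rep(1, k)
    par[[pre("beta")]] <- numeric(k)
    par[[pre("act_u")]] <- .glorot(k, 1L)[, 1L]
    par[[pre("act_b")]] <- 0
    buf[[paste0("term.", t, ".run_mean")]] <- numeric(k)
    buf[[paste0("term.", t, ".run_var")]] <- rep(1, k)
  }
  sizes <- c(config$n_bits, config$drug_layer_sizes)
  for (i in seq_along(config$drug_layer_sizes)) {
    par[[paste0("drug.W", i)]] <- .glorot(sizes[i], sizes[i + 1L])
    par[[paste0("drug.b", i)]] <- numeric(sizes[i + 1L])
  }
  head_in <- k + utils::tail(config$drug_layer_sizes, 1L)
  par[["head.Wh"]] <- .glorot(head_in, config$head_hidden)
  par[["head.bh"]] <- numeric(config$head_hidden)
  par[["head.Wo"]] <- .glorot(config$head_hidden, 1L)
  par[["head.bo"]] <- 0
  structure(list(config = config, dag = dag, layout = layout,
                 gene_order = gene_order, par = par, buffers = buf,
                 stage = stage,
                 meta = list(seed = config$seed, dag_hash = dag_hash(dag))),
            class = "vnn_model")
}

#' @export
print.vnn_model <- function(x, ...) {
  n_par <- sum(vapply(x$par, length, 1L))
  cat("vnn_model (", x$stage, "): ", length(x$layout), " terms, ",
      length(x$gene_order), " genes, ", n_par, " parameters\n", sep = "")
  invisible(x)
}

#' Total trainable parameter count
#' @param model A \code{vnn_model}.
#' @return Integer number of scalar parameters.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$par, length, 1L))
}

.sigmoid <- function(x) 1 / (1 + exp(-x))
.relu <- function(x) {
  x[x < 0] <- 0
  x
}
.row_softmax <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Full encoder forward over a batch. X: batch x genes (standardized, in
# model$gene_order). Returns term states and, when cache = TRUE, the
# intermediates needed for backpropagation. bn_update = "replace" sets the
# running statistics to this batch's statistics (recalibration pass).
.encoder_forward <- function(model, X, training = FALSE, cache = FALSE,
                             bn_update = "momentum") {
  k <- model$config$k_term_neurons
  B <- nrow(X)
  H <- list()
  caches <- if (cache) list() else NULL
  attn <- list()
  new_buf <- model$buffers
  for (t in model$dag$topo_order) {
    lo <- model$layout[[t]]
    p <- model$par
    pre <- function(x) paste0("term.", t, ".", x)
    blocks <- vector("list", lo$m + (lo$p > 0L))
    Q <- matrix(0, B, lo$m + lo$p)
    if (lo$m > 0L) {
      U <- p[[pre("U_terms")]]
      bt <- p[[pre("b_terms")]]
      for (j in seq_len(lo$m)) {
        Hc <- H[[lo$child_terms[j]]]
        Q[, j] <- tanh(Hc %*% U[, j, drop = FALSE] + bt[j])
      }
    }
    Xg <- NULL
    if (lo$p > 0L) {
      Xg <- X[, lo$gene_idx, drop = FALSE]
      ug <- p[[pre("u_genes")]]
      bg <- p[[pre("b_genes")]]
      Q[, lo$m + seq_len(lo$p)] <-
        tanh(Xg * rep(ug, each = B) + rep(bg, each = B))
    }
    v <- p[[pre("v")]]
    S <- v * Q
    A_w <- .row_softmax(S)
    Xcat <- matrix(0, B, lo$D)
    if (lo$m > 0L) {
      for (j in seq_len(lo$m)) {
        Xcat[, (j - 1L) * k + seq_len(k)] <-
          H[[lo$child_terms[j]]] * A_w[, j]
      }
    }
    if (lo$p > 0L) {
      Xcat[, lo$m * k + seq_len(lo$p)] <-
        Xg * A_w[, lo$m + seq_len(lo$p), drop = FALSE]
    }
    A_lin <- Xcat %*% p[[pre("W")]] + rep(p[[pre("b")]], each = B)
    if (training) {
      mu <- colMeans(A_lin)
      ctr <- A_lin - rep(mu, each = B)
      va <- colMeans(ctr^2)
      if (bn_update == "replace") {
        new_buf[[paste0("term.", t, ".run_mean")]] <- mu
        new_buf[[paste0("term.", t, ".run_var")]] <- va
      } else {
        new_buf[[paste0("term.", t, ".run_mean")]] <-
          (1 - BN_MOMENTUM) * new_buf[[paste0("term.", t, ".run_mean")]] +
          BN_MOMENTUM * mu
        new_buf[[paste0("term.", t, ".run_var")]] <-
          (1 - BN_MOMENTUM) * new_buf[[paste0("term.", t, ".run_var")]] +
          BN_MOMENTUM * va
      }
    } else {
      mu <- model$buffers[[paste0("term.", t, ".run_mean")]]
      va <- model$buffers[[paste0("term.", t, ".run_var")]]
      ctr <- A_lin - rep(mu, each = B)
    }
    sd_b <- sqrt(va + BN_EPS)
    Ahat <- ctr / rep(sd_b, each = B)
    Ybn <- Ahat * rep(p[[pre("gamma")]], each = B) +
      rep(p[[pre("beta")]], each = B)
    H[[t]] <- tanh(Ybn)
    attn[[t]] <- A_w
    if (cache) {
      caches[[t]] <- list(Q = Q, A_w = A_w, Xcat = Xcat, Ahat = Ahat,
                          sd_b = sd_b, Xg = Xg)
    }
  }
  list(H = H, attn = attn, caches = caches, buffers = new_buf)
}

.drug_forward <- function(model, FP, cache = FALSE) {
  p <- model$par
  B <- nrow(FP)
  Z <- FP
  acts <- list(FP)
  n_layers <- length(model$config$drug_layer_sizes)
  for (i in seq_len(n_layers)) {
    A <- Z %*% p[[paste0("drug.W", i)]] +
      rep(p[[paste0("drug.b", i)]], each = B)
    Z <- if (i < n_layers) .relu(A) else A # last layer is linear
    acts[[i + 1L]] <- Z
  }
  if (cache) list(E = Z, acts = acts) else list(E = Z)
}

.head_forward <- function(model, Emb, E, cache = FALSE) {
  p <- model$par
  B <- nrow(Emb)
  U <- cbind(Emb, E)
  Hh <- .relu(U %*% p[["head.Wh"]] + rep(p[["head.bh"]], each = B))
  O <- drop(Hh %*% p[["head.Wo"]] + p[["head.bo"]])
  pred <- if (model$stage == "stage1") .sigmoid(O) else O
  if (cache) list(pred = pred, O = O, Hh = Hh, U = U) else list(pred = pred)
}

# Full network forward on a training_set-like batch.
vnn_forward <- function(model, X, FP, training = FALSE, cache = FALSE) {
  enc <- .encoder_forward(model, X, training = training, cache = cache)
  drug <- .drug_forward(model, FP, cache = cache)
  head <- .head_forward(model, enc$H[[model$dag$root]], drug$E,
                        cache = cache)
  list(pred = head$pred, emb = enc$H[[model$dag$root]], drug_emb = drug$E,
       enc = enc, drug = drug, head = head)
}

#' Encode one patient's transcriptome
#'
#' Runs the expression encoder in inference mode and returns the root
#' embedding together with a per-term attention report. A term that is a
#' child of several parents receives one attention weight per parent
#' context; the report keeps the maximum.
#'
#' @param model A \code{vnn_model}.
#' @param expression Standardized expression vector named by (or ordered
#'   as) the model's gene order.
#' @return List with \code{embedding} (k-vector) and \code{report}, a data
#'   frame with columns \code{term}, \code{depth}, \code{weight},
#'   \code{activation} (rectified scalar term readout). The root term has
#'   weight \code{NA} (it is assigned by no parent).
#' @export
forward_encoder <- function(model, expression) {
  X <- .coerce_expression_row(model, expression)
  enc <- .encoder_forward(model, X, training = FALSE, cache = FALSE)
  w <- stats::setNames(rep(NA_real_, length(model$dag$terms)),
                       model$dag$terms)
  for (t in model$dag$topo_order) {
    lo <- model$layout[[t]]
    if (lo$m > 0L) {
      for (j in seq_len(lo$m)) {
        ch <- lo$child_terms[j]
        a <- enc$attn[[t]][1L, j]
        if (is.na(w[[ch]]) || a > w[[ch]]) w[[ch]] <- a
      }
    }
  }
  act <- vapply(model$dag$terms, function(t) {
    p <- model$par
    max(0, drop(enc$H[[t]] %*% p[[paste0("term.", t, ".act_u")]]) +
          p[[paste0("term.", t, ".act_b")]])
  }, numeric(1))
  report <- data.frame(
    term = model$dag$terms,
    depth = vapply(model$dag$terms, function(t) model$dag$depth[[t]], 1L),
    weight = unname(w[model$dag$terms]),
    activation = unname(act),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(embedding = drop(enc$H[[model$dag$root]]), report = report)
}

.coerce_expression_row <- function(model, expression) {
  if (is.matrix(expression)) expression <- drop(expression)
  if (!is.null(names(expression))) {
    missing <- setdiff(model$gene_order, names(expression))
    if (length(missing)) {
      stop("expression vector lacks gene(s): ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    expression <- expression[model$gene_order]
  }
  if (length(expression) != length(model$gene_order)) {
    stop("expression length ", length(expression), " != annotated gene ",
         "count ", length(model$gene_order))
  }
  matrix(expression, nrow = 1L)
}

#' Encode a drug fingerprint
#' @param model A \code{vnn_model}.
#' @param fingerprint 0/1 vector of length \code{n_bits}.
#' @return Drug embedding vector (last drug layer width).
#' @export
forward_drug <- function(model, fingerprint) {
  if (length(fingerprint) != model$config$n_bits) {
    stop("fingerprint length ", length(fingerprint), " != n_bits ",
         model$config$n_bits)
  }
  drop(.drug_forward(model, matrix(fingerprint, nrow = 1L))$E)
}

#' Combine embeddings into a prediction
#' @param model A \code{vnn_model} whose stage determines the head:
#'   \code{stage1} yields a probability in (0, 1), \code{stage2} an
#'   unbounded log months-to-death.
#' @param embedding Expression embedding (k-vector).
#' @param drug_embedding Drug embedding.
#' @return Scalar prediction.
#' @export
forward_head <- function(model, embedding, drug_embedding) {
  k <- model$config$k_term_neurons
  d <- utils::tail(model$config$drug_layer_sizes, 1L)
  if (length(embedding) != k || length(drug_embedding) != d) {
    stop("head expects embedding of length ", k,
         " and drug embedding of length ", d)
  }
  .head_forward(model, matrix(embedding, nrow = 1L),
                matrix(drug_embedding, nrow = 1L))$pred
}

#' Predict for a training set (inference mode)
#' @param model A \code{vnn_model}.
#' @param ts A \code{training_set}.
#' @return Numeric vector of predictions (probabilities for stage 1, log
#'   months for stage 2).
#' @export
predict_training_set <- function(model, ts) {
  vnn_forward(model, ts$X, ts$FP, training = FALSE, cache = FALSE)$pred
}
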