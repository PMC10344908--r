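# fixture DAG: root T:R {T:A, T:B}; T:A {T:C}; T:B {T:D, gene g4};
# T:C {T:D, genes g1, g5}; T:D {genes g2, g3}; gene order g1..g5

test_that("weight shapes follow the dimension arithmetic of the DAG", {
  dag <- fixture_dag()
  cfg <- vnn_config(seed = 1L) # k = 6, drug 64/32/4, n_bits 2048
  model <- build_model(dag, cfg, "stage1")
  k <- 6L
  # T:C has 1 term child + 2 genes -> input k + 2
  expect_identical(dim(model$par[["term.T:C.W"]]), c(k + 2L, k))
  # T:R has 2 term children, no genes -> input 2k
  expect_identical(dim(model$par[["term.T:R.W"]]), c(2L * k, k))
  # drug encoder dims 2048 -> 64 -> 32 -> 4
  expect_identical(dim(model$par[["drug.W1"]]), c(2048L, 64L))
  expect_identical(dim(model$par[["drug.W2"]]), c(64L, 32L))
  expect_identical(dim(model$par[["drug.W3"]]), c(32L, 4L))
  # head input = 6 + 4 = 10
  expect_identical(dim(model$par[["head.Wh"]]), c(10L, cfg$head_hidden))
})

test_that("total parameter count matches an independent degree-sequence audit", {
  dag <- fixture_dag()
  for (k in c(2L, 6L)) {
    cfg <- vnn_config(k_term_neurons = k, drug_layer_sizes = c(8L, 3L),
                      n_bits = 32L, head_hidden = 5L, seed = 2L)
    model <- build_model(dag, cfg, "stage1")
    expected <- 0L
    for (t in dag$terms) {
      m <- length(dag$child_edges[[t]])
      p <- length(dag$gene_annotations[[t]])
      D <- m * k + p
      expected <- expected +
        (if (m > 0) k * m + m else 0) +  # attention over term children
        (if (p > 0) 2 * p else 0) +      # attention over genes
        1 +                              # shared scorer scale v
        D * k + k +                      # linear
        2 * k +                          # batch norm gamma/beta
        k + 1                            # scalar readout
    }
    expected <- expected + (32 * 8 + 8) + (8 * 3 + 3) +  # drug encoder
      ((k + 3) * 5 + 5) + (5 * 1 + 1)                    # head
    expect_identical(count_parameters(model), as.integer(expected))
  }
})

test_that("initialization is deterministic given the seed", {
  dag <- fixture_dag()
  m1 <- build_model(dag, small_vnn_config(seed = 5L), "stage1")
  m2 <- build_model(dag, small_vnn_config(seed = 5L), "stage1")
  m3 <- build_model(dag, small_vnn_config(seed = 6L), "stage1")
  expect_identical(m1$par, m2$par)
  expect_false(identical(m1$par, m3$par))
})

test_that("encoder forward equals a hand-unrolled computation on the \
5-term DAG", {
  dag <- fixture_dag()
  k <- 2L
  cfg <- vnn_config(k_term_neurons = k, drug_layer_sizes = c(4L, 3L),
                    n_bits = 16L, head_hidden = 3L, seed = 11L)
  model <- build_model(dag, cfg, "stage2")
  # non-trivial inference statistics
  for (t in dag$terms) {
    model$buffers[[paste0("term.", t, ".run_mean")]] <- seq_len(k) / 10
    model$buffers[[paste0("term.", t, ".run_var")]] <- 1 + seq_len(k) / 5
  }
  x <- c(g1 = 0.3, g2 = -1.2, g3 = 0.8, g4 = 2.1, g5 = -0.4)
  out <- forward_encoder(model, x)

  p <- model$par
  eps <- 1e-5
  bn <- function(t, a) {
    rm <- model$buffers[[paste0("term.", t, ".run_mean")]]
    rv <- model$buffers[[paste0("term.", t, ".run_var")]]
    tanh((a - rm) / sqrt(rv + eps) * p[[paste0("term.", t, ".gamma")]] +
           p[[paste0("term.", t, ".beta")]])
  }
  soft <- function(s) exp(s - max(s)) / sum(exp(s - max(s)))
  # T:D: gene children g2, g3
  qD <- tanh(c(x["g2"], x["g3"]) * p[["term.T:D.u_genes"]] +
               p[["term.T:D.b_genes"]])
  aD <- soft(p[["term.T:D.v"]] * qD)
  hD <- bn("T:D", drop(c(aD[1] * x[["g2"]], aD[2] * x[["g3"]]) %*%
                         p[["term.T:D.W"]]) + p[["term.T:D.b"]])
  # T:C: term child T:D then genes g1, g5
  qC <- c(tanh(sum(hD * p[["term.T:C.U_terms"]][, 1]) +
                 p[["term.T:C.b_terms"]][1]),
          tanh(c(x["g1"], x["g5"]) * p[["term.T:C.u_genes"]] +
                 p[["term.T:C.b_genes"]]))
  aC <- soft(p[["term.T:C.v"]] * qC)
  hC <- bn("T:C", drop(c(aC[1] * hD, aC[2] * x[["g1"]],
                         aC[3] * x[["g5"]]) %*% p[["term.T:C.W"]]) +
            p[["term.T:C.b"]])
  # T:B: term child T:D then gene g4
  qB <- c(tanh(sum(hD * p[["term.T:B.U_terms"]][, 1]) +
                 p[["term.T:B.b_terms"]][1]),
          tanh(x["g4"] * p[["term.T:B.u_genes"]] + p[["term.T:B.b_genes"]]))
  aB <- soft(p[["term.T:B.v"]] * qB)
  hB <- bn("T:B", drop(c(aB[1] * hD, aB[2] * x[["g4"]]) %*%
                         p[["term.T:B.W"]]) + p[["term.T:B.b"]])
  # T:A: single term child T:C
  qA <- tanh(sum(hC * p[["term.T:A.U_terms"]][, 1]) +
               p[["term.T:A.b_terms"]][1])
  aA <- 1 # softmax of a singleton
  hA <- bn("T:A", drop((aA * hC) %*% p[["term.T:A.W"]]) + p[["term.T:A.b"]])
  # root T:R: term children T:A, T:B
  qR <- c(tanh(sum(hA * p[["term.T:R.U_terms"]][, 1]) +
                 p[["term.T:R.b_terms"]][1]),
          tanh(sum(hB * p[["term.T:R.U_terms"]][, 2]) +
                 p[["term.T:R.b_terms"]][2]))
  aR <- soft(p[["term.T:R.v"]] * qR)
  hR <- bn("T:R", drop(c(aR[1] * hA, aR[2] * hB) %*% p[["term.T:R.W"]]) +
             p[["term.T:R.b"]])

  expect_equal(unname(out$embedding), unname(hR), tolerance = 1e-6)
  w <- stats::setNames(out$report$weight, out$report$term)
  expect_equal(unname(w["T:A"]), unname(aR[1]), tolerance = 1e-6)
  expect_equal(unname(w["T:B"]), unname(aR[2]), tolerance = 1e-6)
  # T:C is T:A's only child: softmax of a singleton is 1
  expect_equal(unname(w["T:C"]), 1, tolerance = 1e-12)
  # T:D is a child of both T:B and T:C: report keeps the maximum
  expect_equal(unname(w["T:D"]), max(aB[1], aC[1]), tolerance = 1e-6)
  expect_true(is.na(w["T:R"]))
})

test_that("attention weights per parent are nonnegative and sum to 1", {
  ds <- small_dataset()
  model <- build_model(ds$ont$dag, small_vnn_config(), "stage1")
  std <- suppressWarnings(standardize_expression(ds$coh$expression))
  X <- t(std[model$gene_order, 1:7])
  enc <- drugvnn:::.encoder_forward(model, X, training = FALSE)
  for (t in names(enc$attn)) {
    A <- enc$attn[[t]]
    expect_true(all(A >= 0))
    expect_lt(max(abs(rowSums(A) - 1)), 1e-6)
  }
  # singleton child carries weight exactly 1
  m_counts <- vapply(model$layout, function(lo) lo$m + lo$p, 1L)
  singletons <- names(m_counts)[m_counts == 1L]
  for (t in singletons) expect_true(all(enc$attn[[t]] == 1))
})

test_that("a child with attention weight exactly 0 has no influence", {
  dag <- fixture_dag()
  cfg <- vnn_config(k_term_neurons = 2L, drug_layer_sizes = c(4L, 3L),
                    n_bits = 16L, head_hidden = 3L, seed = 13L)
  model <- build_model(dag, cfg, "stage2")
  # saturate T:C's attention so that gene g1 receives exactly zero weight
  model$par[["term.T:C.v"]] <- 2000
  model$par[["term.T:C.u_genes"]] <- c(0, 0)
  model$par[["term.T:C.b_genes"]] <- c(-20, 20)   # g1 -> -1, g5 -> +1
  model$par[["term.T:C.U_terms"]][] <- 0
  model$par[["term.T:C.b_terms"]] <- 20
  x <- c(g1 = 0.5, g2 = 1, g3 = -1, g4 = 0.2, g5 = 0.7)
  base <- forward_encoder(model, x)
  w <- stats::setNames(base$report$weight, base$report$term)
  # finite-difference: perturbing g1 changes nothing downstream
  for (delta in c(1e-3, 0.5, 3)) {
    x2 <- x
    x2["g1"] <- x["g1"] + delta
    pert <- forward_encoder(model, x2)
    expect_identical(pert$embedding, base$embedding)
  }
})

test_that("drug encoder maps any fingerprint to the embedding width, \
deterministically", {
  dag <- fixture_dag()
  model <- build_model(dag, vnn_config(seed = 4L), "stage1")
  fp <- as.integer(runif(2048) < 0.1)
  e1 <- forward_drug(model, fp)
  expect_length(e1, 4L)
  expect_identical(e1, forward_drug(model, fp))
  e0 <- forward_drug(model, integer(2048))
  expect_true(all(is.finite(e0)))
  expect_error(forward_drug(model, integer(100)), "n_bits")
})

test_that("heads respect their output ranges and input dimensions", {
  dag <- fixture_dag()
  m1 <- build_model(dag, vnn_config(seed = 4L), "stage1")
  m2 <- build_model(dag, vnn_config(seed = 4L), "stage2")
  emb <- rnorm(6)
  de <- rnorm(4)
  p1 <- forward_head(m1, emb, de)
  expect_gt(p1, 0)
  expect_lt(p1, 1)
  p2 <- forward_head(m2, emb, de)
  months <- exp(p2)
  expect_gt(months * 30.4375, 0) # back-transforms to positive days
  expect_error(forward_head(m1, rnorm(3), de), "head expects")
})

test_that("inference is batch-size invariant", {
  ds <- small_dataset()
  model <- build_model(ds$ont$dag, small_vnn_config(), "stage2")
  std <- suppressWarnings(standardize_expression(ds$coh$expression))
  pairs <- data.frame(patient_id = colnames(std)[1:6],
                      drug = rep(ds$lib$table$name[1:3], 2),
                      label = rnorm(6))
  ts <- make_training_set(pairs, std, ds$lib, ds$ont$dag$genes)
  batch_pred <- predict_training_set(model, ts)
  single_pred <- vapply(1:6, function(i) {
    predict_training_set(model, drugvnn:::subset_training_set(ts, i))
  }, numeric(1))
  expect_equal(unname(batch_pred), unname(single_pred), tolerance = 1e-12)
})
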