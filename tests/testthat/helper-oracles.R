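# Independent oracle implementations used to cross-check the package's
# estimators.  These are deliberately written in the most literal way
# possible (explicit pair counting, coalition enumeration, Monte-Carlo
# integration) and must never share code with the package internals.

# Pair-counting AUROC: fraction of positive/negative pairs ranked
# correctly, ties counted as half.
oracle_auroc_paircount <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Confusion-table metrics computed from an explicitly tallied table with
# the "score >= threshold is positive" convention.
oracle_confusion <- function(scores, labels, threshold) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       accuracy = (tp + tn) / length(labels))
}

# Exact Shapley values for a prediction function over p features by full
# coalition enumeration, with absent features replaced by their
# background-average contribution (interventional expectation over a
# background set).
oracle_shapley_exact <- function(predict_fn, x, background) {
  p <- length(x)
  value <- function(S) {
    # expectation of f with features in S fixed to x, others drawn from
    # the background rows
    reps <- t(apply(background, 1, function(b) {
      v <- b
      v[S] <- x[S]
      v
    }))
    mean(predict_fn(reps))
  }
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- which(unlist(subsets[r, ]))
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w * (value(c(S, j)) - value(S))
    }
  }
  phi
}

# Exact Shapley values for an XGBoost tree ensemble by full coalition
# enumeration over the tree-structural value function: with a coalition S
# fixed to x, each tree is traversed following x at splits on features in
# S and taking the cover-weighted average of both children otherwise.
# For depth-1 trees this is exactly the game the path-dependent tree
# explainer solves, so its output must match to float32 precision.
oracle_shapley_tree <- function(booster, x, p) {
  dt <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  base_score <- as.numeric(
    xgboost::xgb.config(booster)$learner$learner_model_param$base_score)
  tree_value <- function(rows, S) {
    walk <- function(id) {
      nd <- rows[rows$ID == id, ]
      if (nd$Feature == "Leaf") return(nd$Gain)
      j <- match(nd$Feature, names(x))
      if (j %in% S) {
        if (x[j] < nd$Split) walk(nd$Yes) else walk(nd$No)
      } else {
        cl <- rows$Cover[rows$ID == nd$Yes]
        cr <- rows$Cover[rows$ID == nd$No]
        (cl * walk(nd$Yes) + cr * walk(nd$No)) / (cl + cr)
      }
    }
    walk(rows$ID[rows$Node == 0])
  }
  value <- function(S) {
    stats::qlogis(base_score) +
      sum(vapply(split(dt, dt$Tree), tree_value, numeric(1), S = S))
  }
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- which(unlist(subsets[r, ]))
      if (j %in% S) next
      s <- length(S)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + w * (value(c(S, j)) - value(S))
    }
  }
  list(phi = phi, base_value = value(integer(0)))
}

# Monte-Carlo KL divergence between N(mu, diag(exp(logvar))) and N(0, I).
oracle_kl_mc <- function(mu, logvar, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  k <- length(mu)
  z <- matrix(rnorm(n_draws * k), ncol = k)
  z <- sweep(sweep(z, 2, exp(logvar / 2), "*"), 2, mu, "+")
  logq <- rowSums(dnorm(z, mean = matrix(mu, n_draws, k, byrow = TRUE),
                        sd = matrix(exp(logvar / 2), n_draws, k, byrow = TRUE),
                        log = TRUE))
  logp <- rowSums(dnorm(z, log = TRUE))
  mean(logq - logp)
}

# Tiny deterministic cohort fixtures shared across tests.
make_test_ecg <- function(seed = 1, noise = TRUE, hr = 60) {
  p <- ecg_sim_params(heart_rate_bpm = hr, duration_s = 10, fs_hz = 500,
                      noise_sd_mv = if (noise) 0.02 else 0,
                      wander_amp_mv = if (noise) 0.1 else 0,
                      seed = seed)
  list(params = p, record = simulate_ecg(p))
}
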