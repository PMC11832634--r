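# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the package implementation.

# Posterior by explicit Gaussian density x prior, normalised.  Uses
# solve() and the full quadratic form rather than the linear discriminant
# expansion.
oracle_posterior <- function(model, newdata) {
  x <- as.matrix(newdata[model$features])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  P <- solve(model$pooled_cov)
  K <- length(model$classes)
  logdens <- matrix(0, nrow(z), K)
  for (k in seq_len(K)) {
    dev <- sweep(z, 2, model$means[k, ])
    logdens[, k] <- -0.5 * rowSums((dev %*% P) * dev) +
      log(model$priors[k])
  }
  m <- apply(logdens, 1, max)
  e <- exp(logdens - m)
  post <- e / rowSums(e)
  colnames(post) <- model$classes
  post
}

# Exhaustive maximum-cardinality minimum-cost matching by recursion over
# peaks of A (each either unmatched or matched to a feasible free peak of
# B).  Exponential; only for small instances.
oracle_match <- function(A, B, gates) {
  dims <- attr(A, "dims")
  C <- matrix(0, nrow(A), nrow(B))
  feasible <- matrix(TRUE, nrow(A), nrow(B))
  for (d in dims) {
    dd <- outer(A[[d]], B[[d]], "-") / gates[[d]]
    feasible <- feasible & abs(dd) <= 1
    C <- C + dd^2
  }
  best_n <- -1L
  best_cost <- Inf
  usedB <- rep(FALSE, nrow(B))
  nA <- nrow(A)
  rec <- function(i, n, cost) {
    if (i > nA) {
      if (n > best_n || (n == best_n && cost < best_cost)) {
        best_n <<- n
        best_cost <<- cost
      }
      return(invisible())
    }
    rec(i + 1L, n, cost)
    for (j in which(feasible[i, ] & !usedB)) {
      usedB[j] <<- TRUE
      rec(i + 1L, n + 1L, cost + C[i, j])
      usedB[j] <<- FALSE
    }
  }
  rec(1L, 0L, 0)
  list(n = best_n, cost = best_cost)
}

# All-starts enumeration of chain placements by direct probability
# products (no logs), normalised over admissible starts.
oracle_placements <- function(posteriors, sequence) {
  n <- nrow(posteriors)
  L <- length(sequence)
  starts <- seq_len(L - n + 1)
  logp <- vapply(starts, function(s) {
    lp <- 0
    for (i in seq_len(n)) {
      ty <- sequence[s + i - 1]
      pi <- if (ty %in% colnames(posteriors)) posteriors[i, ty] else 0
      if (pi == 0) return(-Inf)
      lp <- lp + log(pi)
    }
    lp
  }, numeric(1))
  adm <- is.finite(logp)
  norm <- rep(0, length(starts))
  if (any(adm)) {
    w <- exp(logp[adm] - max(logp[adm]))
    norm[adm] <- w / sum(w)
  }
  data.frame(start = starts, log_score = logp, norm_prob = norm,
             admissible = adm)[order(-logp, starts), ]
}

# random unassigned peak list in the HN/N plane
random_peak_list <- function(n, temperature = 5) {
  peak_list(cbind(runif(n, 105, 130), runif(n, 7.5, 9)),
            dims = c("N", "HN"), experiment = "HSQC",
            temperature = temperature)
}

# labelled training frame drawn from per-class Gaussians (for classifier
# oracle tests, independent of the package generator)
random_training <- function(K, d, n_per_class) {
  # feature names must come from the controlled vocabulary (d <= 15)
  feats <- tcassign::subset_preset("vi")[seq_len(d)]
  classes <- sample(c("A","C","D","E","F","H","I","K","L","M",
                      "N","Q","R","S","T","V","W","Y"), K)
  mu <- matrix(rnorm(K * d, sd = 2), K, d)
  rows <- lapply(seq_len(K), function(k) {
    x <- matrix(rnorm(n_per_class * d), n_per_class, d) +
      matrix(mu[k, ], n_per_class, d, byrow = TRUE)
    df <- as.data.frame(x)
    names(df) <- feats
    cbind(data.frame(res_type = classes[k], stringsAsFactors = FALSE), df)
  })
  do.call(rbind, rows)
}
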