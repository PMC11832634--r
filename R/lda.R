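#' Feature subsets for spin-system typing
#'
#' Six standard combinations of chemical shifts (CS) and per-interval
#' temperature coefficients (TC), named `"i"` to `"vi"`:
#'
#' * `i`:   HN, N, C, CA shifts;
#' * `ii`:  subset i plus the first-interval TC of each of those nuclei;
#' * `iii`: subset i plus first- and second-interval TCs;
#' * `iv`:  HN, N, C, CA, CB shifts;
#' * `v`:   subset iv plus the first-interval TC of each nucleus;
#' * `vi`:  subset iv plus first- and second-interval TCs.
#'
#' Shift features are named `HN`, `N`, `C`, `CA`, `CB`; coefficient
#' features `TC1_<nucleus>` (first interval, e.g. 5-10 degC) and
#' `TC2_<nucleus>` (second interval, e.g. 10-15 degC).
#'
#' @param name one of `"i" ... "vi"`.
#' @return character vector of feature names.
#' @export
subset_preset <- function(name) {
  name <- match.arg(tolower(as.character(name)),
                    c("i", "ii", "iii", "iv", "v", "vi"))
  four <- c("HN", "N", "C", "CA")
  five <- c(four, "CB")
  switch(name,
         i   = four,
         ii  = c(four, paste0("TC1_", four)),
         iii = c(four, paste0("TC1_", four), paste0("TC2_", four)),
         iv  = five,
         v   = c(five, paste0("TC1_", five)),
         vi  = c(five, paste0("TC1_", five), paste0("TC2_", five)))
}

#' Linear discriminant model for amino-acid-type recognition
#'
#' Fits a shared-covariance Gaussian (linear discriminant) classifier on
#' labelled spin systems.  Features are standardised to zero mean and unit
#' variance over the pooled training set; class means and the pooled
#' within-class covariance
#' \deqn{\Sigma = \frac{1}{N-K} \sum_k \sum_{i \in k} (x_i-\mu_k)(x_i-\mu_k)^T}
#' are estimated on the standardised scale, and the covariance is shrunk
#' towards its diagonal, \eqn{\Sigma_\lambda = (1-\lambda)\Sigma + \lambda D}
#' with \eqn{D = \mathrm{diag}(\Sigma)} (zero diagonal entries are replaced
#' by one pooled-variance unit so degenerate scatter still yields a valid
#' model).  Posterior probabilities follow the usual linear discriminant
#' rule; see [predict.tclda()].
#'
#' @param data data frame of labelled spin systems: a `res_type` column
#'   (one-letter codes) plus feature columns.  Rows with unknown type or
#'   incomplete features for `features` are dropped.
#' @param features character vector of feature names, e.g.
#'   [subset_preset()]`("v")`.
#' @param priors `"uniform"` (default), `"sequence"` (proportional to type
#'   counts in `sequence`, excluded types removed and renormalised), or a
#'   named numeric vector of prior probabilities.
#' @param lambda shrinkage weight in `[0, 1]` towards the diagonal;
#'   default 0.05.
#' @param min_class_size classes with fewer complete training systems are
#'   dropped with a warning; default 3.
#' @param exclude character vector of types to exclude before fitting
#'   (e.g. `c("G", "P")`: glycines are usually obvious and prolines are
#'   invisible in HN-detected spectra).
#' @param sequence character vector of one-letter codes (required for
#'   `priors = "sequence"`).
#' @param keep_data keep the standardised training matrix in the model
#'   (needed by `plot` and `summary`)?
#' @return an object of class `tclda`.
#' @seealso [predict.tclda()], [tclda_family()], [tclda_from_statistics()]
#' @export
tclda <- function(data, features = subset_preset("v"),
                  priors = "uniform", lambda = 0.05, min_class_size = 3,
                  exclude = NULL, sequence = NULL, keep_data = TRUE) {
  stopifnot(is.data.frame(data), length(features) >= 1)
  if (anyDuplicated(features)) stop("duplicate feature names")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols))
    stop("feature column(s) absent from data: ",
         paste(missing_cols, collapse = ", "))
  keep <- !is.na(data$res_type) & !data$res_type %in% exclude &
    stats::complete.cases(data[features])
  train <- data[keep, , drop = FALSE]
  if (nrow(train) == 0) stop("no complete labelled training systems")
  counts <- table(train$res_type)
  small <- names(counts)[counts < min_class_size]
  if (length(small)) {
    warning("class(es) dropped (fewer than ", min_class_size,
            " training systems): ", paste(small, collapse = ", "))
    train <- train[!train$res_type %in% small, , drop = FALSE]
  }
  classes <- sort(unique(train$res_type))
  if (length(classes) < 2)
    stop("fewer than 2 classes remain after filtering")
  x <- as.matrix(train[features])
  y <- train$res_type
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(scale == 0))
    stop("feature(s) constant over the training set: ",
         paste(features[scale == 0], collapse = ", "))
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  K <- length(classes); d <- length(features); N <- nrow(z)
  means <- matrix(0, K, d, dimnames = list(classes, features))
  S <- matrix(0, d, d)
  for (k in seq_len(K)) {
    zk <- z[y == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(zk)
    dev <- sweep(zk, 2, means[k, ])
    S <- S + crossprod(dev)
  }
  S <- S / (N - K)
  target <- diag(S)
  target[target == 0] <- 1  # one pooled-variance unit on standardised scale
  S_l <- (1 - lambda) * S + lambda * diag(target, d)
  ch <- tryCatch(chol(S_l), error = function(e) NULL)
  if (is.null(ch))
    stop("regularised pooled covariance is singular; increase lambda")
  precision <- chol2inv(ch)
  pr <- make_priors(priors, classes, sequence)
  structure(list(classes = classes,
                 means = means,
                 pooled_cov = S_l,
                 precision = precision,
                 priors = pr,
                 center = center,
                 scale = scale,
                 lambda = lambda,
                 min_class_size = min_class_size,
                 n_per_class = as.integer(table(factor(y, classes))),
                 features = features,
                 excluded = union(exclude, small),
                 x = if (keep_data) z else NULL,
                 y = if (keep_data) y else NULL,
                 call = match.call()),
            class = "tclda")
}

make_priors <- function(priors, classes, sequence = NULL) {
  K <- length(classes)
  if (is.numeric(priors)) {
    if (is.null(names(priors)) || !all(classes %in% names(priors)))
      stop("numeric priors must be named with every class")
    pr <- priors[classes]
    if (any(pr <= 0)) stop("priors must be positive")
    return(pr / sum(pr))
  }
  mode <- match.arg(priors, c("uniform", "sequence"))
  if (mode == "uniform") return(setNames(rep(1 / K, K), classes))
  if (is.null(sequence))
    stop("priors = \"sequence\" requires a sequence")
  counts <- table(factor(sequence, levels = classes))
  if (any(counts == 0))
    stop("sequence contains no residue of class(es): ",
         paste(classes[counts == 0], collapse = ", "))
  pr <- as.numeric(counts) / sum(counts)
  setNames(pr, classes)
}

#' @export
print.tclda <- function(x, ...) {
  cat(sprintf(paste0("Linear discriminant spin-system classifier\n",
                     "  %d classes (%s)\n",
                     "  %d features: %s\n",
                     "  %d training systems, lambda = %g\n"),
              length(x$classes), paste(x$classes, collapse = ""),
              length(x$features), paste(x$features, collapse = ", "),
              sum(x$n_per_class), x$lambda))
  if (length(x$excluded))
    cat("  excluded classes:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' @method summary tclda
#' @export
summary.tclda <- function(object, ...) {
  tab <- data.frame(class = object$classes,
                    n = object$n_per_class,
                    prior = as.numeric(object$priors))
  res <- list(model = object, classes = tab)
  if (!is.null(object$x)) {
    post <- predict(object, object$x, type = "posterior")
    pred <- object$classes[max.col(post, ties.method = "first")]
    res$training_accuracy <- mean(pred == object$y)
    res$confusion <- table(truth = object$y,
                           predicted = factor(pred, object$classes))
  }
  class(res) <- "summary.tclda"
  res
}

#' @export
print.summary.tclda <- function(x, ...) {
  print(x$model)
  print(x$classes, row.names = FALSE)
  if (!is.null(x$training_accuracy))
    cat(sprintf("Training accuracy: %.3f\n", x$training_accuracy))
  invisible(x)
}

#' Discriminant coefficients
#'
#' Returns the linear discriminant functions on the standardised feature
#' scale: for class k the posterior-maximising score is
#' `x %*% coef[k, -1] + coef[k, 1]`.
#'
#' @param object a [tclda()] model.
#' @param ... unused.
#' @return matrix with one row per class: intercept
#'   (`-0.5 * mu' P mu + log prior`) and feature weights (`P mu`).
#' @method coef tclda
#' @export
coef.tclda <- function(object, ...) {
  W <- object$means %*% object$precision
  b <- -0.5 * rowSums(W * object$means) + log(object$priors)
  cbind(`(Intercept)` = b, W)
}

#' Posterior amino-acid-type probabilities
#'
#' For a standardised query x the discriminant score of class k is
#' \deqn{\delta_k(x) = x^T \Sigma_\lambda^{-1}\mu_k
#'       - \tfrac12 \mu_k^T \Sigma_\lambda^{-1}\mu_k + \log\pi_k,}
#' and posteriors are the softmax of the scores (stabilised by subtracting
#' the row maximum).  This equals Bayes' rule under class-conditional
#' Gaussians with shared covariance.
#'
#' @param object a [tclda()] model.
#' @param newdata data frame of spin systems (or numeric matrix already on
#'   the standardised scale, with `ncol` equal to the number of model
#'   features).  All model features must be present; for incomplete spin
#'   systems use [tclda_family()] / [predict.tclda_family()].
#' @param type `"posterior"` (matrix of class probabilities, rows sum
#'   to 1), `"class"` (top-ranked type) or `"ranked"` (list of
#'   [classification_result()] objects).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.tclda <- function(object, newdata,
                          type = c("posterior", "class", "ranked"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    missing_cols <- setdiff(object$features, names(newdata))
    if (length(missing_cols))
      stop("missing feature column(s): ",
           paste(missing_cols, collapse = ", "),
           "; use tclda_family() for incomplete spin systems")
    x <- as.matrix(newdata[object$features])
    if (anyNA(x))
      stop("query has missing feature values; ",
           "use tclda_family() for incomplete spin systems")
    z <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  } else {
    z <- as.matrix(newdata)
    if (ncol(z) != length(object$features))
      stop("matrix input must have one column per model feature")
  }
  W <- object$precision %*% t(object$means)            # d x K
  delta <- z %*% W
  delta <- sweep(delta, 2,
                 0.5 * colSums(t(object$means) * W) - log(object$priors))
  m <- apply(delta, 1, max)
  e <- exp(delta - m)
  post <- e / rowSums(e)
  colnames(post) <- object$classes
  rownames(post) <- rownames(z)
  switch(type,
         posterior = post,
         class = object$classes[max.col(post, ties.method = "first")],
         ranked = lapply(seq_len(nrow(post)), function(i)
           classification_result(post[i, ], subset = object$features,
                                 excluded = object$excluded)))
}

#' Ranked classification result
#'
#' @param posteriors named numeric vector of class posteriors (sums to 1).
#' @param subset feature names used for the classification.
#' @param excluded classes excluded from the model, if any.
#' @return object of class `classification_result` with posteriors and the
#'   ranking by descending probability (ties broken by class label).
#' @export
classification_result <- function(posteriors, subset = NULL,
                                  excluded = character(0)) {
  stopifnot(abs(sum(posteriors) - 1) < 1e-9)
  ord <- order(-posteriors, names(posteriors))
  structure(list(posteriors = posteriors,
                 ranking = names(posteriors)[ord],
                 subset = subset,
                 excluded = excluded),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, threshold = 0.1, ...) {
  keep <- x$ranking[x$posteriors[x$ranking] >= threshold]
  if (!length(keep)) keep <- x$ranking[1]
  cat(paste(sprintf("%s %.0f%%", keep, 100 * x$posteriors[keep]),
            collapse = ", "), "\n")
  if (length(x$subset) > 0)
    cat("  features:", paste(x$subset, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn tclda plot training systems on the first two canonical
#'   discriminant axes (requires `keep_data = TRUE`).
#' @param x,... plot method arguments.
#' @method plot tclda
#' @export
plot.tclda <- function(x, ...) {
  if (is.null(x$x)) stop("model was fitted with keep_data = FALSE")
  # between-class scatter on standardised scale
  B <- crossprod(x$means * sqrt(x$n_per_class)) -
    tcrossprod(colSums(x$means * x$n_per_class)) / sum(x$n_per_class)
  ev <- eigen(x$precision %*% B)
  A <- Re(ev$vectors[, 1:min(2, ncol(ev$vectors)), drop = FALSE])
  sc <- x$x %*% A
  if (ncol(sc) == 1) sc <- cbind(sc, 0)
  cls <- factor(x$y, x$classes)
  graphics::plot(sc[, 1], sc[, 2], col = as.integer(cls),
                 pch = as.integer(cls) %% 25,
                 xlab = "discriminant axis 1", ylab = "discriminant axis 2",
                 ...)
  mu <- x$means %*% A
  graphics::text(mu[, 1], if (ncol(A) > 1) mu[, 2] else 0, x$classes,
                 font = 2)
  invisible(sc)
}

#' @describeIn tclda draw labelled spin systems from the fitted
#'   class-conditional Gaussians (classes sampled from the priors), on the
#'   original feature scale.
#' @param object fitted model.
#' @param nsim number of spin systems to draw.
#' @param seed optional RNG seed.
#' @export
simulate.tclda <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ch <- chol(object$pooled_cov)
  k <- sample(length(object$classes), nsim, replace = TRUE,
              prob = object$priors)
  d <- length(object$features)
  z <- matrix(rnorm(nsim * d), nsim, d) %*% ch + object$means[k, , drop = FALSE]
  x <- sweep(sweep(z, 2, object$scale, "*"), 2, object$center, "+")
  colnames(x) <- object$features
  cbind(data.frame(res_type = object$classes[k], stringsAsFactors = FALSE),
        as.data.frame(x))
}

#' Fit a discriminant model from a per-type statistics table
#'
#' Alternative training pathway when no assigned spin systems of the same
#' protein are available: class means are taken from a per-type
#' mean/standard-deviation table (e.g. database-derived random-coil
#' statistics) and the pooled covariance is diagonal, each feature's
#' variance being the per-class squared standard deviations averaged over
#' classes (classes treated as equally sized).  The resulting object is an
#' ordinary [tclda()] model and uses the same posterior machinery.
#'
#' @param stats a [type_statistics()] table.
#' @param features character vector of feature names.
#' @param priors,sequence,exclude as in [tclda()].
#' @return a `tclda` model.
#' @export
tclda_from_statistics <- function(stats, features = subset_preset("iv"),
                                  priors = "uniform", sequence = NULL,
                                  exclude = NULL) {
  stopifnot(inherits(stats, "type_statistics"))
  types <- setdiff(sort(unique(stats$type)), exclude)
  have <- vapply(types, function(t)
    all(vapply(features, function(f)
      !is.null(stats_lookup(stats, t, f)), logical(1))), logical(1))
  if (any(!have))
    warning("class(es) dropped (no statistics for every feature): ",
            paste(types[!have], collapse = ", "))
  classes <- types[have]
  if (length(classes) < 2)
    stop("fewer than 2 classes have statistics for every feature")
  d <- length(features)
  means <- matrix(0, length(classes), d,
                  dimnames = list(classes, features))
  vars <- matrix(0, length(classes), d)
  for (k in seq_along(classes)) for (j in seq_len(d)) {
    s <- stats_lookup(stats, classes[k], features[j])
    means[k, j] <- s$mean
    vars[k, j] <- s$sd^2
  }
  S <- diag(colMeans(vars), d)
  structure(list(classes = classes,
                 means = means,
                 pooled_cov = S,
                 precision = diag(1 / colMeans(vars), d),
                 priors = make_priors(priors, classes, sequence),
                 center = setNames(rep(0, d), features),
                 scale = setNames(rep(1, d), features),
                 lambda = 0,
                 min_class_size = 0L,
                 n_per_class = rep(NA_integer_, length(classes)),
                 features = features,
                 excluded = union(exclude, types[!have]),
                 x = NULL, y = NULL,
                 call = match.call()),
            class = "tclda")
}

#' Exclude amino-acid classes
#'
#' Removes the given types from labelled training data, a statistics
#' table, or a fitted model (renormalising the priors).  Typical use is
#' excluding glycines (assignment usually obvious) and prolines
#' (invisible in HN-detected spectra).
#'
#' @param x data frame with `res_type`, [type_statistics()] table, or
#'   [tclda()] model.
#' @param types character vector of one-letter codes to remove.
#' @return object of the same kind as `x`.
#' @export
exclude_classes <- function(x, types) UseMethod("exclude_classes")

#' @export
exclude_classes.data.frame <- function(x, types) {
  x[is.na(x$res_type) | !x$res_type %in% types, , drop = FALSE]
}

#' @export
exclude_classes.type_statistics <- function(x, types) {
  type_statistics(as.data.frame(x)[!x$type %in% types, , drop = FALSE])
}

#' @export
exclude_classes.tclda <- function(x, types) {
  keep <- !x$classes %in% types
  if (sum(keep) < 2) stop("fewer than 2 classes would remain")
  if (all(keep)) return(x)
  x$classes <- x$classes[keep]
  x$means <- x$means[keep, , drop = FALSE]
  x$priors <- x$priors[keep] / sum(x$priors[keep])
  x$n_per_class <- x$n_per_class[keep]
  x$excluded <- union(x$excluded, types)
  if (!is.null(x$x)) {
    sel <- x$y %in% x$classes
    x$x <- x$x[sel, , drop = FALSE]
    x$y <- x$y[sel]
  }
  x
}
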