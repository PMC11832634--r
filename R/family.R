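#' Family of discriminant models for incomplete spin systems
#'
#' Real spin systems often lack features (a missing CB, no second
#' temperature series).  Rather than imputing, the classifier is refitted
#' on the training systems that are complete for exactly the features a
#' query carries, so every classification is an ordinary linear
#' discriminant decision on fully observed data.  Fits are cached per
#' feature subset, so queries with the same missingness pattern share one
#' model.
#'
#' @param data labelled training spin systems (see [tclda()]).
#' @param features the base feature set; queries use the largest subset of
#'   it that they carry completely.
#' @param ... further arguments passed to [tclda()] (`priors`, `lambda`,
#'   `min_class_size`, `exclude`, `sequence`).
#' @return an object of class `tclda_family`.
#' @export
tclda_family <- function(data, features = subset_preset("v"), ...) {
  stopifnot(is.data.frame(data))
  args <- list(...)
  keep <- !is.na(data$res_type)
  if (!is.null(args$exclude))
    keep <- keep & !data$res_type %in% args$exclude
  classes <- sort(unique(data$res_type[keep]))
  structure(list(data = data, features = features, args = args,
                 classes = classes, cache = new.env(parent = emptyenv())),
            class = "tclda_family")
}

#' @export
print.tclda_family <- function(x, ...) {
  cat(sprintf(paste0("Discriminant model family: base features %s\n",
                     "  %d cached subset fit(s)\n"),
              paste(x$features, collapse = ", "),
              length(ls(x$cache))))
  invisible(x)
}

family_model <- function(object, subset) {
  key <- paste(subset, collapse = "|")
  if (!is.null(object$cache[[key]])) return(object$cache[[key]])
  model <- tryCatch(
    do.call(tclda, c(list(data = object$data, features = subset,
                          keep_data = FALSE), object$args)),
    error = function(e) structure(list(message = conditionMessage(e)),
                                  class = "tclda_unusable"))
  object$cache[[key]] <- model
  model
}

#' Classify spin systems with automatic subset selection
#'
#' Each query is classified with the model refitted on the largest subset
#' of the family's base features that the query carries completely.
#'
#' @param object a [tclda_family()].
#' @param newdata data frame of query spin systems.
#' @param type `"posterior"` or `"ranked"` as in [predict.tclda()].
#' @param ... unused.
#' @return for `"posterior"`, a matrix with one column per training class
#'   (classes untrainable for a query's subset get probability 0) and
#'   attributes `subset` (list of feature subsets used per row) and
#'   `n_features`.  Queries whose subset supports no model raise an error.
#' @export
predict.tclda_family <- function(object, newdata,
                                 type = c("posterior", "ranked"), ...) {
  type <- match.arg(type)
  n <- nrow(newdata)
  present_cols <- intersect(object$features, names(newdata))
  keys <- vapply(seq_len(n), function(i) {
    avail <- present_cols[!is.na(unlist(newdata[i, present_cols]))]
    paste(avail, collapse = "|")
  }, character(1))
  post <- matrix(0, n, length(object$classes),
                 dimnames = list(rownames(newdata), object$classes))
  used <- vector("list", n)
  for (key in unique(keys)) {
    subset <- strsplit(key, "|", fixed = TRUE)[[1]]
    rows <- which(keys == key)
    if (length(subset) == 0)
      stop("spin system(s) ", paste(rows, collapse = ", "),
           " carry none of the model features")
    model <- family_model(object, subset)
    if (inherits(model, "tclda_unusable"))
      stop("no usable model for feature subset {",
           paste(subset, collapse = ", "), "}: ", model$message)
    p <- predict(model, newdata[rows, , drop = FALSE], type = "posterior")
    post[rows, colnames(p)] <- p
    for (r in rows) used[[r]] <- subset
  }
  attr(post, "subset") <- used
  attr(post, "n_features") <- lengths(used)
  if (type == "ranked")
    return(lapply(seq_len(n), function(i)
      classification_result(post[i, ], subset = used[[i]])))
  post
}
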