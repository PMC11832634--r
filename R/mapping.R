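#' Score one placement of a spin-system chain on the sequence
#'
#' A chain of n unidentified spin systems placed at sequence position
#' `start` covers residues `start ... start+n-1`.  Its score is the sum of
#' log posterior probabilities of each system for the residue type at its
#' position (independent per-position posteriors; no positional
#' weighting).  A position with posterior at or below `floor` makes the
#' placement inadmissible (`-Inf`).
#'
#' @param posteriors numeric matrix, one row per chain position, columns
#'   named by amino-acid type (a [predict.tclda()] /
#'   [predict.tclda_family()] result).  A type absent from the columns has
#'   probability 0.
#' @param sequence character vector of one-letter codes (1-based).
#' @param start 1-based position of the chain's first system.
#' @param floor posterior floor; probabilities `<= floor` give `-Inf`
#'   (default 0: zero-posterior positions are inadmissible, not floored).
#' @return the log score (`<= 0`; `-Inf` if inadmissible).
#' @export
score_placement <- function(posteriors, sequence, start, floor = 0) {
  posteriors <- as.matrix(posteriors)
  n <- nrow(posteriors)
  if (start < 1 || start + n - 1 > length(sequence))
    stop("placement runs outside the sequence (start ", start,
         ", chain length ", n, ", sequence length ", length(sequence), ")")
  types <- sequence[start:(start + n - 1)]
  j <- match(types, colnames(posteriors))
  p <- ifelse(is.na(j), 0, posteriors[cbind(seq_len(n), j)])
  if (any(p <= floor)) return(-Inf)
  sum(log(p))
}

#' Rank all placements of a chain on the sequence
#'
#' Evaluates every start position the chain fits at, applies the optional
#' constraints, and ranks admissible placements by log score (descending;
#' ties by start ascending).  `norm_prob` normalises `exp(log_score)` over
#' the admissible placements.
#'
#' Constraints only remove placements, never reorder them:
#' * `"boundary"`: when a chain boundary flag is `"proline"` the adjacent
#'   sequence position must be a proline (P); `"terminus"` requires the
#'   chain to touch the corresponding sequence end; `"break"` imposes
#'   nothing.
#' * `"overlap"`: the chain must not cover any position in `assigned`.
#'
#' @param chain an [ss_chain()] (boundary flags used by the `"boundary"`
#'   constraint) or `NULL` when only `posteriors` matter.
#' @param posteriors matrix of per-system type posteriors, one row per
#'   chain position.
#' @param sequence character vector of one-letter codes.
#' @param constraints character subset of `c("boundary", "overlap")`.
#' @param assigned integer vector of already-assigned sequence positions.
#' @param floor see [score_placement()].
#' @return data frame of class `placements`: columns `start`, `log_score`,
#'   `norm_prob`, `admissible`, `reason`, sorted admissible-first by
#'   descending score.  Zero admissible placements yield a data frame with
#'   no admissible rows (a diagnostic is attached as attribute
#'   `diagnostic`).
#' @export
rank_placements <- function(chain = NULL, posteriors, sequence,
                            constraints = c("boundary", "overlap"),
                            assigned = integer(0), floor = 0) {
  posteriors <- as.matrix(posteriors)
  n <- nrow(posteriors)
  L <- length(sequence)
  if (n > L) stop("chain (length ", n, ") is longer than the sequence")
  starts <- seq_len(L - n + 1)
  res <- data.frame(start = starts, log_score = -Inf,
                    norm_prob = 0, admissible = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  for (i in seq_along(starts)) {
    s <- starts[i]
    reason <- ""
    if ("boundary" %in% constraints && !is.null(chain)) {
      if (chain$left_boundary == "proline" &&
          (s == 1 || sequence[s - 1] != "P"))
        reason <- "left boundary requires preceding proline"
      else if (chain$left_boundary == "terminus" && s != 1)
        reason <- "left boundary requires N-terminus"
      else if (chain$right_boundary == "proline" &&
               (s + n > L || sequence[s + n] != "P"))
        reason <- "right boundary requires following proline"
      else if (chain$right_boundary == "terminus" && s + n - 1 != L)
        reason <- "right boundary requires C-terminus"
    }
    if (!nzchar(reason) && "overlap" %in% constraints &&
        length(assigned) && any(assigned %in% s:(s + n - 1)))
      reason <- "overlaps assigned residues"
    if (!nzchar(reason)) {
      ls <- score_placement(posteriors, sequence, s, floor = floor)
      if (is.finite(ls)) {
        res$log_score[i] <- ls
        res$admissible[i] <- TRUE
      } else reason <- "zero-posterior position"
    }
    res$reason[i] <- reason
  }
  adm <- which(res$admissible)
  if (length(adm)) {
    m <- max(res$log_score[adm])
    w <- exp(res$log_score[adm] - m)
    res$norm_prob[adm] <- w / sum(w)
  } else {
    attr(res, "diagnostic") <-
      "no admissible placement; check constraints and posterior floor"
  }
  ord <- order(!res$admissible, -res$log_score, res$start)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("placements", "data.frame")
  res
}

#' @export
print.placements <- function(x, top = 5, ...) {
  adm <- x[x$admissible, , drop = FALSE]
  cat(sprintf("%d admissible placement(s) of %d\n", nrow(adm),
              nrow(x)))
  print(as.data.frame(head(adm, top)), row.names = FALSE)
  invisible(x)
}

#' Assignment report for a set of chains
#'
#' For every chain, classifies its spin systems (with automatic subset
#' handling for incomplete systems), ranks its placements on the sequence,
#' and reports the top placements together with the ranked type
#' recognitions per spin system above a display threshold.
#'
#' @param chains list of [ss_chain()] objects.
#' @param systems data frame of (query) spin systems with an `id` column.
#' @param model a [tclda()] or [tclda_family()] object.
#' @param sequence character vector of one-letter codes.
#' @param constraints,assigned,floor passed to [rank_placements()].
#' @param top number of placements reported per chain.
#' @param threshold minimum posterior for a type to be listed (default
#'   0.1: only recognitions above 10% are shown).
#' @return list with `placements` (data frame: chain, rank, start,
#'   log_score, norm_prob) and `types` (data frame: chain, id, position,
#'   type, prob), both deterministic for fixed inputs.
#' @export
assign_report <- function(chains, systems, model, sequence,
                          constraints = c("boundary", "overlap"),
                          assigned = integer(0), floor = 0,
                          top = 5, threshold = 0.1) {
  placements <- list()
  types <- list()
  for (ch in chains) {
    idx <- match(ch$ids, systems$id)
    if (anyNA(idx))
      stop("chain '", ch$name, "' references unknown spin system(s): ",
           paste(ch$ids[is.na(idx)], collapse = ", "))
    q <- systems[idx, , drop = FALSE]
    post <- predict(model, q, type = "posterior")
    pl <- rank_placements(ch, post, sequence, constraints = constraints,
                          assigned = assigned, floor = floor)
    adm <- pl[pl$admissible, , drop = FALSE]
    if (nrow(adm))
      placements[[length(placements) + 1]] <- data.frame(
        chain = ch$name, rank = seq_len(min(top, nrow(adm))),
        start = adm$start[seq_len(min(top, nrow(adm)))],
        log_score = adm$log_score[seq_len(min(top, nrow(adm)))],
        norm_prob = adm$norm_prob[seq_len(min(top, nrow(adm)))],
        stringsAsFactors = FALSE)
    for (i in seq_along(ch$ids)) {
      p <- post[i, ]
      keep <- names(p)[p > threshold]
      keep <- keep[order(-p[keep], keep)]
      if (length(keep))
        types[[length(types) + 1]] <- data.frame(
          chain = ch$name, id = ch$ids[i], position = i,
          type = keep, prob = as.numeric(p[keep]),
          stringsAsFactors = FALSE)
    }
  }
  empty_pl <- data.frame(chain = character(0), rank = integer(0),
                         start = integer(0), log_score = numeric(0),
                         norm_prob = numeric(0))
  empty_ty <- data.frame(chain = character(0), id = character(0),
                         position = integer(0), type = character(0),
                         prob = numeric(0))
  list(placements = if (length(placements))
    do.call(rbind, placements) else empty_pl,
    types = if (length(types)) do.call(rbind, types) else empty_ty)
}
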