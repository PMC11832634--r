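#' Default matching gates
#'
#' Maximum per-dimension displacement (ppm) allowed when pairing peaks
#' between two temperatures: 0.05 ppm for HN and 0.5 ppm for N, C, CA, CB,
#' typical of amide shift changes over a 5 degC step in disordered proteins.
#'
#' @return named numeric vector of gates in ppm.
#' @export
default_gates <- function() c(HN = 0.05, N = 0.5, C = 0.5, CA = 0.5, CB = 0.5)

#' Match peaks between two peak lists
#'
#' Finds the one-to-one correspondence between the peaks of two lists
#' (typically the same spectrum at two temperatures).  Only pairs whose
#' displacement along every dimension is within its gate are allowed; the
#' cost of an allowed pair is the sum over dimensions of
#' (displacement / gate)^2.  The default method solves the global
#' minimum-cost assignment (maximum number of pairs first, then minimum
#' total cost); `method = "greedy"` repeatedly takes the closest remaining
#' pair, which is faster but order-dependent in crowded spectra.
#'
#' When both lists carry parsed assignment labels, peaks with the same
#' residue number and type are paired outright and label pairs override
#' distance (disable with `use_labels = FALSE`).
#'
#' @param A,B [peak_list()] objects sharing the same dimensions.
#' @param gates named numeric vector of per-dimension gates in ppm;
#'   defaults to [default_gates()] for the shared dimensions.
#' @param method `"assignment"` (global optimum) or `"greedy"`.
#' @param use_labels logical; force pairs with equal known assignment
#'   labels?
#' @return an object of class `peak_match`: a list with `pairs` (two-column
#'   integer matrix of row indices into A and B), `unmatched_A`,
#'   `unmatched_B` (integer vectors), `cost` (total normalised distance of
#'   all pairs) and `ambiguous` (data frame of pairs whose second-nearest
#'   alternative was within 10% extra cost, logged for review).
#' @export
match_peaks <- function(A, B, gates = NULL,
                        method = c("assignment", "greedy"),
                        use_labels = TRUE) {
  method <- match.arg(method)
  dims <- pl_dims(A)
  if (!identical(dims, pl_dims(B)))
    stop("peak lists have different dimensions: ",
         paste(dims, collapse = "-"), " vs ",
         paste(pl_dims(B), collapse = "-"))
  if (is.null(gates)) gates <- default_gates()[dims]
  gates <- gates[dims]
  if (anyNA(gates) || any(gates <= 0))
    stop("a positive gate is required for every dimension")
  nA <- nrow(A); nB <- nrow(B)
  forced <- matrix(integer(0), 0, 2)
  if (use_labels && nA > 0 && nB > 0) {
    la <- parse_assignment_labels(A$label)
    lb <- parse_assignment_labels(B$label)
    ka <- ifelse(is.na(la$res_num) | is.na(la$res_type), NA,
                 paste0(la$res_type, la$res_num))
    kb <- ifelse(is.na(lb$res_num) | is.na(lb$res_type), NA,
                 paste0(lb$res_type, lb$res_num))
    common <- intersect(ka[!is.na(ka) & !duplicated(ka)],
                        kb[!is.na(kb) & !duplicated(kb)])
    if (length(common))
      forced <- cbind(match(common, ka), match(common, kb))
  }
  freeA <- setdiff(seq_len(nA), forced[, 1])
  freeB <- setdiff(seq_len(nB), forced[, 2])
  pairs <- forced
  cost_tot <- 0
  if (nrow(forced)) {
    d <- pair_costs(A[forced[, 1], dims, drop = FALSE],
                    B[forced[, 2], dims, drop = FALSE], gates)
    cost_tot <- sum(diag(as.matrix(d)))
  }
  ambiguous <- data.frame(a = integer(0), b = integer(0),
                          cost = numeric(0), runner_up = numeric(0))
  if (length(freeA) && length(freeB)) {
    C <- pair_costs(A[freeA, dims, drop = FALSE],
                    B[freeB, dims, drop = FALSE], gates)
    feasible <- attr(C, "feasible")
    if (method == "assignment") {
      sol <- lap_match(C, feasible)
    } else {
      sol <- greedy_match(C, feasible)
    }
    if (nrow(sol)) {
      for (r in seq_len(nrow(sol))) {
        i <- sol[r, 1]; j <- sol[r, 2]
        alt <- C[i, feasible[i, ], drop = TRUE]
        alt <- sort(alt)
        if (length(alt) > 1 && alt[2] <= alt[1] * 1.1)
          ambiguous <- rbind(ambiguous,
                             data.frame(a = freeA[i], b = freeB[j],
                                        cost = C[i, j], runner_up = alt[2]))
      }
      cost_tot <- cost_tot + sum(C[sol])
      pairs <- rbind(pairs, cbind(freeA[sol[, 1]], freeB[sol[, 2]]))
    }
  }
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(pairs = unname(pairs),
                 unmatched_A = setdiff(seq_len(nA), pairs[, 1]),
                 unmatched_B = setdiff(seq_len(nB), pairs[, 2]),
                 cost = cost_tot,
                 ambiguous = ambiguous),
            class = "peak_match")
}

#' @export
print.peak_match <- function(x, ...) {
  cat(sprintf("Peak match: %d pairs (total cost %.4g), %d/%d unmatched\n",
              nrow(x$pairs), x$cost,
              length(x$unmatched_A), length(x$unmatched_B)))
  if (nrow(x$ambiguous))
    cat(nrow(x$ambiguous), "ambiguous pair(s) logged for review\n")
  invisible(x)
}

# matrix of normalised squared distances; attr "feasible" marks pairs
# within every gate
pair_costs <- function(a, b, gates) {
  na <- nrow(a); nb <- nrow(b)
  C <- matrix(0, na, nb)
  feasible <- matrix(TRUE, na, nb)
  for (d in names(gates)) {
    dd <- outer(a[[d]], b[[d]], "-") / gates[[d]]
    feasible <- feasible & abs(dd) <= 1
    C <- C + dd^2
  }
  attr(C, "feasible") <- feasible
  C
}

# maximum-cardinality minimum-cost matching via a padded square LAP:
# UNMATCH is the price of leaving one peak out; any feasible pair costs
# less than 2*UNMATCH, so cardinality is maximised first.
lap_match <- function(C, feasible) {
  na <- nrow(C); nb <- ncol(C)
  if (!any(feasible)) return(matrix(integer(0), 0, 2))
  UNMATCH <- 1e3
  BIG <- 1e8
  n <- na + nb
  M <- matrix(BIG, n, n)
  M[seq_len(na), seq_len(nb)] <- ifelse(feasible, C, BIG)
  for (i in seq_len(na)) M[i, nb + i] <- UNMATCH
  for (j in seq_len(nb)) M[na + j, j] <- UNMATCH
  M[(na + 1):n, (nb + 1):n] <- 0
  col <- solve_lap(M)
  keep <- which(seq_len(na) <= na & col[seq_len(na)] <= nb)
  keep <- keep[feasible[cbind(keep, col[keep])]]
  cbind(keep, col[keep])
}

greedy_match <- function(C, feasible) {
  out <- matrix(integer(0), 0, 2)
  C2 <- ifelse(feasible, C, Inf)
  while (any(is.finite(C2))) {
    ij <- which(C2 == min(C2), arr.ind = TRUE)[1, , drop = TRUE]
    out <- rbind(out, ij)
    C2[ij[1], ] <- Inf
    C2[, ij[2]] <- Inf
  }
  unname(out)
}

#' Temperature coefficient from two chemical shifts
#'
#' The per-interval temperature coefficient is the slope of chemical shift
#' against temperature over one interval,
#' `1000 * (shift_high - shift_low) / (T_high - T_low)`, in ppb/K
#' (temperature differences in degC equal differences in K).  Positive
#' values mean a downfield shift with increasing temperature.
#'
#' @param shift_low,shift_high chemical shifts (ppm) at the two
#'   temperatures.
#' @param t_low,t_high the two temperatures in degC; must differ.
#' @return temperature coefficient(s) in ppb/K (vectorised).
#' @export
compute_tc <- function(shift_low, shift_high, t_low, t_high) {
  if (any(t_high == t_low)) stop("temperatures must differ")
  1000 * (shift_high - shift_low) / (t_high - t_low)
}

#' Per-interval temperature coefficients for linked spin systems
#'
#' Given the same set of spin systems observed at two or more temperatures
#' (rows linked by `id`), computes one temperature coefficient per nucleus
#' per consecutive temperature interval.  A shift missing at either end of
#' an interval yields a missing coefficient; nothing is imputed.
#'
#' @param systems_by_temperature list of spin-system data frames (columns
#'   `id` plus shift columns), one per temperature, same ids.
#' @param temperatures numeric vector of temperatures (degC), strictly
#'   increasing, same length as the list.
#' @return data frame with columns `id`, `nucleus`, `interval` (1-based
#'   index of the consecutive interval), `t_low`, `t_high`, `tc` (ppb/K,
#'   `NA` when either shift is missing).
#' @export
tc_table <- function(systems_by_temperature, temperatures) {
  k <- length(systems_by_temperature)
  if (k < 2) stop("need at least two temperatures")
  if (length(temperatures) != k)
    stop("one temperature per spin-system table required")
  if (any(diff(temperatures) <= 0))
    stop("temperatures must be strictly increasing")
  ids <- unique(unlist(lapply(systems_by_temperature, function(d) d$id)))
  out <- list()
  for (iv in seq_len(k - 1)) {
    lo <- systems_by_temperature[[iv]]
    hi <- systems_by_temperature[[iv + 1]]
    nucs <- intersect(DIMS, intersect(names(lo), names(hi)))
    lo_i <- match(ids, lo$id)
    hi_i <- match(ids, hi$id)
    for (nuc in nucs) {
      s_lo <- lo[[nuc]][lo_i]
      s_hi <- hi[[nuc]][hi_i]
      tc <- ifelse(is.na(s_lo) | is.na(s_hi), NA_real_,
                   1000 * (s_hi - s_lo) /
                     (temperatures[iv + 1] - temperatures[iv]))
      out[[length(out) + 1]] <- data.frame(
        id = ids, nucleus = nuc, interval = iv,
        t_low = temperatures[iv], t_high = temperatures[iv + 1],
        tc = tc, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(match(res$id, ids), match(res$nucleus, DIMS), res$interval), ,
      drop = FALSE]
}

#' Attach temperature-coefficient columns to a spin-system table
#'
#' Spreads a long [tc_table()] result into `TC<interval>_<nucleus>` columns
#' joined onto `systems` by `id`.
#'
#' @param systems spin-system data frame with an `id` column.
#' @param tcs long-format coefficient table from [tc_table()].
#' @return `systems` with one additional column per (interval, nucleus).
#' @export
merge_tcs <- function(systems, tcs) {
  for (iv in sort(unique(tcs$interval))) {
    for (nuc in unique(tcs$nucleus[tcs$interval == iv])) {
      sub <- tcs[tcs$interval == iv & tcs$nucleus == nuc, ]
      systems[[sprintf("TC%d_%s", iv, nuc)]] <-
        sub$tc[match(systems$id, sub$id)]
    }
  }
  systems
}
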