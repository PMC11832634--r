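#' Configuration for the synthetic spin-system generator
#'
#' The generator emulates a variable-temperature backbone assignment
#' study: per-residue chemical shifts drawn from per-type Gaussians, a
#' linear shift-temperature dependence with per-nucleus temperature
#' coefficients drawn from per-type TC Gaussians, measurement noise, and
#' optional missingness.  Prolines produce no HN-rooted spin system and
#' glycines no CB.  Defaults mirror a typical disordered-protein study:
#' spectra at 5, 10 and 15 degC and a 239-residue protein whose random
#' composition contains about 12% glycine and 11% proline.
#'
#' @param sequence character vector of one-letter codes, or `NULL` to
#'   sample one.
#' @param length protein length used when `sequence` is `NULL`.
#' @param composition named numeric vector of residue frequencies used
#'   when sampling a sequence (default: G 28/239, P 26/239, remainder
#'   uniform).
#' @param stats a [type_statistics()] table supplying per-type shift and
#'   TC means/sds; default [default_statistics()].
#' @param temperatures strictly increasing vector of temperatures (degC).
#' @param noise named per-nucleus measurement noise sd (ppm), applied
#'   independently to every measured shift.
#' @param missingness named per-nucleus probability that a shift is
#'   unobserved at a given temperature.
#' @param distinct_intervals if `TRUE` and the statistics table carries
#'   `TC2_*` rows, the second-interval coefficient is drawn separately;
#'   otherwise one coefficient applies to all intervals.
#' @param seed integer RNG seed; the whole generation is reproducible
#'   from it.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(sequence = NULL, length = 239,
                             composition = NULL,
                             stats = default_statistics(),
                             temperatures = c(5, 10, 15),
                             noise = c(HN = 0.002, N = 0.02, C = 0.02,
                                       CA = 0.02, CB = 0.02),
                             missingness = c(HN = 0, N = 0, C = 0,
                                             CA = 0, CB = 0),
                             distinct_intervals = FALSE,
                             seed = 1L) {
  if (is.null(composition)) {
    composition <- setNames(rep((1 - 28 / 239 - 26 / 239) / 18, 20), AA20)
    composition["G"] <- 28 / 239
    composition["P"] <- 26 / 239
  }
  if (!is.null(sequence)) {
    bad <- setdiff(unique(sequence), AA20)
    if (length(bad)) stop("unknown residue letter(s): ",
                          paste(bad, collapse = ", "))
  }
  if (any(diff(temperatures) <= 0) || length(temperatures) < 2)
    stop("temperatures must be strictly increasing, length >= 2")
  noise <- fill_named(noise, DIMS, 0)
  missingness <- fill_named(missingness, DIMS, 0)
  if (any(noise < 0)) stop("noise sds must be >= 0")
  if (any(missingness < 0 | missingness > 1))
    stop("missingness rates must be in [0, 1]")
  structure(list(sequence = sequence, length = length,
                 composition = composition / sum(composition),
                 stats = stats, temperatures = temperatures,
                 noise = noise, missingness = missingness,
                 distinct_intervals = distinct_intervals,
                 seed = as.integer(seed)),
            class = "generator_config")
}

fill_named <- function(x, names_all, default) {
  out <- setNames(rep(default, length(names_all)), names_all)
  out[names(x)] <- x
  out
}

#' Generate a synthetic protein with known ground truth
#'
#' Draws, for every residue, base chemical shifts and per-nucleus
#' temperature coefficients from the per-type Gaussians of the
#' configuration's statistics table; the shift at temperature T follows
#' the (piecewise) linear model
#' `shift(T) = shift(T0) + TC * (T - T0) / 1000` plus measurement noise.
#' Missingness is applied after generation; the truth table records every
#' latent value.
#'
#' @param config a [generator_config()].
#' @param label_peaks write assignment labels (`"T212N-H"` style) into the
#'   emitted peak lists?
#' @return list with components
#'   `systems` (labelled spin-system data frame at the base temperature,
#'   with `TC1_*`/`TC2_*` columns computed from the measured shifts;
#'   prolines absent),
#'   `systems_by_temperature` (list of id/shift tables, one per
#'   temperature),
#'   `peak_lists` (per temperature: HSQC, HNCO, HNCOCA and CBCACONH
#'   [peak_list()]s),
#'   `truth` (latent base shifts and interval TCs per residue and
#'   nucleus) and `sequence`.
#' @export
sample_protein <- function(config, label_peaks = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  seqn <- config$sequence
  if (is.null(seqn))
    seqn <- sample(names(config$composition), config$length,
                   replace = TRUE, prob = config$composition)
  L <- length(seqn)
  temps <- config$temperatures
  nT <- length(temps)
  stats <- config$stats
  truth <- list()
  meas <- list()  # per residue: matrix nucleus x temperature
  for (i in seq_len(L)) {
    t <- seqn[i]
    nucs <- DIMS[vapply(DIMS, function(nu)
      !is.null(stats_lookup(stats, t, nu)), logical(1))]
    if (t == "P") nucs <- setdiff(nucs, "HN")  # no amide proton
    if (t == "G") nucs <- setdiff(nucs, "CB")
    m <- matrix(NA_real_, length(nucs), nT,
                dimnames = list(nucs, paste0("T", temps)))
    for (nu in nucs) {
      s <- stats_lookup(stats, t, nu)
      base <- rnorm(1, s$mean, s$sd)
      tc1s <- stats_lookup(stats, t, paste0("TC1_", nu))
      tc1 <- if (is.null(tc1s)) 0 else rnorm(1, tc1s$mean, tc1s$sd)
      tcs <- rep(tc1, nT - 1)
      if (config$distinct_intervals && nT > 2) {
        for (iv in 2:(nT - 1)) {
          t2s <- stats_lookup(stats, t, paste0("TC", iv, "_", nu))
          if (!is.null(t2s)) tcs[iv] <- rnorm(1, t2s$mean, t2s$sd)
        }
      }
      latent <- cumsum(c(base, tcs * diff(temps) / 1000))[seq_len(nT)]
      observed <- latent + rnorm(nT, 0, config$noise[[nu]])
      observed[stats::runif(nT) < config$missingness[[nu]]] <- NA
      m[nu, ] <- observed
      truth[[length(truth) + 1]] <- data.frame(
        res_num = i, res_type = t, nucleus = nu, base_shift = base,
        tc = I(list(tcs)), stringsAsFactors = FALSE)
    }
    meas[[i]] <- m
  }
  truth <- do.call(rbind, truth)
  for (iv in seq_len(nT - 1))
    truth[[sprintf("tc%d", iv)]] <- vapply(truth$tc, `[`, numeric(1), iv)
  truth$tc <- NULL
  # spin systems: one per non-proline residue
  keep <- which(seqn != "P")
  ids <- sprintf("ss%03d", keep)
  sbt <- lapply(seq_len(nT), function(k) {
    d <- data.frame(id = ids, stringsAsFactors = FALSE)
    for (nu in DIMS)
      d[[nu]] <- vapply(keep, function(i)
        if (nu %in% rownames(meas[[i]])) meas[[i]][nu, k] else NA_real_,
        numeric(1))
    d
  })
  systems <- data.frame(id = ids, res_type = seqn[keep], res_num = keep,
                        stringsAsFactors = FALSE)
  systems <- cbind(systems, sbt[[1]][DIMS])
  tcs <- tc_table(sbt, temps)
  systems <- merge_tcs(systems, tcs)
  truth$id <- ifelse(truth$res_num %in% keep,
                     sprintf("ss%03d", truth$res_num), NA_character_)
  peak_lists <- lapply(seq_len(nT), function(k)
    emit_peak_lists(seqn, meas, k, temps[k], label_peaks))
  names(peak_lists) <- paste0("T", temps)
  list(systems = systems, systems_by_temperature = sbt,
       peak_lists = peak_lists, truth = truth, sequence = seqn)
}

emit_peak_lists <- function(seqn, meas, k, temp, label_peaks) {
  L <- length(seqn)
  root_ok <- vapply(seq_len(L), function(i)
    all(c("HN", "N") %in% rownames(meas[[i]])) &&
      !is.na(meas[[i]]["HN", k]) && !is.na(meas[[i]]["N", k]),
    logical(1))
  lab <- function(i, mid = NULL)
    if (!label_peaks) "?-?"
    else paste(c(paste0(seqn[i], i, "N"), mid, "H"), collapse = "-")
  get <- function(i, nu)
    if (nu %in% rownames(meas[[i]])) meas[[i]][nu, k] else NA_real_
  roots <- which(root_ok)
  hsqc <- peak_list(cbind(vapply(roots, get, numeric(1), nu = "N"),
                          vapply(roots, get, numeric(1), nu = "HN")),
                    dims = c("N", "HN"),
                    labels = vapply(roots, lab, character(1)),
                    experiment = "HSQC", temperature = temp)
  three_d <- function(nu, dim_label, exp_name) {
    sel <- roots[!is.na(vapply(roots, get, numeric(1), nu = nu))]
    peak_list(cbind(vapply(sel, get, numeric(1), nu = "N"),
                    vapply(sel, get, numeric(1), nu = nu),
                    vapply(sel, get, numeric(1), nu = "HN")),
              dims = c("N", dim_label, "HN"),
              labels = vapply(sel, lab, character(1), mid = dim_label),
              experiment = exp_name, temperature = temp)
  }
  cbca_sel <- roots[!is.na(vapply(roots, get, numeric(1), nu = "CA")) |
                      !is.na(vapply(roots, get, numeric(1), nu = "CB"))]
  rows <- list(); labs <- character(0)
  for (i in cbca_sel) for (nu in c("CA", "CB")) {
    v <- get(i, nu)
    if (!is.na(v)) {
      rows[[length(rows) + 1]] <- c(get(i, "N"), v, get(i, "HN"))
      labs <- c(labs, lab(i, mid = nu))
    }
  }
  if (!length(rows)) rows <- list(matrix(numeric(0), 0, 3))
  cbca <- peak_list(do.call(rbind, rows), dims = c("N", "CA", "HN"),
                    labels = labs, experiment = "CBCACONH",
                    temperature = temp)
  list(HSQC = hsqc,
       HNCO = three_d("C", "C", "HNCO"),
       HNCOCA = three_d("CA", "CA", "HNCOCA"),
       CBCACONH = cbca)
}

#' Train/query benchmark split
#'
#' Partitions the generated spin systems into a labelled training set and
#' an unlabelled query set, mirroring the practical situation where part
#' of a protein is already assigned and short chains between prolines
#' remain to be typed and mapped.  Query residues forming runs of
#' consecutive sequence positions are returned as chains with boundary
#' flags (`"proline"`, `"terminus"` or `"break"`).
#'
#' Sizes follow `round(fraction * n_assignable)` (base-R `round`), where
#' assignable residues are the non-prolines; the query size is capped by
#' what the training split leaves over.
#'
#' @param config a [generator_config()].
#' @param n_train_fraction fraction of assignable residues used for
#'   training, in (0, 1).
#' @param ambiguous_fraction fraction treated as unassigned queries, in
#'   (0, 1).
#' @return list with `train` (labelled systems), `query` (systems with
#'   `res_type`/`res_num` blanked), `chains` (list of [ss_chain()]),
#'   `truth`, `sequence` and the full `systems` table.
#' @export
make_benchmark <- function(config, n_train_fraction = 0.6,
                           ambiguous_fraction = 0.4) {
  if (n_train_fraction <= 0 || n_train_fraction >= 1 ||
      ambiguous_fraction <= 0 || ambiguous_fraction >= 1)
    stop("fractions must lie strictly inside (0, 1)")
  sp <- sample_protein(config)
  sys <- sp$systems
  n <- nrow(sys)
  n_train <- round(n_train_fraction * n)
  n_query <- min(n - n_train, round(ambiguous_fraction * n))
  if (n_train < 1 || n_query < 1)
    stop("degenerate split: train ", n_train, ", query ", n_query)
  qi <- sort(sample(n, n_query))
  ti <- sort(sample(setdiff(seq_len(n), qi), n_train))
  train <- sys[ti, , drop = FALSE]
  query <- sys[qi, , drop = FALSE]
  truth_query <- query[c("id", "res_type", "res_num")]
  query$res_type <- NA_character_
  query$res_num <- NA_integer_
  chains <- extract_chains(sys$res_num[qi], sys$id[qi], sp$sequence)
  list(train = train, query = query, chains = chains,
       query_truth = truth_query, truth = sp$truth,
       sequence = sp$sequence, systems = sys)
}

# group query residues into runs of consecutive sequence positions and
# flag what bounds each run
extract_chains <- function(res_nums, ids, sequence) {
  o <- order(res_nums)
  res_nums <- res_nums[o]; ids <- ids[o]
  runs <- split(seq_along(res_nums),
                cumsum(c(1, diff(res_nums) != 1)))
  L <- length(sequence)
  lapply(seq_along(runs), function(r) {
    ii <- runs[[r]]
    a <- res_nums[ii[1]]; b <- res_nums[ii[length(ii)]]
    left <- if (a == 1) "terminus"
    else if (sequence[a - 1] == "P") "proline" else "break"
    right <- if (b == L) "terminus"
    else if (sequence[b + 1] == "P") "proline" else "break"
    ss_chain(ids[ii], left, right, name = sprintf("chain_%d_%d", a, b))
  })
}

#' Synthetic per-type statistics table
#'
#' Returns the packaged per-amino-acid-type table of chemical-shift and
#' temperature-coefficient means and standard deviations used as the
#' default generator input and as the statistics-based training example.
#' The values are a synthetic approximation of random-coil behaviour
#' (shipped as `inst/extdata/type_statistics_synthetic.csv`); they are a
#' fixture for simulation and testing, not literature reference values.
#' Glycine has no CB entries and proline no HN entries.
#'
#' @return a [type_statistics()] table.
#' @export
default_statistics <- function() {
  path <- system.file("extdata", "type_statistics_synthetic.csv",
                      package = "tcassign", mustWork = TRUE)
  read_statistics_table(path)
}

#' Well-separated benchmark statistics
#'
#' Builds a deliberately well-separated 18-class statistics table (no
#' glycine or proline) for closed-loop validation: the CA shift separates
#' the classes by ten standard deviations, the other shift features are
#' uninformative, and (optionally) pairs of classes are made
#' indistinguishable by shifts alone while their first-interval HN
#' temperature coefficients differ by `tc_gap_sd` standard deviations -
#' exactly the situation where TCs rescue the classification.
#'
#' @param tied_pairs list of length-2 character vectors: class pairs given
#'   identical shift distributions (`NULL` for none).
#' @param tc_gap_sd separation of the tied pairs' `TC1_HN` means, in sd
#'   units.
#' @return a [type_statistics()] table.
#' @export
benchmark_statistics <- function(tied_pairs = list(c("K", "Q"),
                                                   c("I", "V")),
                                 tc_gap_sd = 3) {
  aa18 <- setdiff(AA20, c("G", "P"))
  ca_sd <- 0.25
  ca_mean <- setNames(40 + 2.5 * seq_along(aa18), aa18)
  tc_sd <- c(HN = 1.2, N = 1.0, C = 1.0, CA = 1.0, CB = 1.0)
  tc_mean <- matrix(0, length(aa18), 5,
                    dimnames = list(aa18, DIMS))
  for (pair in tied_pairs) {
    if (!all(pair %in% aa18)) stop("tied pair outside the 18 classes")
    ca_mean[pair[2]] <- ca_mean[pair[1]]
    tc_mean[pair[1], "HN"] <- -tc_gap_sd * tc_sd[["HN"]] / 2
    tc_mean[pair[2], "HN"] <- +tc_gap_sd * tc_sd[["HN"]] / 2
  }
  shift_mean <- c(HN = 8.2, N = 119, C = 176, CB = 35)
  shift_sd <- c(HN = 0.08, N = 0.5, C = 0.3, CA = ca_sd, CB = 0.3)
  rows <- list()
  add <- function(type, feature, mean, sd)
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, feature = feature, mean = mean, sd = sd,
      stringsAsFactors = FALSE)
  for (t in aa18) {
    for (nu in DIMS) {
      add(t, nu, if (nu == "CA") ca_mean[[t]] else shift_mean[[nu]],
          shift_sd[[nu]])
      add(t, paste0("TC1_", nu), tc_mean[t, nu], tc_sd[[nu]])
      add(t, paste0("TC2_", nu), tc_mean[t, nu], tc_sd[[nu]])
    }
  }
  type_statistics(do.call(rbind, rows))
}
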