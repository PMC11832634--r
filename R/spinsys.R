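#' Assemble spin systems from triple-resonance peak lists
#'
#' Groups peaks from carbon-dimension experiments under their amide (HN, N)
#' roots.  Each root collects, from every attached list, the third-dimension
#' shifts of peaks lying within `tol` of the root in both HN and N.  The
#' experiment type decides where the carbon shift is stored:
#'
#' * `HNCO`-type lists contribute the carbonyl shift `C`;
#' * `HN(CO)CA`-type lists contribute `CA`;
#' * `CBCA`-type lists (e.g. (HBHA)CBCA(CO)NH) contribute a CA/CB pair.
#'   When an HN(CO)CA-derived CA is available for the root, the CBCA peak
#'   within `ca_tol` of it becomes CA and the other CB; otherwise the
#'   larger shift inside the 40-70 ppm CA range is taken as CA (documented
#'   heuristic).  A single CBCA peak (glycine-like root) is stored as CA
#'   when it falls in the CA range, else as CB.
#'
#' Multiple candidate peaks for one slot are never silently overwritten:
#' the nearest is kept and the event is recorded in the `conflicts`
#' attribute.  Every stored shift is traceable to its source peak through
#' the `provenance` attribute.
#'
#' @param roots [peak_list()] of amide roots (an HSQC or an HN/N
#'   projection) with dimensions including HN and N.
#' @param attached named list of [peak_list()] objects; names identify the
#'   experiment (matched case-insensitively against HNCO / HN(CO)CA /
#'   CBCA patterns).
#' @param tol named numeric vector with elements `HN` and `N`: matching
#'   tolerance around the root, in ppm.
#' @param ca_tol tolerance (ppm) for recognising the HN(CO)CA CA value
#'   among CBCA peaks.
#' @return spin-system data frame (one row per root; columns `id`,
#'   `res_type`, `res_num`, `HN`, `N`, `C`, `CA`, `CB`) with attributes
#'   `provenance` and `conflicts`.
#' @export
assemble_spin_systems <- function(roots, attached,
                                  tol = c(HN = 0.02, N = 0.2),
                                  ca_tol = 0.3) {
  if (!all(c("HN", "N") %in% pl_dims(roots)))
    stop("root list must have HN and N dimensions")
  if (is.null(names(attached)) || any(!nzchar(names(attached))))
    stop("attached peak lists must be named by experiment")
  kinds <- vapply(names(attached), experiment_kind, character(1))
  lab <- parse_assignment_labels(roots$label)
  n <- nrow(roots)
  sys <- data.frame(id = ifelse(is.na(lab$res_num),
                                sprintf("ss%03d", seq_len(n)),
                                paste0(lab$res_type, lab$res_num)),
                    res_type = lab$res_type, res_num = lab$res_num,
                    HN = roots$HN, N = roots$N,
                    C = NA_real_, CA = NA_real_, CB = NA_real_,
                    stringsAsFactors = FALSE)
  prov <- list()
  confl <- list()
  note <- function(lst, ...) c(lst, list(data.frame(..., stringsAsFactors = FALSE)))
  for (e in seq_along(attached)) {
    pl <- attached[[e]]
    kind <- kinds[e]
    dims <- pl_dims(pl)
    if (!all(c("HN", "N") %in% dims))
      stop("attached list '", names(attached)[e], "' lacks HN or N")
    third <- setdiff(dims, c("HN", "N"))
    if (length(third) != 1)
      stop("attached list '", names(attached)[e],
           "' must have exactly one carbon dimension")
    for (i in seq_len(n)) {
      hit <- which(abs(pl$HN - roots$HN[i]) <= tol[["HN"]] &
                     abs(pl$N - roots$N[i]) <= tol[["N"]])
      if (!length(hit)) next
      d2 <- ((pl$HN[hit] - roots$HN[i]) / tol[["HN"]])^2 +
        ((pl$N[hit] - roots$N[i]) / tol[["N"]])^2
      hit <- hit[order(d2)]
      vals <- pl[[third]][hit]
      if (kind %in% c("HNCO", "HNCOCA")) {
        slot <- if (kind == "HNCO") "C" else "CA"
        if (length(hit) > 1)
          confl <- note(confl, system = sys$id[i], experiment = names(attached)[e],
                        slot = slot, kept = vals[1],
                        discarded = paste(format(vals[-1]), collapse = ";"))
        sys[[slot]][i] <- vals[1]
        prov <- note(prov, system = sys$id[i], nucleus = slot,
                     experiment = names(attached)[e], peak = hit[1])
      } else if (kind == "CBCA") {
        if (length(hit) > 2) {
          confl <- note(confl, system = sys$id[i], experiment = names(attached)[e],
                        slot = "CA/CB", kept = NA_real_,
                        discarded = paste(format(vals[-(1:2)]), collapse = ";"))
          hit <- hit[1:2]; vals <- vals[1:2]
        }
        ca_ref <- sys$CA[i]
        if (length(hit) == 1) {
          if (!is.na(ca_ref) && abs(vals - ca_ref) <= ca_tol) {
            # the peak restates the HN(CO)CA-derived CA; nothing new
            next
          }
          slot <- if (is.na(ca_ref) && vals >= 40 && vals <= 70) "CA"
          else "CB"
          sys[[slot]][i] <- vals
          prov <- note(prov, system = sys$id[i], nucleus = slot,
                       experiment = names(attached)[e], peak = hit)
        } else {
          if (!is.na(ca_ref) && any(abs(vals - ca_ref) <= ca_tol)) {
            # CA already known: only the non-matching peak is new (CB)
            cb_j <- which.max(abs(vals - ca_ref))
            sys$CB[i] <- vals[cb_j]
            prov <- note(prov, system = sys$id[i], nucleus = "CB",
                         experiment = names(attached)[e], peak = hit[cb_j])
            next
          }
          in_range <- vals >= 40 & vals <= 70
          ca_j <- if (any(in_range)) which(in_range)[which.max(vals[in_range])]
          else NA_integer_
          if (is.na(ca_j)) {       # both outside the CA range: keep one CB
            sys$CB[i] <- vals[1]
            prov <- note(prov, system = sys$id[i], nucleus = "CB",
                         experiment = names(attached)[e], peak = hit[1])
          } else {
            cb_j <- setdiff(1:2, ca_j)
            sys$CA[i] <- vals[ca_j]
            sys$CB[i] <- vals[cb_j]
            prov <- note(prov, system = sys$id[i], nucleus = "CA",
                         experiment = names(attached)[e], peak = hit[ca_j])
            prov <- note(prov, system = sys$id[i], nucleus = "CB",
                         experiment = names(attached)[e], peak = hit[cb_j])
          }
        }
      } else {
        stop("unrecognised experiment kind for '", names(attached)[e], "'")
      }
    }
  }
  bindrows <- function(l) if (length(l)) do.call(rbind, l) else
    data.frame()
  structure(sys,
            provenance = bindrows(prov),
            conflicts = bindrows(confl))
}

# classify an experiment name into the nucleus it contributes
experiment_kind <- function(name) {
  s <- gsub("[^A-Z]", "", toupper(name))
  if (grepl("CBCA|CACB", s)) "CBCA"
  else if (grepl("HNCACO", s)) "HNCO"            # HN(CA)CO measures C'
  else if (grepl("HNCOCA|HNCA", s)) "HNCOCA"     # CA-contributing
  else if (grepl("HNCO", s)) "HNCO"
  else stop("cannot classify experiment '", name,
            "' as HNCO-, HN(CO)CA- or CBCA-type")
}

#' Does a spin system carry every feature of a subset?
#'
#' @param s one spin system: a one-row data frame or a named vector/list
#'   of features.
#' @param subset character vector of feature names (see [subset_preset()]).
#' @return `TRUE` iff every feature in `subset` is present (non-missing).
#' @export
complete_feature_set <- function(s, subset) {
  if (is.data.frame(s)) {
    if (nrow(s) != 1) stop("s must be a single spin system")
    s <- as.list(s)
  }
  all(vapply(subset, function(f)
    !is.null(s[[f]]) && !is.na(s[[f]]), logical(1)))
}

#' Construct a spin-system chain
#'
#' A chain is an ordered run of sequentially connected, unidentified spin
#' systems together with flags describing why it ends on each side:
#' `"proline"` (the neighbouring residue is a proline, invisible in
#' HN-detected spectra), `"break"` (missing peaks) or `"terminus"`.
#'
#' @param ids character vector of spin-system ids, in sequence order.
#' @param left_boundary,right_boundary boundary flags.
#' @param name chain name.
#' @return an object of class `ss_chain`.
#' @export
ss_chain <- function(ids, left_boundary = "break", right_boundary = "break",
                     name = paste(ids[1], "chain")) {
  flags <- c("proline", "break", "terminus")
  if (length(ids) < 1) stop("a chain needs at least one spin system")
  structure(list(name = name, ids = as.character(ids),
                 left_boundary = match.arg(left_boundary, flags),
                 right_boundary = match.arg(right_boundary, flags)),
            class = "ss_chain")
}

#' @export
print.ss_chain <- function(x, ...) {
  cat(sprintf("Chain '%s': %d systems [%s | %s], boundaries %s/%s\n",
              x$name, length(x$ids), x$ids[1], x$ids[length(x$ids)],
              x$left_boundary, x$right_boundary))
  invisible(x)
}

#' Read or write chains as JSON
#'
#' @param path JSON file path.
#' @return `read_chains`: list of [ss_chain()] objects.
#' @export
read_chains <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw$chains)) {
    raw <- lapply(seq_len(nrow(raw$chains)), function(i)
      as.list(raw$chains[i, ]))
  } else raw <- raw$chains
  lapply(raw, function(ch)
    ss_chain(unlist(ch$ids), ch$left_boundary, ch$right_boundary, ch$name))
}

#' @rdname read_chains
#' @param chains list of [ss_chain()] objects.
#' @export
write_chains <- function(chains, path) {
  jsonlite::write_json(
    list(chains = lapply(chains, function(ch)
      list(name = ch$name, ids = as.list(ch$ids),
           left_boundary = ch$left_boundary,
           right_boundary = ch$right_boundary))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
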