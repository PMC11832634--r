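#' @importFrom utils read.csv write.csv head modifyList
#' @importFrom stats rnorm setNames predict simulate coef
NULL

# Controlled vocabulary of peak-list dimensions: backbone amide proton and
# nitrogen, carbonyl (C), alpha and beta carbons.
DIMS <- c("HN", "N", "C", "CA", "CB")

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a peak list
#'
#' A peak list is a data frame with one row per peak, a `label` column
#' (Sparky assignment string, `"?-?"` style for unassigned peaks) and one
#' numeric column per dimension, in ppm.  The experiment name, sample
#' temperature (degrees Celsius) and dimension order are carried as
#' attributes.
#'
#' @param shifts numeric matrix or data frame of chemical shifts (ppm),
#'   one column per dimension.
#' @param dims character vector of dimension labels, a subset of
#'   `c("HN","N","C","CA","CB")`, matching the columns of `shifts`.
#' @param labels optional character vector of assignment labels.
#' @param experiment experiment name, e.g. `"HSQC"` or `"HNCO"`.
#' @param temperature sample temperature in degrees Celsius.
#' @param heights optional numeric vector of peak heights.
#' @return an object of class `peak_list` (a data frame).
#' @export
peak_list <- function(shifts, dims, labels = NULL, experiment = "unknown",
                      temperature = NA_real_, heights = NULL) {
  shifts <- as.data.frame(shifts)
  dims <- match.arg(as.character(dims), DIMS, several.ok = TRUE)
  if (anyDuplicated(dims))
    stop("duplicate dimension labels")
  if (ncol(shifts) != length(dims))
    stop("shifts has ", ncol(shifts), " columns but ", length(dims),
         " dimension labels were given")
  names(shifts) <- dims
  if (nrow(shifts) > 0 && !all(vapply(shifts, is.numeric, logical(1))))
    stop("all shifts must be numeric")
  if (nrow(shifts) > 0 && !all(is.finite(as.matrix(shifts))))
    stop("all shifts must be finite")
  if (is.null(labels)) labels <- rep("?-?", nrow(shifts))
  df <- cbind(data.frame(label = as.character(labels),
                         stringsAsFactors = FALSE), shifts)
  if (!is.null(heights)) df$height <- as.numeric(heights)
  structure(df,
            experiment = experiment,
            temperature = as.numeric(temperature),
            dims = dims,
            class = c("peak_list", "data.frame"))
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Peak list '%s' at %s degC: %d peaks, dimensions %s\n",
              attr(x, "experiment"),
              format(attr(x, "temperature")), nrow(x),
              paste(attr(x, "dims"), collapse = "-")))
  print(as.data.frame(head(x, 10)))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more peaks)\n", sep = "")
  invisible(x)
}

pl_dims <- function(x) attr(x, "dims")
pl_temperature <- function(x) attr(x, "temperature")

#' Read a Sparky peak list
#'
#' Reads the common whitespace-separated Sparky `.list` export: an optional
#' header line starting with "Assignment", then one row per peak with the
#' assignment label in the first column followed by one chemical shift (ppm)
#' per dimension.  A trailing numeric column, if present, is interpreted as
#' the peak height only when `height = TRUE`; otherwise it is ignored.
#'
#' @param path path to the `.list` file.
#' @param experiment experiment name to tag the list with.
#' @param temperature sample temperature in degrees Celsius.
#' @param dims dimension labels in file column order (see [peak_list()]).
#' @param height logical; keep a trailing height column?
#' @return a [peak_list()].
#' @export
read_sparky_list <- function(path, experiment = "unknown",
                             temperature = NA_real_, dims, height = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  dims <- match.arg(as.character(dims), DIMS, several.ok = TRUE)
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*$", lines) & !grepl("^\\s*Assignment", lines) &
    !grepl("^\\s*#", lines)
  rows <- which(is_data)
  if (length(rows) == 0) {
    warning("empty peak list: ", path)
    return(peak_list(matrix(numeric(0), 0, length(dims)), dims,
                     experiment = experiment, temperature = temperature))
  }
  nd <- length(dims)
  labs <- character(length(rows))
  mat <- matrix(NA_real_, length(rows), nd)
  hts <- rep(NA_real_, length(rows))
  for (i in seq_along(rows)) {
    ln <- rows[i]
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < nd + 1)
      stop("line ", ln, ": expected at least ", nd + 1,
           " columns (label + ", nd, " shifts), found ", length(tok))
    vals <- suppressWarnings(as.numeric(tok[2:(nd + 1)]))
    if (anyNA(vals))
      stop("line ", ln, ": non-numeric chemical shift in '", lines[ln], "'")
    labs[i] <- tok[1]
    mat[i, ] <- vals
    if (height && length(tok) >= nd + 2)
      hts[i] <- suppressWarnings(as.numeric(tok[nd + 2]))
  }
  peak_list(mat, dims, labels = labs, experiment = experiment,
            temperature = temperature,
            heights = if (height) hts else NULL)
}

#' Write a Sparky peak list
#'
#' @param x a [peak_list()].
#' @param path output file path.
#' @param digits decimal places for chemical shifts.
#' @return `path`, invisibly.
#' @export
write_sparky_list <- function(x, path, digits = 3) {
  dims <- pl_dims(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(" Assignment",
                     sprintf("w%d", seq_along(dims))), collapse = "  "), con)
  writeLines("", con)
  if (nrow(x) > 0) {
    fmt <- paste0("%.", digits, "f")
    body <- apply(as.matrix(x[dims]), 1,
                  function(v) paste(sprintf(fmt, v), collapse = "  "))
    writeLines(paste(format(x$label, width = 12), body, sep = "  "), con)
  }
  invisible(path)
}

#' Parse a Sparky assignment label
#'
#' Understands labels such as `"T212N-H"`, `"G45N-HN"`, `"S3N-C-H"` and the
#' unassigned convention `"?-?"`.  The residue type and number are taken from
#' the first atom group; atom names after each `"-"` inherit that residue.
#' Parsing is total: an unparseable string yields an all-unknown label with a
#' warning, never an error.
#'
#' @param label assignment string (length-1 character).
#' @return a list with components `res_type` (one-letter code or `NA`),
#'   `res_num` (integer or `NA`) and `atoms` (character vector, possibly
#'   containing `"?"`).
#' @export
parse_assignment_label <- function(label) {
  unknown <- list(res_type = NA_character_, res_num = NA_integer_,
                  atoms = character(0))
  if (length(label) != 1 || is.na(label) || !nzchar(label)) {
    warning("empty assignment label")
    return(unknown)
  }
  tok <- strsplit(label, "-", fixed = TRUE)[[1]]
  m <- regexec("^([A-Za-z?])([0-9]+|\\?)?([A-Za-z0-9']*|\\?)$", tok[1])[[1]]
  if (m[1] == -1) {
    warning("unparseable assignment label: '", label, "'")
    return(c(unknown["res_type"], unknown["res_num"],
             list(atoms = rep("?", length(tok)))))
  }
  parts <- regmatches(tok[1], regexec(
    "^([A-Za-z?])([0-9]+|\\?)?([A-Za-z0-9']*|\\?)$", tok[1]))[[1]]
  res_type <- if (parts[2] == "?") NA_character_ else toupper(parts[2])
  res_num <- if (is.na(parts[3]) || parts[3] %in% c("", "?"))
    NA_integer_ else as.integer(parts[3])
  first_atom <- parts[4]
  atoms <- c(if (nzchar(first_atom)) first_atom else "?",
             if (length(tok) > 1) tok[-1] else character(0))
  # later tokens may re-state a residue prefix (e.g. "C213N"); strip it
  atoms <- sub("^[A-Za-z][0-9]+", "", atoms)
  atoms[!nzchar(atoms)] <- "?"
  list(res_type = res_type, res_num = res_num, atoms = toupper(atoms))
}

#' Parse many assignment labels at once
#'
#' @param labels character vector of Sparky assignment strings.
#' @return data frame with columns `label`, `res_type`, `res_num`.
#' @export
parse_assignment_labels <- function(labels) {
  parsed <- lapply(labels, function(l)
    suppressWarnings(parse_assignment_label(l)))
  data.frame(label = labels,
             res_type = vapply(parsed, `[[`, character(1), "res_type"),
             res_num = vapply(parsed, `[[`, integer(1), "res_num"),
             stringsAsFactors = FALSE)
}

#' Read a single-record FASTA file
#'
#' @param path path to a FASTA file containing exactly one protein record.
#' @return character vector of one-letter residue codes; positions are
#'   1-based throughout the package.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1)
    stop("expected exactly one FASTA record, found ", length(set))
  raw <- readLines(path, warn = FALSE)
  if (any(grepl("[a-z]", raw[!startsWith(raw, ">")])))
    warning("lowercase residues upcased")
  s <- toupper(as.character(set[[1]]))
  res <- strsplit(s, "")[[1]]
  bad <- which(!res %in% AA20)
  if (length(bad))
    stop("illegal residue letter '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Read a per-type chemical-shift statistics table
#'
#' The table is a CSV with header `type,feature,mean,sd`, one row per
#' (amino-acid type, feature) pair.  Features are named `HN`, `N`, `C`,
#' `CA`, `CB` for chemical shifts (ppm) and `TC1_<nucleus>` /
#' `TC2_<nucleus>` for the first- and second-interval temperature
#' coefficients (ppb/K).  Absent (type, feature) combinations mean the
#' statistic does not exist for that type (e.g. no CB for glycine), not
#' zero.
#'
#' @param path CSV file path.
#' @return a data frame of class `type_statistics`.
#' @export
read_statistics_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  type_statistics(df)
}

#' @rdname read_statistics_table
#' @param df data frame with columns `type`, `feature`, `mean`, `sd`.
#' @export
type_statistics <- function(df) {
  need <- c("type", "feature", "mean", "sd")
  if (!all(need %in% names(df)))
    stop("statistics table must have columns ", paste(need, collapse = ", "))
  df <- df[need]
  if (any(!is.finite(df$mean)) || any(!is.finite(df$sd)))
    stop("non-finite mean or sd in statistics table")
  if (any(df$sd <= 0))
    stop("statistics table has sd <= 0 for ",
         paste(df$type[df$sd <= 0], df$feature[df$sd <= 0],
               sep = ":", collapse = ", "))
  key <- paste(df$type, df$feature)
  if (anyDuplicated(key))
    stop("duplicate (type, feature) rows: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  bad <- !df$type %in% AA20
  if (any(bad))
    stop("unknown amino-acid type: ", paste(unique(df$type[bad]),
                                            collapse = ", "))
  ok_feat <- grepl("^(HN|N|C|CA|CB)$|^TC[0-9]+_(HN|N|C|CA|CB)$", df$feature)
  if (!all(ok_feat))
    stop("unknown feature name: ",
         paste(unique(df$feature[!ok_feat]), collapse = ", "))
  ntypes <- length(unique(df$type))
  if (ntypes < 2) stop("statistics table needs at least 2 types")
  structure(df, class = c("type_statistics", "data.frame"))
}

#' @export
print.type_statistics <- function(x, ...) {
  cat(sprintf("Type statistics: %d types, %d features, %d rows\n",
              length(unique(x$type)), length(unique(x$feature)), nrow(x)))
  invisible(x)
}

stats_lookup <- function(stats, type, feature) {
  i <- which(stats$type == type & stats$feature == feature)
  if (length(i) == 0) NULL else list(mean = stats$mean[i], sd = stats$sd[i])
}

#' Read or write a spin-system table
#'
#' Spin systems are stored as a CSV with columns `id`, `res_type`,
#' `res_num`, the five shift columns `HN,N,C,CA,CB` (ppm) and optional
#' temperature-coefficient columns `TC1_HN,...,TC2_CB` (ppb/K).  Empty
#' cells mean the value is missing.
#'
#' @param path CSV file path.
#' @return data frame of spin systems.
#' @export
read_spin_systems <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                 na.strings = c("NA", ""))
  if (!all(c("id", "res_type", "res_num") %in% names(df)))
    stop("spin-system table must have columns id, res_type, res_num")
  feat <- intersect_features(names(df))
  if (length(feat) == 0)
    stop("spin-system table has no recognised feature columns")
  df$id <- as.character(df$id)
  df$res_type <- as.character(df$res_type)
  df$res_num <- as.integer(df$res_num)
  empty <- rowSums(!is.na(df[feat])) == 0
  if (any(empty)) stop("spin system(s) with no shifts at all: ",
                       paste(df$id[empty], collapse = ", "))
  df
}

#' @rdname read_spin_systems
#' @param x spin-system data frame.
#' @param header_lines optional character vector of comment lines to
#'   prepend (each will be prefixed with `#`).
#' @export
write_spin_systems <- function(x, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  write.csv(as.data.frame(x), con, row.names = FALSE, na = "")
  invisible(path)
}

# feature column names present in a character vector, in canonical order
intersect_features <- function(nms) {
  canon <- c(DIMS, paste0("TC1_", DIMS), paste0("TC2_", DIMS),
             paste0("TC3_", DIMS))
  canon[canon %in% nms]
}
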