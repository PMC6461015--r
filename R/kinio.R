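# Marker trajectory I/O and core containers.

#' Construct a marker trajectory dataset
#'
#' A `marker_dataset` holds one trial's wide kinematic matrix: `T` frames by
#' `N = 3 * n` columns, column order `(x, y, z)` per marker with markers in
#' `marker_labels` order.
#'
#' @param data numeric T x N matrix of coordinates.
#' @param marker_labels character vector of n marker names (N = 3n).
#' @param sampling_rate frames per second, strictly positive.
#' @param subject_id,trial_id identity tags carried through the pipeline.
#' @param missing_mask logical T x N matrix flagging gap samples; defaults to
#'   `is.na(data)`.
#' @param units length unit tag, metadata only ("mm" or "m").
#' @return An object of class `marker_dataset`.
#' @export
marker_dataset <- function(data, marker_labels, sampling_rate,
                           subject_id = "S1", trial_id = "T1",
                           missing_mask = NULL, units = "mm") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(missing_mask)) missing_mask <- is.na(data)
  x <- structure(list(
    subject_id = as.character(subject_id),
    trial_id = as.character(trial_id),
    sampling_rate = as.numeric(sampling_rate),
    marker_labels = as.character(marker_labels),
    data = data,
    missing_mask = missing_mask,
    units = units
  ), class = "marker_dataset")
  validate_marker_dataset(x)
}

#' @rdname marker_dataset
#' @param x object to validate.
#' @export
validate_marker_dataset <- function(x) {
  n <- length(x$marker_labels)
  if (ncol(x$data) != 3L * n)
    stop("N (", ncol(x$data), ") must equal 3 x number of marker labels (", n, ")")
  if (nrow(x$data) < 2L) stop("need at least 2 frames, got ", nrow(x$data))
  if (!isTRUE(x$sampling_rate > 0)) stop("sampling_rate must be > 0")
  if (!identical(dim(x$missing_mask), dim(x$data)))
    stop("missing_mask dimensions must match data")
  bad <- !x$missing_mask & !is.finite(x$data)
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-finite value outside missing_mask at frame ", ij[1L],
         ", column ", ij[2L])
  }
  x
}

#' @export
print.marker_dataset <- function(x, ...) {
  cat(sprintf("marker_dataset: subject %s trial %s | %d frames x %d markers @ %g Hz [%s]\n",
              x$subject_id, x$trial_id, nrow(x$data),
              length(x$marker_labels), x$sampling_rate, x$units))
  ng <- sum(x$missing_mask)
  if (ng > 0) cat(sprintf("  %d gap samples flagged\n", ng))
  invisible(x)
}

#' Column names for the wide CSV layout
#' @noRd
wide_header <- function(marker_labels) {
  as.vector(vapply(marker_labels,
                   function(l) paste0(l, c(".X", ".Y", ".Z")),
                   character(3L)))
}

#' Read one trial from a wide delimited text file
#'
#' Expects one row per frame and three columns per marker. Two dialects are
#' accepted: `"labeled"` (header row `label.X,label.Y,label.Z` per marker, or
#' a bare label repeated on each of its three columns) and `"headerless"`
#' (raw numeric export; labels are generated as `m01, m02, ...`). Empty cells
#' and `NaN`/`NA` tokens are read as gaps and flagged in `missing_mask`.
#'
#' @param path file to read.
#' @param sampling_rate frames per second of the recording.
#' @param dialect `"labeled"` or `"headerless"`.
#' @param subject_id,trial_id identity tags; default to the file name.
#' @param sep field separator.
#' @param units length unit tag.
#' @return A [marker_dataset].
#' @export
read_trial <- function(path, sampling_rate, dialect = c("labeled", "headerless"),
                       subject_id = NULL, trial_id = NULL, sep = ",",
                       units = "mm") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = (dialect == "labeled"),
                          na.strings = c("", "NA", "NaN", "nan"),
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) %% 3L != 0L)
    stop("format error: ", ncol(dt), " columns, not divisible by 3")
  m <- matrix(NA_real_, nrow(dt), ncol(dt))
  for (j in seq_len(ncol(dt))) {
    col <- dt[[j]]
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & !is.na(col))
    if (length(bad))
      stop("parse error: non-numeric value '", col[bad[1L]],
           "' at row ", bad[1L], ", column ", j)
    m[, j] <- v
  }
  if (dialect == "labeled") {
    h <- names(dt)
    labels <- sub("[._ ]?[XYZxyz]$", "", h[seq(1L, ncol(dt), by = 3L)])
  } else {
    labels <- sprintf("m%02d", seq_len(ncol(dt) / 3L))
  }
  base <- sub("\\.[^.]*$", "", basename(path))
  marker_dataset(m, labels, sampling_rate,
                 subject_id = subject_id %||% base,
                 trial_id = trial_id %||% base,
                 units = units)
}

#' Write a trial to a wide CSV file
#'
#' Inverse of [read_trial] (labeled dialect): header `label.X,label.Y,label.Z`,
#' gap samples serialized as empty cells. Values round-trip to text precision
#' (15 significant digits).
#'
#' @param trial a [marker_dataset].
#' @param path output file.
#' @export
write_trial <- function(trial, path) {
  m <- trial$data
  m[trial$missing_mask] <- NA_real_
  df <- as.data.frame(m)
  names(df) <- wide_header(trial$marker_labels)
  data.table::fwrite(df, path, na = "", sep = ",")
  invisible(path)
}

#' Write a table of labelled numbers as delimited text
#'
#' Plain CSV with a header row and locale-independent decimal point; `NA`/`NaN`
#' serialized as the token `NA`.
#'
#' @param rows a non-empty data.frame (or coercible).
#' @param path output file.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L || ncol(rows) == 0L) stop("rows must be non-empty")
  data.table::fwrite(rows, path, na = "NA", sep = ",")
  invisible(path)
}

#' Read back a table written by [write_table]
#' @param path file to read.
#' @export
read_table <- function(path) {
  data.table::fread(path, na.strings = "NA", data.table = FALSE)
}

#' Build an anthropometric mass model
#'
#' Expands a per-marker body-mass-fraction mapping to per-column weights
#' `w_i` (each marker's fraction repeated for its x, y and z columns), the
#' diagonal of the weighting matrix applied to the centered data. Markers
#' absent from `spec` receive weight 0 with a warning.
#'
#' @param spec named numeric vector or list, marker label -> mass fraction.
#' @param marker_labels ordered labels of the dataset the model will weight.
#' @param name model tag.
#' @return An object of class `mass_model` with fields `per_marker_mass` and
#'   `column_weights` (length `3 * length(marker_labels)`).
#' @export
build_mass_model <- function(spec, marker_labels, name = "custom") {
  spec <- unlist(spec)
  if (any(spec < 0)) stop("negative mass fraction in spec")
  unknown <- setdiff(names(spec), marker_labels)
  if (length(unknown))
    stop("spec labels not present in marker_labels: ",
         paste(unknown, collapse = ", "))
  if (sum(spec) > 1 + 1e-6)
    warning("mass fractions sum to ", signif(sum(spec), 4), " > 1")
  w <- stats::setNames(rep(0, length(marker_labels)), marker_labels)
  w[names(spec)] <- spec
  missing <- marker_labels[!(marker_labels %in% names(spec))]
  if (length(missing))
    warning("markers without mass fraction get weight 0: ",
            paste(missing, collapse = ", "))
  structure(list(
    name = name,
    per_marker_mass = w,
    column_weights = rep(unname(w), each = 3L)
  ), class = "mass_model")
}

#' @export
print.mass_model <- function(x, ...) {
  cat(sprintf("mass_model '%s': %d markers, total fraction %.4f\n",
              x$name, length(x$per_marker_mass), sum(x$per_marker_mass)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
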