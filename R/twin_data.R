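#' Twin-pair dataset
#'
#' Wraps a wide data frame of twin pairs (one row per pair) together with the
#' bifactor structure of its item battery. Canonical columns are
#' `pair_id`, `zygosity` ("MZ"/"DZ"), `age1, sex1, cohort1, age2, sex2,
#' cohort2`, then the item scores `i01_t1 .. i<n>_t1, i01_t2 .. i<n>_t2`.
#' Missing item scores are `NA` (empty cells on disk).
#'
#' @param pairs data frame in the canonical wide layout.
#' @param structure a [bifactor_structure] describing the item battery.
#' @return An object of class `twin_data` (list with `pairs`, `structure`).
#' @export
twin_data <- function(pairs, structure) {
  stopifnot(is.data.frame(pairs), inherits(structure, "bifactor_structure"))
  need <- c("pair_id", "zygosity", "age1", "sex1", "cohort1",
            "age2", "sex2", "cohort2", item_cols(structure))
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  pairs <- pairs[, need]
  pairs$pair_id <- as.character(pairs$pair_id)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, structure = structure), class = "twin_data")
}

item_cols <- function(structure, twin = NULL) {
  n <- structure$n_items
  if (is.null(twin)) c(item_cols(structure, 1L), item_cols(structure, 2L))
  else sprintf("i%02d_t%d", seq_len(n), twin)
}

#' @export
print.twin_data <- function(x, ...) {
  z <- table(x$pairs$zygosity)
  cat(sprintf("Twin dataset: %d pairs (%s), %d items\n", nrow(x$pairs),
              paste(names(z), as.integer(z), sep = "=", collapse = ", "),
              x$structure$n_items))
  invisible(x)
}

#' Number of pairs in a twin dataset
#' @param data a [twin_data] object.
#' @export
n_pairs <- function(data) nrow(data$pairs)

#' Extract the item-score matrix of one twin
#'
#' @param data a [twin_data] object.
#' @param twin 1 or 2.
#' @return numeric matrix, pairs x items, `NA` for missing scores.
#' @export
item_matrix <- function(data, twin) {
  as.matrix(data$pairs[, item_cols(data$structure, twin)])
}

# pairs x 2n matrix ordered [twin1 items | twin2 items]
pair_matrix <- function(data) {
  cbind(item_matrix(data, 1L), item_matrix(data, 2L))
}

#' Read a twin-pair CSV file
#'
#' Expects the canonical wide layout (header required, UTF-8, empty cells for
#' missing values).
#'
#' @param path file path.
#' @param structure a [bifactor_structure]; defaults to [conners_structure()].
#' @return a [twin_data] object.
#' @export
read_twin_csv <- function(path, structure = conners_structure()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", fileEncoding = "UTF-8")
  twin_data(df, structure)
}

#' Write a twin-pair dataset to CSV
#'
#' Missing values are written as empty cells so that a read/write round trip
#' is lossless including the missingness pattern.
#'
#' @param data a [twin_data] object.
#' @param path output file path.
#' @export
write_twin_csv <- function(data, path) {
  utils::write.csv(data$pairs, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a twin-pair dataset
#'
#' Report-style validation: returns a character vector of violations (empty
#' when the dataset is valid) rather than raising errors.
#'
#' Checks: zygosity codes in {MZ, DZ}; unique pair ids; item vectors of the
#' right length; raw (non-residualized) scores in {0,1,2,3}.
#'
#' @param data a [twin_data] object.
#' @param structure a [bifactor_structure] (defaults to the one carried by
#'   `data`).
#' @param raw_scores if `TRUE` (default) item values must lie in {0,1,2,3};
#'   set `FALSE` after residualization.
#' @return character vector of human-readable violations; `character(0)` iff
#'   the dataset is valid.
#' @export
validate_dataset <- function(data, structure = data$structure,
                             raw_scores = TRUE) {
  out <- character(0)
  p <- data$pairs
  bad_z <- !p$zygosity %in% c("MZ", "DZ")
  if (any(bad_z)) {
    out <- c(out, sprintf("pair %s: invalid zygosity code '%s'",
                          p$pair_id[bad_z], p$zygosity[bad_z]))
  }
  dup <- unique(p$pair_id[duplicated(p$pair_id)])
  if (length(dup)) out <- c(out, sprintf("duplicate pair_id '%s'", dup))
  # item-count mismatch between data columns and the declared structure
  have <- grep("^i[0-9]+_t[12]$", names(p), value = TRUE)
  want <- item_cols(structure)
  if (!setequal(have, want)) {
    out <- c(out, sprintf(
      "item columns do not match a %d-item structure (%d per twin found)",
      structure$n_items, length(grep("_t1$", have))))
  } else if (raw_scores) {
    x <- as.matrix(p[, want])
    bad <- which(!is.na(x) & !x %in% c(0, 1, 2, 3), arr.ind = TRUE)
    if (nrow(bad)) {
      rows <- unique(bad[, 1L])
      out <- c(out, sprintf("pair %s: raw item scores outside {0,1,2,3}",
                            p$pair_id[rows]))
    }
  }
  out
}
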