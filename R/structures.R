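#' Define a bifactor item-to-group structure
#'
#' A bifactor structure assigns each of `n` items to exactly one of `m`
#' disjoint group factors; a general factor loads on all items. This object
#' is carried by loading matrices, parameter sets and datasets so that
#' structural zeros (an item may only load on its own group factor) can be
#' enforced consistently.
#'
#' @param group_of integer vector of length `n`; `group_of[i]` is the group
#'   (1..m) that item `i` belongs to. Every group must contain at least two
#'   items.
#' @param group_names optional character vector of length `m`.
#' @param item_labels optional character vector of length `n`.
#' @return An object of class `bifactor_structure` with fields `n_items`,
#'   `n_groups`, `group_of`, `group_names`, `item_labels`.
#' @examples
#' s <- bifactor_structure(rep(1:2, c(3, 2)))
#' s$n_items
#' @export
bifactor_structure <- function(group_of, group_names = NULL, item_labels = NULL) {
  group_of <- as.integer(group_of)
  if (length(group_of) < 2L || anyNA(group_of)) {
    stop("group_of must be a complete integer vector with >= 2 items")
  }
  m <- max(group_of)
  if (!setequal(unique(group_of), seq_len(m))) {
    stop("group indices must be consecutive integers 1..m")
  }
  sizes <- tabulate(group_of, m)
  if (any(sizes < 2L)) stop("every group factor needs at least 2 items")
  n <- length(group_of)
  if (is.null(group_names)) group_names <- paste0("F", seq_len(m))
  if (is.null(item_labels)) item_labels <- sprintf("item%02d", seq_len(n))
  stopifnot(length(group_names) == m, length(item_labels) == n)
  structure(
    list(n_items = n, n_groups = m, group_of = group_of,
         group_names = as.character(group_names),
         item_labels = as.character(item_labels)),
    class = "bifactor_structure"
  )
}

#' @export
print.bifactor_structure <- function(x, ...) {
  cat(sprintf("Bifactor structure: %d items, general + %d group factors\n",
              x$n_items, x$n_groups))
  for (g in seq_len(x$n_groups)) {
    cat(sprintf("  %s: %d items\n", x$group_names[g], sum(x$group_of == g)))
  }
  invisible(x)
}

#' Default 20-item attention/hyperactivity structure
#'
#' The structure of the short adult self-report Conners scale: an 11-item
#' inattention subscale followed by a 9-item hyperactivity subscale, each
#' item rated 0-3. This is the default fixture used throughout the package.
#'
#' @return A [bifactor_structure] with 20 items and 2 groups.
#' @export
conners_structure <- function() {
  labels <- c(
    "Struggles paying attention", "Makes mistakes",
    "Struggles focusing on tasks", "Struggles focusing on conversations",
    "Struggles following instructions", "Struggles finishing tasks",
    "Struggles with organisation", "Dislikes complex tasks",
    "Loses things", "Gets distracted", "Forgets things",
    "Struggles sitting still", "Leaves seat inappropriately",
    "Feels restless", "Struggles remaining quiet", "Prefers being on the go",
    "Talks too much", "Blurts out answers to questions",
    "Struggles waiting turns", "Interrupts others"
  )
  bifactor_structure(rep(1:2, c(11L, 9L)),
                     group_names = c("Inattention", "Hyperactivity"),
                     item_labels = labels)
}

#' Construct a general + group loading matrix
#'
#' @param values numeric matrix, `n_items` rows and `1 + n_groups` columns;
#'   column 1 is the general factor, columns 2.. are the group factors in
#'   structure order.
#' @param structure a [bifactor_structure].
#' @param enforce_zeros if `TRUE` (default) entries in a group column for
#'   items outside that group are set to exactly 0; if `FALSE` the values
#'   (e.g. estimated cross-loadings) are kept as given.
#' @return A numeric matrix of class `loading_matrix` with the structure
#'   attached as attribute `"structure"`.
#' @export
loading_matrix <- function(values, structure, enforce_zeros = TRUE) {
  values <- as.matrix(values)
  stopifnot(inherits(structure, "bifactor_structure"))
  n <- structure$n_items
  m <- structure$n_groups
  if (nrow(values) != n || ncol(values) != m + 1L) {
    stop(sprintf("loading matrix must be %d x %d", n, m + 1L))
  }
  if (any(!is.finite(values))) stop("loadings must all be finite")
  if (enforce_zeros) {
    for (g in seq_len(m)) values[structure$group_of != g, g + 1L] <- 0
  }
  dimnames(values) <- list(structure$item_labels,
                           c("general", structure$group_names))
  structure(values, structure = structure, class = c("loading_matrix", "matrix"))
}

#' @export
print.loading_matrix <- function(x, digits = 3, ...) {
  print(round(unclass(x), digits))
  invisible(x)
}

# Structural-zero mask: TRUE where a loading is allowed to be nonzero.
loading_mask <- function(structure) {
  n <- structure$n_items
  m <- structure$n_groups
  mask <- matrix(FALSE, n, m + 1L)
  mask[, 1L] <- TRUE
  for (g in seq_len(m)) mask[structure$group_of == g, g + 1L] <- TRUE
  mask
}

# Flip each column of a loading matrix so its sum is nonnegative
# (sign-identification convention used everywhere in the package).
apply_sign_convention <- function(L) {
  for (k in seq_len(ncol(L))) if (sum(L[, k]) < 0) L[, k] <- -L[, k]
  L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
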