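#' ADT count matrix
#'
#' Container for raw antibody-derived-tag (ADT) counts: a cells-by-antibodies
#' matrix of nonnegative integers with unique cell and antibody names, and a
#' logical flag per antibody marking isotype (negative) controls. Isotype
#' controls carry no target-specific signal; their counts measure the ambient
#' antibody captured in each droplet and are what the Gaussian-process offset
#' of [adtgp()] is learned from.
#'
#' @param counts numeric matrix of nonnegative integers, cells as rows and
#'   antibodies as columns.
#' @param antibody_names character vector of unique column names. Defaults to
#'   `colnames(counts)`.
#' @param cell_ids character vector of unique row names. Defaults to
#'   `rownames(counts)`, or `cell1..celln` when absent.
#' @param isotype_flags logical vector, one entry per antibody, `TRUE` for
#'   isotype controls. Defaults to name matching against `isotype_pattern`.
#' @param isotype_pattern substring used to auto-flag isotype controls by
#'   antibody name when `isotype_flags` is not given (fixed match, default
#'   `"IgG"`). Explicit flags always win over pattern matching.
#'
#' @return An object of class `adt_counts`: the integer count matrix with
#'   attributes `isotype_flags`.
#' @examples
#' m <- matrix(c(5L, 9L, 2L, 3L), 2, 2,
#'             dimnames = list(c("c1", "c2"), c("CD11b", "IgG1")))
#' x <- adt_counts(m)
#' isotype_flags(x)
#' @export
adt_counts <- function(counts, antibody_names = colnames(counts),
                       cell_ids = rownames(counts), isotype_flags = NULL,
                       isotype_pattern = "IgG") {
  counts <- as.matrix(counts)
  if (!is_count_vector(as.vector(counts))) {
    bad <- which(!(is.finite(counts) & counts >= 0 & counts == floor(counts)),
                 arr.ind = TRUE)
    adtgp_error(
      sprintf("counts must be nonnegative integers; first offending entry at [%d, %d]",
              bad[1, 1], bad[1, 2]),
      "adtgp_error_format")
  }
  if (is.null(antibody_names)) {
    adtgp_error("antibody names are required", "adtgp_error_format")
  }
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  antibody_names <- as.character(antibody_names)
  cell_ids <- as.character(cell_ids)
  if (length(antibody_names) != ncol(counts) || anyDuplicated(antibody_names)) {
    adtgp_error("antibody names must be unique and match the column count",
                "adtgp_error_format")
  }
  if (length(cell_ids) != nrow(counts) || anyDuplicated(cell_ids)) {
    adtgp_error("cell ids must be unique and match the row count",
                "adtgp_error_format")
  }
  if (is.null(isotype_flags)) {
    isotype_flags <- grepl(isotype_pattern, antibody_names, fixed = TRUE)
  }
  isotype_flags <- as.logical(isotype_flags)
  if (length(isotype_flags) != ncol(counts) || anyNA(isotype_flags)) {
    adtgp_error("isotype_flags must be one non-missing logical per antibody",
                "adtgp_error_format")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cell_ids, antibody_names)
  structure(counts, isotype_flags = isotype_flags, class = c("adt_counts", "matrix", "array"))
}

#' @rdname adt_counts
#' @param x an `adt_counts` object.
#' @export
isotype_flags <- function(x) {
  stopifnot(inherits(x, "adt_counts"))
  stats::setNames(attr(x, "isotype_flags"), colnames(x))
}

#' @export
`[.adt_counts` <- function(x, i, j, drop = TRUE) {
  m <- unclass(x)
  flags <- stats::setNames(attr(x, "isotype_flags"), colnames(m))
  if (missing(i)) i <- seq_len(nrow(m))
  if (missing(j)) j <- seq_len(ncol(m))
  out <- m[i, j, drop = FALSE]
  if (isTRUE(drop) && (nrow(out) == 1L || ncol(out) == 1L)) {
    return(drop(out))
  }
  adt_counts(out, isotype_flags = unname(flags[colnames(out)]))
}

#' @export
print.adt_counts <- function(x, ...) {
  iso <- attr(x, "isotype_flags")
  cat(sprintf("ADT count matrix: %d cells x %d antibodies (%d isotype control%s)\n",
              nrow(x), ncol(x), sum(iso), if (sum(iso) == 1) "" else "s"))
  cat("antibodies:", paste0(colnames(x), ifelse(iso, "*", ""), collapse = ", "), "\n")
  invisible(x)
}

#' Design matrix for the count model
#'
#' A design matrix in the convention used throughout the package: the first
#' column must be named `"mu0"` and hold the constant 1 (the intercept); every
#' further column is a categorical covariate coded with positive integer
#' levels `1..L`. Non-contiguous level codes are re-indexed to `1..L` and the
#' mapping is recorded in the `"level_map"` attribute (and messaged).
#'
#' @param x data frame or matrix; first column `mu0`, all 1.
#' @return An `adt_design` data frame; attribute `level_map` records, per
#'   covariate, the original code for each re-indexed level.
#' @examples
#' d <- adt_design(data.frame(mu0 = 1, T = rep(c(1, 2), each = 3)))
#' attr(d, "level_map")
#' @export
adt_design <- function(x) {
  x <- as.data.frame(x)
  if (nrow(x) < 1) {
    adtgp_error("a design matrix needs at least one cell (zero-length data are refused)",
                "adtgp_error_design")
  }
  if (ncol(x) < 1 || names(x)[1] != "mu0") {
    adtgp_error(paste0(
      "the first design column must be named \"mu0\" and hold the constant 1 ",
      "(the intercept)"), "adtgp_error_design")
  }
  if (!all(x$mu0 == 1)) {
    adtgp_error("the mu0 column must be constant 1", "adtgp_error_design")
  }
  level_map <- list()
  for (j in seq_len(ncol(x))[-1]) {
    v <- x[[j]]
    if (!is_count_vector(v) || any(v < 1)) {
      adtgp_error(sprintf("covariate '%s' must be coded with positive integers",
                          names(x)[j]), "adtgp_error_design")
    }
    lev <- sort(unique(v))
    if (!identical(as.numeric(lev), as.numeric(seq_along(lev)))) {
      message(sprintf("re-indexing levels of '%s': %s -> %s", names(x)[j],
                      paste(lev, collapse = ","), paste(seq_along(lev), collapse = ",")))
    }
    level_map[[names(x)[j]]] <- lev
    x[[j]] <- match(v, lev)
  }
  x$mu0 <- 1L
  structure(x, level_map = level_map, class = c("adt_design", "data.frame"))
}

# number of occupied levels per non-intercept column
design_levels <- function(design) {
  cols <- names(design)[-1]
  stats::setNames(vapply(cols, function(j) length(unique(design[[j]])), 1L), cols)
}

# Cartesian product of occupied covariate levels, lexicographic with the
# earliest design column most significant; one row per combination.
design_combinations <- function(design) {
  lv <- design_levels(design)
  if (length(lv) == 0) {
    return(structure(data.frame(row.names = 1), labels = "(intercept)"))
  }
  g <- expand.grid(rev(lapply(lv, seq_len)), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(g)), drop = FALSE]
  names(g) <- names(lv)
  labels <- apply(g, 1, function(r) paste(paste0(names(lv), "=", r), collapse = ","))
  structure(g, labels = unname(labels))
}
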