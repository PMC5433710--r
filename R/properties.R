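#' Amino-acid physicochemical property table
#'
#' A curated set of 31 physicochemical properties, one value per (property,
#' amino acid): 20 standard published empirical scales (hydropathy, polarity,
#' volume, secondary-structure propensities, transfer energies, ...) plus 11
#' exact compositional descriptors (atom counts, charge, hydrogen-bond
#' donors/acceptors, ...). The packaged table is the package's single,
#' versioned source of truth for radical-change scoring.
#'
#' @return A 31 x 20 numeric matrix; rownames are property ids, colnames the
#'   one-letter amino-acid symbols in `ARNDCQEGHILKMFPSTWYV` order.
#' @export
aa_property_table <- function() {
  if (!is.null(.prop_env$table)) return(.prop_env$table)
  path <- system.file("extdata", "aa_properties_31.tsv", package = "mitocons")
  if (path == "") path <- file.path("inst", "extdata", "aa_properties_31.tsv")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -(1:2)])
  rownames(m) <- df$property_id
  storage.mode(m) <- "double"
  stopifnot(nrow(m) == 31L, ncol(m) == 20L, !anyNA(m))
  assign("table", m, envir = .prop_env)
  m
}

.prop_env <- new.env(parent = emptyenv())

#' Property change-magnitude bin edges
#'
#' For each property, the maximum attainable pairwise absolute change
#' (range of the scale) divided into 8 equal-width magnitude categories.
#'
#' @param table Property matrix from [aa_property_table()].
#' @return Numeric vector of per-property maximum pairwise change magnitudes.
#' @export
property_max_change <- function(table = aa_property_table()) {
  apply(table, 1L, function(v) max(v) - min(v))
}

#' Magnitude category of an amino-acid replacement for one property
#'
#' Bins the absolute property change |value(to) - value(from)| into 8
#' equal-width categories spanning the property's maximum attainable pairwise
#' change. Identity replacements return the 0 sentinel (no change). Category 8
#' is closed at the maximum.
#'
#' @param from,to One-letter amino-acid symbols (among the 20).
#' @param property Property id (rowname of the table), or omit for all 31.
#' @param table Property matrix.
#' @return Integer category in 0..8; a named vector over properties when
#'   `property` is `NULL`.
#' @export
#' @examples
#' magnitude_category("A", "A", "kd_hydropathy")  # 0
magnitude_category <- function(from, to, property = NULL,
                               table = aa_property_table()) {
  aas <- colnames(table)
  if (!(from %in% aas) || !(to %in% aas)) {
    stop("unknown residue: ", from, "/", to, call. = FALSE)
  }
  props <- if (is.null(property)) rownames(table) else property
  if (!all(props %in% rownames(table))) {
    stop("unknown property: ", paste(setdiff(props, rownames(table)),
                                     collapse = ", "), call. = FALSE)
  }
  if (from == to) {
    out <- rep(0L, length(props))
    names(out) <- props
    return(if (is.null(property)) out else unname(out[1L]))
  }
  delta <- abs(table[props, to] - table[props, from])
  maxc <- property_max_change(table)[props]
  cat <- ifelse(maxc == 0, 0L, pmin(8L, floor(delta / maxc * 8) + 1L))
  cat[delta == 0] <- 0L
  cat <- as.integer(cat)
  names(cat) <- props
  if (is.null(property)) cat else unname(cat[1L])
}

#' Magnitude categories for all ordered amino-acid pairs
#'
#' Precomputes the 8-bin magnitude category of every (from, to) replacement
#' for every property; used by the z-score and per-site radical summaries.
#'
#' @param table Property matrix.
#' @return Integer array `properties x from x to` with categories 0..8.
#' @export
magnitude_category_array <- function(table = aa_property_table()) {
  aas <- colnames(table)
  maxc <- property_max_change(table)
  arr <- array(0L, dim = c(nrow(table), 20L, 20L),
               dimnames = list(rownames(table), aas, aas))
  for (p in seq_len(nrow(table))) {
    d <- abs(outer(table[p, ], table[p, ], "-"))
    cat <- pmin(8L, floor(d / maxc[p] * 8) + 1L)
    cat[d == 0] <- 0L
    arr[p, , ] <- as.integer(cat)
  }
  arr
}
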