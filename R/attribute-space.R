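#' Define a DCE attribute space
#'
#' An attribute space is the vocabulary of a discrete choice experiment: an
#' ordered set of attributes, each with an ordered set of categorical levels.
#' Levels are effects coded: each attribute with `L` levels contributes
#' `L - 1` design-matrix columns; the reference level (by default the last
#' listed level) is coded `-1` on every column of its attribute's block, so
#' that level utilities sum to zero within an attribute.
#'
#' @param attributes named list; each element a character vector of at least
#'   two unique level labels, in display order. Attribute order is preserved
#'   and defines the coded column order (attribute-major, level-minor).
#' @param reference optional integer vector (one entry per attribute) giving
#'   the index of the omitted (reference) level; defaults to the last level.
#' @return An object of class `attribute_space` with the per-attribute
#'   effects-coding maps and frozen column names of the form `"attr=level"`.
#' @examples
#' sp <- attribute_space(list(cost = c("Free", "$5", "$10"),
#'                            app  = c("Web", "Mobile")))
#' sp$n_columns  # 3
#' @export
attribute_space <- function(attributes, reference = NULL) {
  if (!is.list(attributes) || length(attributes) == 0)
    stop("'attributes' must be a non-empty named list of level label vectors")
  nm <- names(attributes)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm))
    stop("attribute names must be unique and non-empty")
  n_levels <- vapply(attributes, length, integer(1))
  if (any(n_levels < 2))
    stop("every attribute needs at least 2 levels; offending: ",
         paste(nm[n_levels < 2], collapse = ", "))
  for (k in seq_along(attributes)) {
    lv <- attributes[[k]]
    if (!is.character(lv)) attributes[[k]] <- lv <- as.character(lv)
    if (anyDuplicated(lv))
      stop("duplicate level labels within attribute '", nm[k], "'")
  }
  if (is.null(reference)) reference <- n_levels
  reference <- as.integer(reference)
  if (length(reference) != length(attributes) ||
      any(reference < 1L | reference > n_levels))
    stop("'reference' must give one valid level index per attribute")

  coding <- vector("list", length(attributes))
  colnames_all <- character(0)
  for (k in seq_along(attributes)) {
    L <- n_levels[k]
    keep <- setdiff(seq_len(L), reference[k])  # non-reference levels, in order
    C <- matrix(0, nrow = L, ncol = L - 1L,
                dimnames = list(attributes[[k]],
                                paste0(nm[k], "=", attributes[[k]][keep])))
    for (j in seq_along(keep)) C[keep[j], j] <- 1
    C[reference[k], ] <- -1
    coding[[k]] <- C
    colnames_all <- c(colnames_all, colnames(C))
  }
  names(coding) <- nm
  structure(list(attributes = attributes,
                 n_levels = n_levels,
                 reference = stats::setNames(reference, nm),
                 coding = coding,
                 column_names = colnames_all,
                 n_columns = sum(n_levels - 1L)),
            class = "attribute_space")
}

#' @export
print.attribute_space <- function(x, ...) {
  cat("Attribute space:", length(x$attributes), "attributes,",
      x$n_columns, "effects-coded columns\n")
  for (k in seq_along(x$attributes)) {
    nm <- names(x$attributes)[k]
    lv <- x$attributes[[k]]
    lv[x$reference[k]] <- paste0(lv[x$reference[k]], " (ref)")
    cat("  ", nm, ": ", paste(lv, collapse = " | "), "\n", sep = "")
  }
  invisible(x)
}

#' Effects-code attribute profiles
#'
#' Maps level labels to the effects-coded design matrix of the space: a
#' non-reference level puts `+1` in its own column and `0` elsewhere in its
#' attribute's block; the reference level is `-1` across the whole block.
#'
#' @param space an [attribute_space()].
#' @param profiles a data frame with one column per attribute (level labels),
#'   or a single named character vector / list describing one profile.
#' @return Numeric matrix with one row per profile and `space$n_columns`
#'   columns named `"attr=level"`.
#' @export
effects_code <- function(space, profiles) {
  stopifnot(inherits(space, "attribute_space"))
  if (!is.data.frame(profiles)) {
    profiles <- as.data.frame(as.list(unlist(profiles)), stringsAsFactors = FALSE)
  }
  nm <- names(space$attributes)
  missing <- setdiff(nm, names(profiles))
  if (length(missing))
    stop("profile is missing attribute(s): ", paste(missing, collapse = ", "))
  n <- nrow(profiles)
  out <- matrix(0, n, space$n_columns,
                dimnames = list(NULL, space$column_names))
  pos <- 1L
  for (k in seq_along(nm)) {
    C <- space$coding[[k]]
    idx <- match(as.character(profiles[[nm[k]]]), space$attributes[[k]])
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop("unknown level '", profiles[[nm[k]]][bad], "' for attribute '",
           nm[k], "' (profile row ", bad, ")")
    }
    ncolk <- ncol(C)
    out[, pos:(pos + ncolk - 1L)] <- C[idx, , drop = FALSE]
    pos <- pos + ncolk
  }
  out
}

#' Decode effects-coded rows back to level labels
#'
#' Inverse of [effects_code()]: recovers the profile whose coding equals each
#' row of `X`.
#'
#' @param space an [attribute_space()].
#' @param X coded matrix (or a single coded vector).
#' @return Data frame of level labels, one column per attribute.
#' @export
decode_profiles <- function(space, X) {
  stopifnot(inherits(space, "attribute_space"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != space$n_columns)
    stop("X has ", ncol(X), " columns; space expects ", space$n_columns)
  nm <- names(space$attributes)
  out <- vector("list", length(nm))
  pos <- 1L
  for (k in seq_along(nm)) {
    L <- space$n_levels[k]
    block <- X[, pos:(pos + L - 2L), drop = FALSE]
    lab <- character(nrow(block))
    keep <- setdiff(seq_len(L), space$reference[k])
    for (i in seq_len(nrow(block))) {
      b <- block[i, ]
      if (all(b == -1)) {
        lab[i] <- space$attributes[[k]][space$reference[k]]
      } else {
        j <- which(b == 1)
        if (length(j) != 1L || any(b[-j] != 0))
          stop("row ", i, " is not a valid effects coding for attribute '",
               nm[k], "'")
        lab[i] <- space$attributes[[k]][keep[j]]
      }
    }
    out[[k]] <- lab
    pos <- pos + L - 1L
  }
  names(out) <- nm
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Complete an effects-coded coefficient block
#'
#' Under effects coding the level coefficients of one attribute sum to zero,
#' so the omitted (reference) level's coefficient is recoverable as minus the
#' sum of the `L - 1` estimated ones. Given those estimates this returns the
#' full length-`L` set, which sums to exactly zero.
#'
#' @param estimated numeric vector of the `L - 1` estimated level
#'   coefficients of one attribute (any names are kept).
#' @return Numeric vector of length `L`; the appended final element is the
#'   reference level's implied coefficient, named `"(ref)"` if the input is
#'   named.
#' @examples
#' complete_coefficients(c(0.70, -0.11))  # reference level -0.59
#' @export
complete_coefficients <- function(estimated) {
  if (!is.numeric(estimated) || length(estimated) < 1)
    stop("'estimated' must be a non-empty numeric vector")
  if (any(!is.finite(estimated))) stop("'estimated' must be finite")
  ref <- -sum(estimated)
  out <- c(estimated, ref)
  if (!is.null(names(estimated))) names(out) <- c(names(estimated), "(ref)")
  out
}

#' Full per-level coefficient table for a coded coefficient vector
#'
#' Expands a vector of coded-column coefficients (named as the space's
#' columns) into a tidy table over every level of every attribute, filling
#' each reference level with the zero-sum completion.
#'
#' @param space an [attribute_space()].
#' @param beta named numeric vector containing (at least) one entry per coded
#'   column of `space`; extra entries (e.g. an opt-out constant) are ignored.
#' @return Data frame with columns `attribute`, `level`, `estimate`.
#' @export
level_coefficients <- function(space, beta) {
  stopifnot(inherits(space, "attribute_space"))
  miss <- setdiff(space$column_names, names(beta))
  if (length(miss))
    stop("beta is missing coded columns: ", paste(miss, collapse = ", "))
  nm <- names(space$attributes)
  rows <- vector("list", length(nm))
  for (k in seq_along(nm)) {
    lv <- space$attributes[[k]]
    ref <- space$reference[k]
    keep <- setdiff(seq_along(lv), ref)
    est <- numeric(length(lv))
    est[keep] <- beta[paste0(nm[k], "=", lv[keep])]
    est[ref] <- -sum(est[keep])
    rows[[k]] <- data.frame(attribute = nm[k], level = lv, estimate = est,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# space <-> JSON (schema used by the packaged study fixture)
#' Read / write an attribute space as JSON
#'
#' @param path file path.
#' @return `read_attribute_space` returns an [attribute_space()].
#' @export
read_attribute_space <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  att <- j$attributes
  lv <- att$levels
  if (is.data.frame(att)) {
    spec <- stats::setNames(lv, att$name)
  } else {
    spec <- stats::setNames(lapply(att, `[[`, "levels"),
                            vapply(att, `[[`, "", "name"))
  }
  attribute_space(as.list(spec))
}

#' @rdname read_attribute_space
#' @param space an [attribute_space()] to serialize.
#' @export
write_attribute_space <- function(space, path) {
  stopifnot(inherits(space, "attribute_space"))
  j <- list(schema = "dcekit/attribute_space/1",
            attributes = lapply(names(space$attributes), function(nm)
              list(name = nm, levels = space$attributes[[nm]])))
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
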