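# D-efficient choice-set design by coordinate exchange.
#
# The design criterion is the MNL D-error: the determinant of the inverse
# Fisher information of the design at prior coefficients, normalized per
# choice set and scaled to a per-parameter magnitude, det(I^-1)^(1/K).
# Replicating every set leaves the criterion unchanged; lower is better.

#' Enumerate all candidate profiles of an attribute space
#'
#' Full factorial of level combinations in lexicographic order (first
#' attribute most significant).
#'
#' @param space an [attribute_space()].
#' @param cap refuse factorials larger than this (default 1e6).
#' @return Data frame with one column per attribute (level labels).
#' @export
enumerate_candidates <- function(space, cap = 1e6) {
  stopifnot(inherits(space, "attribute_space"))
  n <- prod(space$n_levels)
  if (n > cap)
    stop("full factorial has ", n, " profiles, above the cap of ", cap)
  g <- expand.grid(rev(space$attributes), KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(space$attributes)), drop = FALSE]
  rownames(g) <- NULL
  g
}

# per-set information matrix at priors (J x K coded block)
.set_info <- function(Xs, priors) {
  p <- choice_probabilities(drop(Xs %*% priors))
  xbar <- colSums(Xs * p)
  crossprod(Xs, Xs * p) - tcrossprod(xbar)
}

.design_coded <- function(design) {
  effects_code(design$space,
               design$profiles[, names(design$space$attributes), drop = FALSE])
}

# D-error from a list of per-set information matrices; a rank-deficient
# information matrix scores +Inf
.d_error_from_info <- function(info_list, K) {
  I <- Reduce(`+`, info_list) / length(info_list)
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(abs(ev)) * 1e-9 || max(ev) <= 0) return(Inf)
  exp(-sum(log(ev)) / K)
}

#' D-error of a choice design
#'
#' `det(I(beta)^-1)^(1/K)` where `I` is the multinomial-logit Fisher
#' information of the design evaluated at prior coefficients `priors`,
#' averaged over choice sets (so replicating all sets leaves the D-error
#' unchanged). A design with no information (singular `I`) scores `+Inf`
#' with a warning.
#'
#' @param design a `choice_design`.
#' @param priors coefficient vector of length equal to the coded column
#'   count (default: zero vector, under which all within-set choice
#'   probabilities are `1/J`).
#' @param include_optout evaluate the information of the administered
#'   choice situation, i.e. with a constant all-zero opt-out alternative
#'   appended to every set (default `FALSE`: designed alternatives only).
#'   Required for identifiability when `n_sets * (n_alts - 1)` is below
#'   the coded column count.
#' @return Scalar D-error (lower is better).
#' @export
d_error <- function(design, priors = NULL, include_optout = FALSE) {
  stopifnot(inherits(design, "choice_design"))
  K <- design$space$n_columns
  if (is.null(priors)) priors <- numeric(K)
  if (length(priors) != K)
    stop("'priors' must have length ", K)
  X <- .design_coded(design)
  sets <- split(seq_len(nrow(X)), design$profiles$set)
  info <- lapply(sets, function(i) {
    Xs <- X[i, , drop = FALSE]
    if (include_optout) Xs <- rbind(Xs, 0)
    .set_info(Xs, priors)
  })
  de <- .d_error_from_info(info, K)
  if (!is.finite(de))
    warning("singular information matrix: degenerate design")
  de
}

.new_design <- function(space, levmat, n_sets, n_alts, d_err, seed,
                        block = rep(1L, n_sets)) {
  prof <- as.data.frame(lapply(seq_along(space$attributes), function(k)
    space$attributes[[k]][levmat[, k]]), stringsAsFactors = FALSE)
  names(prof) <- names(space$attributes)
  prof <- cbind(set = rep(seq_len(n_sets), each = n_alts),
                alt = rep(seq_len(n_alts), times = n_sets), prof)
  structure(list(profiles = prof,
                 block = block,
                 n_sets = n_sets, n_alts = n_alts,
                 d_error = d_err, seed = seed, space = space),
            class = "choice_design")
}

#' @export
print.choice_design <- function(x, ...) {
  cat("Choice design:", x$n_sets, "sets x", x$n_alts, "alternatives,",
      length(unique(x$block)), "block(s); D-error",
      format(x$d_error, digits = 5), "\n")
  invisible(x)
}

#' Search for a D-efficient choice design
#'
#' Random-start coordinate exchange: starting from a seeded random design
#' (with no duplicate profiles within a set), each sweep visits every
#' (set, alternative, attribute) coordinate and tries every alternative
#' level, accepting the first strict D-error improvement; ties keep the
#' incumbent. The search stops after `n_sweeps` sweeps or when a full sweep
#' makes no improvement. Deterministic given the seed; the final D-error
#' never exceeds the initial random design's.
#'
#' @param space an [attribute_space()].
#' @param n_sets number of choice sets (study default 12).
#' @param n_alts designed alternatives per set (default 2; the opt-out is
#'   appended at survey time, not designed).
#' @param priors prior coefficients for the D-error (default zeros).
#' @param seed RNG seed for the random start.
#' @param n_sweeps sweep budget (default 50).
#' @param include_optout optimize the administered situation with an
#'   appended opt-out alternative, see [d_error()] (default `FALSE`).
#' @return A `choice_design` with its D-error and seed recorded.
#' @export
search_design <- function(space, n_sets = 12, n_alts = 2, priors = NULL,
                          seed = 1, n_sweeps = 50, include_optout = FALSE) {
  stopifnot(inherits(space, "attribute_space"))
  if (n_sets < 1) stop("'n_sets' must be >= 1")
  K <- space$n_columns
  if (is.null(priors)) priors <- numeric(K)
  if (length(priors) != K) stop("'priors' must have length ", K)
  n_attr <- length(space$attributes)
  set.seed(as.integer(seed) %% .Machine$integer.max)

  # random start, resampling any within-set duplicate profile
  lev <- matrix(0L, n_sets * n_alts, n_attr)
  for (k in seq_len(n_attr))
    lev[, k] <- sample.int(space$n_levels[k], n_sets * n_alts, replace = TRUE)
  for (s in seq_len(n_sets)) {
    rows <- (s - 1L) * n_alts + seq_len(n_alts)
    for (tries in 1:100) {
      key <- apply(lev[rows, , drop = FALSE], 1, paste, collapse = ",")
      if (!anyDuplicated(key)) break
      j <- which(duplicated(key))[1]
      for (k in seq_len(n_attr))
        lev[rows[j], k] <- sample.int(space$n_levels[k], 1)
    }
  }

  code_rows <- function(rows) {
    out <- matrix(0, length(rows), K)
    pos <- 1L
    for (k in seq_len(n_attr)) {
      C <- space$coding[[k]]
      out[, pos:(pos + ncol(C) - 1L)] <- C[lev[rows, k], , drop = FALSE]
      pos <- pos + ncol(C)
    }
    if (include_optout) out <- rbind(out, 0)
    out
  }
  info <- lapply(seq_len(n_sets), function(s)
    .set_info(code_rows((s - 1L) * n_alts + seq_len(n_alts)), priors))
  d_cur <- .d_error_from_info(info, K)
  d_init <- d_cur

  for (sweep in seq_len(n_sweeps)) {
    improved <- FALSE
    for (s in seq_len(n_sets)) {
      rows <- (s - 1L) * n_alts + seq_len(n_alts)
      for (j in seq_len(n_alts)) {
        for (k in seq_len(n_attr)) {
          cur <- lev[rows[j], k]
          for (l in seq_len(space$n_levels[k])) {
            if (l == cur) next
            old <- lev[rows[j], k]
            lev[rows[j], k] <- l
            key <- apply(lev[rows, , drop = FALSE], 1, paste, collapse = ",")
            if (anyDuplicated(key)) { lev[rows[j], k] <- old; next }
            new_info <- .set_info(code_rows(rows), priors)
            cand <- info
            cand[[s]] <- new_info
            d_new <- .d_error_from_info(cand, K)
            if (d_new < d_cur - 1e-12) {
              info <- cand
              d_cur <- d_new
              improved <- TRUE
              break   # first improvement: move to next coordinate
            }
            lev[rows[j], k] <- old
          }
        }
      }
    }
    if (!improved) break
  }

  des <- .new_design(space, lev, n_sets, n_alts, d_cur, seed)
  des$d_error_initial <- d_init
  des$include_optout <- include_optout
  des
}

# between-block level-count imbalance (sum over attributes and levels of
# absolute deviation from the per-block expected count)
.block_imbalance <- function(design, block) {
  obj <- 0
  B <- length(unique(block))
  prof <- design$profiles
  row_block <- block[prof$set]
  for (k in names(design$space$attributes)) {
    tb <- table(factor(row_block, levels = seq_len(B)),
                factor(prof[[k]], levels = design$space$attributes[[k]]))
    expected <- colSums(tb) / B
    obj <- obj + sum(abs(sweep(tb, 2, expected)))
  }
  obj
}

#' Split a design into blocks
#'
#' Assigns choice sets to equally sized blocks so each respondent answers
#' only a fraction of the design (the study splits 12 sets into 2 blocks of
#' 6). A seeded random assignment is improved by greedy pairwise swaps of
#' sets between blocks, accepting any swap that lowers the between-block
#' level-count imbalance, until no swap helps.
#'
#' @param design a `choice_design`.
#' @param n_blocks number of blocks; must divide `n_sets` (default 2).
#' @param seed RNG seed for the initial assignment.
#' @return The design with its `block` assignment replaced.
#' @export
block_design <- function(design, n_blocks = 2, seed = 1) {
  stopifnot(inherits(design, "choice_design"))
  if (design$n_sets %% n_blocks != 0)
    stop("n_sets (", design$n_sets, ") is not divisible by n_blocks (",
         n_blocks, ")")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  per <- design$n_sets / n_blocks
  block <- rep(seq_len(n_blocks), each = per)[sample.int(design$n_sets)]
  obj <- .block_imbalance(design, block)
  repeat {
    improved <- FALSE
    for (a in seq_len(design$n_sets - 1L)) {
      for (b in seq((a + 1L), design$n_sets)) {
        if (block[a] == block[b]) next
        cand <- block
        cand[c(a, b)] <- cand[c(b, a)]
        o2 <- .block_imbalance(design, cand)
        if (o2 < obj - 1e-12) {
          block <- cand
          obj <- o2
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  design$block <- block
  design$block_imbalance <- obj
  design
}
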