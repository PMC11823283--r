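#' Confirmatory loadings pattern
#'
#' Describes which entries of the `K x m` loadings matrix are structurally
#' free (the rest are fixed zeros), which free entry of each column is
#' constrained strictly positive (the sign anchor), and the outcome ordering
#' under which the first `m` rows form the leading block used by the LQ
#' decomposition.
#'
#' @param mask `K x m` logical matrix, `TRUE` = free entry.
#' @param anchors two-column integer matrix of (row, column) anchor
#'   positions, one anchor per factor column.
#' @param outcome_order permutation of `1:K`; the first `m` entries select
#'   the rows of the leading block.
#' @param outcome_labels optional character vector of length `K`.
#' @return An object of class `loadings_pattern`.
#' @export
loadings_pattern <- function(mask, anchors,
                             outcome_order = seq_len(nrow(mask)),
                             outcome_labels = NULL) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  K <- nrow(mask); m <- ncol(mask)
  if (K < m) stop("need at least as many outcomes as factors (K >= m)")
  anchors <- matrix(as.integer(anchors), ncol = 2)
  if (any(anchors[, 1] < 1L | anchors[, 1] > K |
          anchors[, 2] < 1L | anchors[, 2] > m))
    stop("anchor position out of range")
  if (!identical(sort(as.integer(outcome_order)), seq_len(K)))
    stop("`outcome_order` must be a permutation of 1:K")
  if (is.null(outcome_labels)) outcome_labels <- paste0("outcome", seq_len(K))
  structure(list(mask = mask, anchors = anchors,
                 outcome_order = as.integer(outcome_order),
                 outcome_labels = as.character(outcome_labels)),
            class = "loadings_pattern")
}

#' The shared-plus-pairs loadings pattern for six outcomes and four factors
#'
#' Factor 1 loads on all six outcomes; factors 2-4 each load on one
#' pre-specified pair (deaths + ED visits, treatment + buprenorphine,
#' HCV + HIV).  Anchors are the diagonal entries of the leading 4x4 block.
#'
#' @return A [loadings_pattern].
#' @export
default_pattern <- function() {
  mask <- cbind(rep(TRUE, 6),
                c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
                c(FALSE, FALSE, FALSE, TRUE, FALSE, TRUE))
  loadings_pattern(mask, anchors = cbind(1:4, 1:4),
                   outcome_labels = c("death", "ed_visits", "treatment",
                                      "hcv", "buprenorphine", "hiv"))
}

# structural transversal (perfect matching on rows x columns of a boolean
# block) via depth-first augmenting paths; block is m x m
has_transversal <- function(block) {
  m <- ncol(block)
  match_col <- rep(0L, m)
  try_row <- function(r, seen) {
    for (cc in which(block[r, ])) {
      if (seen[cc]) next
      seen[cc] <- TRUE
      if (match_col[cc] == 0L || Recall(match_col[cc], seen)) {
        match_col[cc] <<- r
        return(TRUE)
      }
    }
    FALSE
  }
  for (r in seq_len(m)) if (!try_row(r, rep(FALSE, m))) return(FALSE)
  TRUE
}

leading_block_ok <- function(mask, ord, m) {
  block <- mask[ord[seq_len(m)], , drop = FALSE]
  all(rowSums(block) > 0) && all(colSums(block) > 0) && has_transversal(block)
}

#' Validate a loadings pattern
#'
#' A pattern is valid when (i) every anchor sits on a free entry and each
#' factor column has exactly one anchor, and (ii) the leading `m x m` block
#' (rows picked by `outcome_order`) is generically invertible: it has a free
#' entry in every row and every column and admits a structural transversal.
#' When the leading block fails, a repairing row permutation is searched for
#' and proposed.
#'
#' @param pattern a [loadings_pattern].
#' @return A list with elements `ok` (logical), `problems` (character) and
#'   `suggested_order` (a permutation of `1:K`, or `NULL`).
#' @export
validate_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "loadings_pattern"))
  mask <- pattern$mask
  K <- nrow(mask); m <- ncol(mask)
  problems <- character(0)
  for (a in seq_len(nrow(pattern$anchors))) {
    k <- pattern$anchors[a, 1]; mm <- pattern$anchors[a, 2]
    if (!mask[k, mm])
      problems <- c(problems, sprintf(
        "anchor (%d, %d) is not a free entry", k, mm))
  }
  tab <- tabulate(pattern$anchors[, 2], nbins = m)
  for (mm in which(tab != 1L))
    problems <- c(problems, sprintf(
      "column %d has %d anchors (exactly one required)", mm, tab[mm]))

  ord <- pattern$outcome_order
  block <- mask[ord[seq_len(m)], , drop = FALSE]
  suggested <- NULL
  block_bad <- FALSE
  for (r in which(rowSums(block) == 0)) {
    problems <- c(problems, sprintf("empty row %d of the leading block", r))
    block_bad <- TRUE
  }
  for (cc in which(colSums(block) == 0)) {
    problems <- c(problems, sprintf("empty column %d of the leading block", cc))
    block_bad <- TRUE
  }
  if (!block_bad && !has_transversal(block)) {
    problems <- c(problems,
                  "leading block has no structural transversal (rank deficient for all values)")
    block_bad <- TRUE
  }
  if (block_bad) {
    # search row subsets/orders for a generically invertible leading block
    combos <- utils::combn(K, m)
    for (ci in seq_len(ncol(combos))) {
      cand <- combos[, ci]
      if (leading_block_ok(mask, c(cand, setdiff(seq_len(K), cand)), m)) {
        suggested <- c(cand, setdiff(seq_len(K), cand))
        break
      }
    }
  }
  list(ok = length(problems) == 0L, problems = problems,
       suggested_order = suggested)
}

#' Partition the loadings for the LQ decomposition
#'
#' Transposes the loadings and splits the result into the square leading
#' part `A1` (`m x m`, from the first `m` outcomes under the pattern's
#' outcome order) and the remaining rectangular part `A2` (`m x (K-m)`).
#'
#' @param values `K x m` numeric loadings matrix.
#' @param pattern a validated [loadings_pattern].
#' @return list with elements `A1`, `A2` and the `outcome_order` applied.
#' @export
partition_loadings <- function(values, pattern) {
  chk <- validate_pattern(pattern)
  if (!chk$ok)
    stop("invalid loadings pattern: ", paste(chk$problems, collapse = "; "))
  values <- as.matrix(values)
  K <- nrow(pattern$mask); m <- ncol(pattern$mask)
  if (!identical(dim(values), dim(pattern$mask)))
    stop("loadings values do not match the pattern dimensions")
  g <- values[pattern$outcome_order, , drop = FALSE]
  list(A1 = t(g[seq_len(m), , drop = FALSE]),
       A2 = t(g[-seq_len(m), , drop = FALSE]),
       outcome_order = pattern$outcome_order)
}
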