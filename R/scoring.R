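#' Cohort-wise min-max normalization
#'
#' Maps a vector onto `[0, 1]` by `n(x) = (x - min) / (max - min)`. A
#' constant vector (max == min) maps to 0.5 everywhere — a neutral
#' contribution that avoids division by zero while keeping the component in
#' the score. The transform is invariant under positive affine rescaling:
#' `n(a*x + b) == n(x)` for `a > 0`.
#'
#' @param x Non-empty numeric vector of finite values.
#' @return Numeric vector in `[0, 1]`, same length as `x`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0L)
    stop("cannot normalize an empty vector", call. = FALSE)
  if (!is.numeric(x))
    stop("minmax_normalize expects a numeric vector", call. = FALSE)
  bad <- which(!is.finite(x))
  if (length(bad))
    stop("non-finite value at index ", bad[1L], call. = FALSE)
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) return(rep.int(0.5, length(x)))
  (x - lo) / (hi - lo)
}

#' Composite Bioactivity Score weights
#'
#' The composite score weights softness, electrophilicity, inverse gap and
#' the ESP Score at 0.30, 0.20, 0.20 and 0.15 by default. The defaults
#' deliberately sum to 0.85, not 1, and are applied as-is with no
#' renormalization; set `normalize = TRUE` to rescale them to unit sum.
#'
#' @param w_softness,w_omega,w_inv_gap,w_esp Non-negative weights.
#' @param normalize If `TRUE`, divide all weights by their sum.
#' @return Named list of class `"score_weights"`.
#' @export
score_weights <- function(w_softness = 0.30, w_omega = 0.20,
                          w_inv_gap = 0.20, w_esp = 0.15,
                          normalize = FALSE) {
  w <- c(w_softness = w_softness, w_omega = w_omega,
         w_inv_gap = w_inv_gap, w_esp = w_esp)
  if (any(!is.finite(w)) || any(w < 0))
    stop("score weights must be finite and non-negative", call. = FALSE)
  if (isTRUE(normalize)) {
    if (sum(w) == 0) stop("cannot normalize all-zero weights", call. = FALSE)
    w <- w / sum(w)
  }
  structure(as.list(w), class = "score_weights")
}

#' Composite Bioactivity Score
#'
#' Weighted sum of the four normalized components:
#' `w_softness * n(S) + w_omega * n(omega) + w_inv_gap * n(1/gap) +
#' w_esp * esp_score`. No renormalization is applied, so with the default
#' weights a compound maximal in every component scores 0.85.
#'
#' @param n_softness,n_omega,n_inv_gap,esp_score Normalized component
#'   vectors (equal length, finite).
#' @param weights A [score_weights()] object.
#' @return Numeric vector of composite scores.
#' @export
composite_score <- function(n_softness, n_omega, n_inv_gap, esp_score,
                            weights = score_weights()) {
  if (!inherits(weights, "score_weights")) weights <- do.call(score_weights, weights)
  comp <- cbind(n_softness, n_omega, n_inv_gap, esp_score)
  if (any(!is.finite(comp)))
    stop("all score components must be finite", call. = FALSE)
  weights$w_softness * n_softness + weights$w_omega * n_omega +
    weights$w_inv_gap * n_inv_gap + weights$w_esp * esp_score
}

#' Assemble and rank the cohort score table
#'
#' Joins a descriptor table with an ESP feature table by `compound_id`,
#' min-max-normalizes softness, electrophilicity and inverse gap within the
#' cohort, takes the ESP Score as-is (it is already cohort-relative), forms
#' the composite score and ranks compounds with [rank_compounds()].
#'
#' Because softness equals twice the inverse gap, `n_softness` and
#' `n_inv_gap` are identical columns under min-max normalization; both are
#' kept for transparency.
#'
#' @param descriptors Output of [compute_descriptor_table()] (needs columns
#'   `compound_id`, `softness`, `electrophilicity`, `inv_gap`).
#' @param esp Output of [esp_quantify()] or any table with `compound_id`,
#'   `esp_score`.
#' @param weights A [score_weights()] object.
#' @return `data.frame` sorted by rank: `compound_id`, `n_softness`,
#'   `n_omega`, `n_inv_gap`, `esp_score`, `composite`, `rank`, `tied`.
#' @export
build_score_table <- function(descriptors, esp, weights = score_weights()) {
  dids <- as.character(descriptors$compound_id)
  eids <- as.character(esp$compound_id)
  extra <- setdiff(eids, dids)
  miss <- setdiff(dids, eids)
  if (length(miss) || length(extra))
    stop("compound_id mismatch between descriptor and ESP tables",
         if (length(miss)) paste0("; missing from ESP: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0("; extra in ESP: ",
                                   paste(extra, collapse = ", ")),
         call. = FALSE)
  if (nrow(descriptors) == 0L)
    stop("empty cohort: no compounds to score", call. = FALSE)
  m <- match(dids, eids)
  tab <- data.frame(
    compound_id = dids,
    n_softness = minmax_normalize(descriptors$softness),
    n_omega = minmax_normalize(descriptors$electrophilicity),
    n_inv_gap = minmax_normalize(descriptors$inv_gap),
    esp_score = esp$esp_score[m],
    stringsAsFactors = FALSE
  )
  tab$composite <- composite_score(tab$n_softness, tab$n_omega,
                                   tab$n_inv_gap, tab$esp_score, weights)
  rank_compounds(tab)
}

#' Rank compounds by composite score
#'
#' Deterministic dense ranking: descending composite score, ties broken by
#' ascending `compound_id` (string order). Tied compounds are flagged in the
#' `tied` column. Ranks are the integers `1..N`; the returned table is
#' sorted by rank, so the ordering is invariant under input row permutation.
#'
#' @param table `data.frame` with `compound_id` and `composite` columns.
#' @return The table sorted by rank, with integer `rank` and logical `tied`
#'   columns.
#' @export
rank_compounds <- function(table) {
  if (!all(c("compound_id", "composite") %in% names(table)))
    stop("score table needs compound_id and composite columns", call. = FALSE)
  if (any(!is.finite(table$composite)))
    stop("composite score missing or non-finite for compound ",
         table$compound_id[which(!is.finite(table$composite))[1L]],
         call. = FALSE)
  ord <- order(-table$composite, as.character(table$compound_id),
               method = "radix")
  out <- table[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$tied <- duplicated(out$composite) | duplicated(out$composite,
                                                     fromLast = TRUE)
  rownames(out) <- NULL
  out
}
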