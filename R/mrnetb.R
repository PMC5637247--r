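#' MRNETB network inference from a mutual-information matrix
#'
#' For every target gene Y, a predictor subset S is selected to maximise the
#' maximum-relevance minimum-redundancy objective
#' \deqn{J(S, Y) = \sum_{i \in S} I(X_i; Y) -
#'       \frac{1}{|S|(|S|-1)} \sum_{i \ne j \in S} I(X_i; X_j)}
#' (the redundancy term is the mean pairwise MI inside S; zero for |S| <= 1).
#' Selection starts from all predictors with positive relevance and runs
#' backward elimination - repeatedly dropping the element whose removal yields
#' the largest J, while J does not decrease - followed by sequential
#' replacement: any single in-for-out swap that strictly increases J is
#' accepted, to a local optimum (the backward/replacement pair is the "B"
#' schedule that avoids forward selection's bad-first-pick failure mode).
#'
#' The undirected edge (i, j) exists when i is retained for target j or vice
#' versa; its weight is the larger of the two directional
#' relevance-minus-redundancy scores
#' `u_i = I(X_i;Y) - mean_{j in S, j != i} I(X_i;X_j)`, clamped at 0 so the
#' result is a valid nonnegative similarity network (a retained predictor can
#' carry a slightly negative score at the local optimum).
#'
#' @param mi Symmetric nonnegative MI matrix with gene dimnames (see
#'   [mutual_information()]).
#' @return An `iw_network` whose node universe is all genes of `mi` (genes
#'   that end up with no edge remain as isolated nodes).
#' @export
mrnetb <- function(mi) {
  stopifnot(is.matrix(mi), nrow(mi) == ncol(mi))
  if (max(abs(mi - t(mi))) > 1e-12) abort("MI matrix must be symmetric")
  if (any(mi < 0)) abort("MI matrix must be nonnegative")
  genes <- rownames(mi) %||% as.character(seq_len(nrow(mi)))
  g <- nrow(mi)
  score_rows <- list()
  for (y in seq_len(g)) {
    S <- mrnetb_select(mi, y)
    if (length(S) == 0) next
    sc <- directional_scores(mi, y, S)
    score_rows[[length(score_rows) + 1]] <-
      tibble(from = genes[S], to = genes[y], weight = sc)
  }
  if (length(score_rows) == 0) {
    return(new_network(tibble(from = character(), to = character(),
                              weight = numeric()), sort(genes)))
  }
  all_sc <- bind_rows(score_rows)
  lo <- pmin(all_sc$from, all_sc$to)
  hi <- pmax(all_sc$from, all_sc$to)
  agg <- tibble(from = lo, to = hi, weight = pmax(all_sc$weight, 0)) |>
    group_by(.data$from, .data$to) |>
    summarise(weight = max(.data$weight), .groups = "drop")
  gene_network(agg, nodes = genes)
}

# J(S, y): sum of relevance minus mean pairwise redundancy
mrmr_objective <- function(mi, y, S) {
  if (length(S) == 0) return(0)
  rel <- sum(mi[S, y])
  if (length(S) == 1) return(rel)
  red <- sum(mi[S, S]) / (length(S) * (length(S) - 1))  # diagonal is 0
  rel - red
}

# backward elimination (ties accepted, so irrelevant predictors fall away)
# then sequential replacement to a strict local optimum
mrnetb_select <- function(mi, y) {
  cand <- setdiff(which(mi[, y] > 0), y)
  S <- cand
  J <- mrmr_objective(mi, y, S)
  while (length(S) > 0) {
    Js <- vapply(seq_along(S),
                 function(i) mrmr_objective(mi, y, S[-i]), numeric(1))
    best <- which.max(Js)
    if (Js[best] >= J - 1e-15) {
      S <- S[-best]
      J <- Js[best]
    } else break
  }
  repeat {
    out <- setdiff(cand, S)
    if (length(S) == 0 || length(out) == 0) break
    improved <- FALSE
    for (i in seq_along(S)) {
      for (o in out) {
        S2 <- c(S[-i], o)
        J2 <- mrmr_objective(mi, y, S2)
        if (J2 > J + 1e-15) {
          S <- S2; J <- J2; improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  sort(S)
}

directional_scores <- function(mi, y, S) {
  vapply(S, function(i) {
    others <- setdiff(S, i)
    red <- if (length(others) == 0) 0 else mean(mi[i, others])
    mi[i, y] - red
  }, numeric(1))
}
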