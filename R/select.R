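#' A single Treg-evidence criterion across clusters
#'
#' One row of the selection framework: a per-cluster scalar (count of
#' enriched Treg-related terms, an NES, a Treg abundance, an immune score,
#' ...) with its direction. Values may be given as strings with an interval
#' (`"0.05-0.07"`); intervals are ingested as midpoints.
#'
#' @param criterion label, conventionally one of `"go_terms"`,
#'   `"kegg_nes"`, `"gsea_nes"`, `"treg_fraction"`, `"immune_score"`.
#' @param values named vector (names = clusters), numeric or interval
#'   strings.
#' @param higher_is_more_treg direction flag; `TRUE` means larger values
#'   indicate stronger Treg enrichment.
#' @param significance optional named per-cluster p-values.
#' @return a `criterion_result` list.
#' @export
criterion_result <- function(criterion, values, higher_is_more_treg = TRUE,
                             significance = NULL) {
  if (is.null(names(values)) || any(names(values) == ""))
    stop("values must be named by cluster")
  vals <- parse_criterion_value(values)
  names(vals) <- names(values)
  structure(list(criterion = criterion, values = vals,
                 higher_is_more_treg = isTRUE(higher_is_more_treg),
                 significance = significance),
            class = "criterion_result")
}

#' Assemble the per-criterion rank matrix
#'
#' Ranks every cluster within each criterion (rank 1 = most Treg-like given
#' the criterion's direction; ties share the minimum rank).
#'
#' @param criteria list of [criterion_result()] objects over a consistent
#'   cluster set.
#' @return a `selection_matrix` with `clusters`, `criteria`, `values`
#'   (criteria x clusters) and `ranks` (criteria x clusters).
#' @export
build_selection_matrix <- function(criteria) {
  stopifnot(length(criteria) >= 1)
  clusters <- sort(names(criteria[[1]]$values))
  for (cr in criteria) {
    if (!identical(sort(names(cr$values)), clusters))
      stop("criterion '", cr$criterion,
           "' covers a different cluster set")
  }
  values <- t(vapply(criteria, function(cr) cr$values[clusters],
                     numeric(length(clusters))))
  higher <- vapply(criteria, `[[`, logical(1), "higher_is_more_treg")
  ranks <- t(vapply(seq_along(criteria), function(i) {
    v <- if (higher[i]) -values[i, ] else values[i, ]
    rank(v, ties.method = "min")
  }, numeric(length(clusters))))
  dimnames(values) <- dimnames(ranks) <-
    list(vapply(criteria, `[[`, "", "criterion"), clusters)
  structure(list(clusters = clusters, criteria = criteria,
                 values = values, ranks = ranks),
            class = "selection_matrix")
}

#' @export
print.selection_matrix <- function(x, ...) {
  cat("<selection_matrix> ranks (1 = most Treg-like):\n")
  print(x$ranks)
  invisible(x)
}

#' Name the most Treg-enriched cluster
#'
#' The winner is the cluster with the most criterion-wise rank-1 finishes.
#' Ties are broken by lower mean rank, then by the higher value on the
#' `gsea_nes` criterion (if present), then by cluster name order. The
#' report records per-criterion winners and whether a tie-break fired.
#'
#' @param matrix a [build_selection_matrix()] result.
#' @return a `selection_report` with `selected_cluster`,
#'   `per_criterion_winner`, `wins`, `mean_rank`, `tie_break_used` and an
#'   `evidence` text.
#' @export
select_treg_cluster <- function(matrix) {
  stopifnot(inherits(matrix, "selection_matrix"))
  if (length(matrix$clusters) == 1)
    warning("single cluster supplied; selection is degenerate")
  ranks <- matrix$ranks
  wins <- colSums(ranks == 1)
  mean_rank <- colMeans(ranks)
  per_criterion <- apply(ranks, 1, function(r)
    paste(matrix$clusters[r == 1], collapse = "/"))

  tie_break_used <- FALSE
  cand <- matrix$clusters[wins == max(wins)]
  if (length(cand) > 1) {
    tie_break_used <- TRUE
    cand <- cand[mean_rank[cand] == min(mean_rank[cand])]
    if (length(cand) > 1 && "gsea_nes" %in% rownames(matrix$values)) {
      nes <- matrix$values["gsea_nes", cand]
      cand <- cand[nes == max(nes)]
    }
  }
  selected <- cand[1]

  evidence <- sprintf(
    "cluster %s selected: rank-1 on %d/%d criteria (%s)%s",
    selected, wins[selected], nrow(ranks),
    paste(sprintf("%s->%s", rownames(ranks), per_criterion), collapse = "; "),
    if (tie_break_used) " [tie-break applied]" else "")
  structure(list(selected_cluster = selected,
                 per_criterion_winner = per_criterion,
                 wins = wins, mean_rank = mean_rank,
                 tie_break_used = tie_break_used,
                 evidence = evidence),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>", x$evidence, "\n")
  invisible(x)
}
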