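# Preranked set enrichment of genera and GMM carrier sets over the species
# association results: signed ranking metric, weighted running-sum enrichment
# score, and a set-membership permutation null.

#' Build a direction-stratified ranking from association results
#'
#' Ranking score per species: `sign(beta) * (-log10 p)`, so strong negative
#' associations fall at the bottom of the list and strong positive ones at the
#' top. Ties are broken by `|beta|` (larger first) and then by species id, so
#' the ordering is fully deterministic. Zero p-values are capped at the
#' smallest positive double before the log.
#'
#' @param assoc_results Data frame with one row per species for one outcome:
#'   columns `exposure`, `beta`, `p`.
#' @return Object of class `ranked_list`: named numeric vector of scores in
#'   descending ranking order.
#' @export
make_ranking <- function(assoc_results) {
  if (anyDuplicated(assoc_results$exposure)) {
    stop_input("one association result per species required")
  }
  p <- pmax(assoc_results$p, .Machine$double.xmin)
  score <- sign(assoc_results$beta) * (-log10(p))
  ord <- order(-score, -abs(assoc_results$beta), assoc_results$exposure)
  structure(stats::setNames(score, assoc_results$exposure)[ord],
            class = "ranked_list")
}

#' Weighted running-sum enrichment score
#'
#' Walking the ranking from top to bottom, members of the set add
#' `|score| / sum(|score| over the set)` and non-members subtract
#' `1 / (N - set size)` (weight exponent 1). The enrichment score (ES) is the
#' extremum of largest magnitude of the running sum; the leading edge is the
#' member species at or before a positive extremum, or at or after a negative
#' one.
#'
#' @param ranking A [make_ranking] result.
#' @param member_set Character vector of species ids; must be a non-empty
#'   strict subset of the ranking.
#' @return List: `es`, `running` (profile), `leading_edge`.
#' @export
enrichment_score <- function(ranking, member_set) {
  ids <- names(ranking)
  member_set <- unique(member_set)
  if (!length(member_set)) stop_input("member set is empty")
  if (!all(member_set %in% ids)) {
    stop_input("member set contains species absent from the ranking")
  }
  if (length(member_set) >= length(ids)) {
    stop("degenerate error: member set must be a strict subset of the ranking",
         call. = FALSE)
  }
  hit <- ids %in% member_set
  w <- abs(unclass(ranking))
  denom_hit <- sum(w[hit])
  step <- ifelse(hit,
                 if (denom_hit > 0) w / denom_hit else 1 / sum(hit),
                 -1 / (length(ids) - length(member_set)))
  running <- cumsum(step)
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  leading <- if (es >= 0) ids[hit & seq_along(ids) <= i_ext] else ids[hit & seq_along(ids) >= i_ext]
  list(es = es, running = running, leading_edge = leading)
}

#' Permutation enrichment test over a species-set catalog
#'
#' For each set, the null distribution of the ES is generated by drawing
#' random member sets of the same size from the ranking;
#' `p = (1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)`, with BH adjustment
#' across all tested sets. Sets falling below `min_set_size` after
#' intersection with the ranking are skipped (and reported).
#'
#' @param ranking A [make_ranking] result.
#' @param catalog A [build_species_sets] result.
#' @param n_perm Permutations per set (>= 99).
#' @param seed Integer seed.
#' @param min_set_size Minimum post-intersection set size, default 5.
#' @param fdr Flag threshold on q, default 0.05.
#' @return Object of class `enrichment_result`: data frame with `set_id`,
#'   `kind`, `size`, `es`, `p`, `q`, `flagged`, `leading_edge`
#'   (semicolon-separated); attribute `skipped` lists undersized sets.
#' @export
enrichment_test <- function(ranking, catalog, n_perm = 999L, seed = 1L,
                            min_set_size = 5L, fdr = 0.05) {
  if (n_perm < 99L) stop_config("n_perm must be at least 99")
  ids <- names(ranking)
  sets <- lapply(catalog$sets, intersect, y = ids)
  sizes <- lengths(sets)
  usable <- sizes >= min_set_size & sizes < length(ids)
  skipped <- names(sets)[!usable]
  sets <- sets[usable]
  if (!length(sets)) stop_input("no usable sets after intersection with the ranking")
  rows <- with_local_seed(seed, {
    lapply(names(sets), function(sid) {
      obs <- enrichment_score(ranking, sets[[sid]])
      k <- length(sets[[sid]])
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        es_b <- enrichment_score(ranking, sample(ids, k))$es
        if (abs(es_b) >= abs(obs$es)) exceed <- exceed + 1L
      }
      data.frame(set_id = sid, kind = catalog$kind[[sid]], size = k,
                 es = obs$es, p = (1 + exceed) / (n_perm + 1),
                 leading_edge = paste(obs$leading_edge, collapse = ";"))
    })
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res$flagged <- res$q < fdr
  res <- res[, c("set_id", "kind", "size", "es", "p", "q", "flagged", "leading_edge")]
  rownames(res) <- NULL
  structure(res, skipped = skipped, n_perm = n_perm, seed = seed,
            class = c("enrichment_result", "data.frame"))
}

#' @export
print.enrichment_result <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("Enrichment over %d sets (%d permutations); %d flagged at 5%% FDR\n",
              nrow(df), attr(x, "n_perm"), sum(df$flagged)))
  print(utils::head(df[order(df$p), c("set_id", "kind", "size", "es", "p", "q", "flagged")], 10L),
        row.names = FALSE, digits = 3)
  invisible(x)
}
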