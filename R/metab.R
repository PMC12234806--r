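# Partial Spearman correlation between BP-signature species and plasma
# metabolites, with per-species BH adjustment and top-k selection among
# annotated metabolites.

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y` (mid-ranks for ties), residualises both rank
#' vectors on the covariate design by least squares, and correlates the
#' residuals. The p-value uses the t statistic at `n - 2 - k` degrees of
#' freedom where `k` is the covariate rank. With no covariates this reduces
#' to the ordinary Spearman correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Numeric covariate matrix (no intercept), or `NULL`.
#' @return List: `rho`, `p`, `n`, `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop_input("x and y must have equal length")
  k <- 0L
  rx <- rank(x); ry <- rank(y)
  if (!is.null(covariates)) {
    Z <- cbind(1, as.matrix(covariates))
    qz <- qr(Z, tol = 1e-8)
    k <- qz$rank - 1L
    rx <- stats::residuals(stats::lm.fit(Z, rx))
    ry <- stats::residuals(stats::lm.fit(Z, ry))
  } else {
    rx <- rx - mean(rx); ry <- ry - mean(ry)
  }
  if (n <= k + 3L) stop_input("too few observations for %d covariates", k)
  sx <- sqrt(sum(rx^2)); sy <- sqrt(sum(ry^2))
  scale0 <- sqrt(sum((rank(x) - mean(rank(x)))^2) * sum((rank(y) - mean(rank(y)))^2))
  if (sx * sy <= 1e-14 * max(scale0, 1)) {
    stop("undefined-correlation error: zero residual variance after adjustment",
         call. = FALSE)
  }
  rho <- sum(rx * ry) / (sx * sy)
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), n = n, df = df)
}

#' Metabolite correlation screen for BP-signature species
#'
#' Computes the partial Spearman correlation of every signature species with
#' every metabolite, BH-adjusts within species across metabolites, and selects
#' the `top_k` annotated metabolite associations with the smallest q-values
#' per species. Also emits a sign-pattern matrix (sign of rho for the selected
#' metabolite union across all species) for concordance inspection.
#'
#' @param signature_clr Numeric matrix, samples x signature species (CLR
#'   values).
#' @param metabolites Numeric matrix, samples x metabolites.
#' @param annotated Logical vector per metabolite (named or in column order):
#'   `TRUE` when the metabolite is chemically annotated.
#' @param covariates Numeric covariate matrix (no intercept), or `NULL`.
#' @param top_k Number of annotated associations selected per species.
#' @return Object of class `metab_screen`: list with `results` (data frame:
#'   `species`, `metabolite`, `rho`, `p`, `q`, `n`, `annotated`), `top`
#'   (top-k rows per species), `sign_pattern` (species x metabolite sign
#'   matrix over the union of selected metabolites).
#' @export
metabolite_screen <- function(signature_clr, metabolites, annotated,
                              covariates = NULL, top_k = 10L) {
  signature_clr <- as.matrix(signature_clr)
  metabolites <- as.matrix(metabolites)
  if (nrow(signature_clr) != nrow(metabolites)) {
    stop_input("species and metabolite tables must align on samples")
  }
  if (length(annotated) != ncol(metabolites)) {
    stop_input("need one annotation flag per metabolite")
  }
  annotated <- stats::setNames(as.logical(annotated), colnames(metabolites))
  blocks <- lapply(colnames(signature_clr), function(sp) {
    rows <- lapply(colnames(metabolites), function(mb) {
      r <- partial_spearman(signature_clr[, sp], metabolites[, mb], covariates)
      data.frame(species = sp, metabolite = mb, rho = r$rho, p = r$p, n = r$n,
                 annotated = annotated[[mb]])
    })
    out <- do.call(rbind, rows)
    out$q <- bh_fdr(out$p)
    out
  })
  results <- do.call(rbind, blocks)
  rownames(results) <- NULL
  top <- do.call(rbind, lapply(split(results, results$species), function(dd) {
    ann <- dd[dd$annotated, , drop = FALSE]
    if (!nrow(ann)) return(ann)
    if (nrow(ann) < top_k) {
      warning(sprintf("species %s: only %d annotated metabolites available (top_k = %d)",
                      dd$species[1L], nrow(ann), top_k))
    }
    utils::head(ann[order(ann$q, ann$p), , drop = FALSE], top_k)
  }))
  rownames(top) <- NULL
  if (!nrow(top)) warning("no annotated metabolites; top-k table is empty")
  sel <- unique(top$metabolite)
  sign_pattern <- NULL
  if (length(sel)) {
    sign_pattern <- matrix(0, ncol(signature_clr), length(sel),
                           dimnames = list(colnames(signature_clr), sel))
    for (i in seq_len(nrow(results))) {
      if (results$metabolite[i] %in% sel) {
        sign_pattern[results$species[i], results$metabolite[i]] <- sign(results$rho[i])
      }
    }
  }
  structure(list(results = results, top = top, sign_pattern = sign_pattern),
            class = "metab_screen")
}

#' @export
print.metab_screen <- function(x, ...) {
  cat(sprintf("Metabolite screen: %d species x %d metabolites\n",
              length(unique(x$results$species)), length(unique(x$results$metabolite))))
  if (nrow(x$top)) {
    cat("Top annotated associations per species (by q):\n")
    print(x$top[, c("species", "metabolite", "rho", "q")], row.names = FALSE, digits = 3)
  }
  invisible(x)
}
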