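# Compositional preprocessing: prevalence filtering, pseudo-count CLR with
# per-species zero replacement, rarefaction, alpha diversity, Bray-Curtis.

#' Construct a relative-abundance table
#'
#' Thin validated container for a samples x species relative-abundance matrix
#' (rows sum to one) with an optional species-to-genus map used later for
#' enrichment set construction.
#'
#' @param values Numeric matrix, samples in rows, species in columns; each row
#'   must sum to 1 within `1e-9`. Row and column names identify samples and
#'   species.
#' @param genus_of Named character vector mapping species id to genus; defaults
#'   to each species being its own genus.
#' @return An object of class `abundance_table` (a matrix with a `genus`
#'   attribute).
#' @export
abundance_table <- function(values, genus_of = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("sp", seq_len(ncol(values)))
  if (any(values < 0)) stop_input("relative abundances must be non-negative")
  rs <- rowSums(values)
  if (any(abs(rs - 1) > 1e-9)) {
    stop_input("abundance rows must sum to 1 within 1e-9 (worst deviation %.3g)",
               max(abs(rs - 1)))
  }
  if (is.null(genus_of)) {
    genus_of <- stats::setNames(colnames(values), colnames(values))
  }
  if (!all(colnames(values) %in% names(genus_of))) {
    stop_input("genus_of must name every species in the table")
  }
  structure(values, genus = genus_of[colnames(values)], class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d species (%d genera)\n",
              nrow(x), ncol(x), length(unique(attr(x, "genus")))))
  invisible(x)
}

#' Filter species on abundance and prevalence
#'
#' Keeps species whose relative abundance exceeds `min_abund` in strictly more
#' than a `min_prev` fraction of samples. Rows are deliberately not re-closed
#' after column subsetting: the retained columns keep their original
#' relative-abundance values so that downstream log-ratio quantities refer to
#' the original composition.
#'
#' @param table An [abundance_table].
#' @param min_abund Abundance threshold (fraction), default `1e-4` (0.01%).
#' @param min_prev Prevalence threshold (fraction of samples), default `0.30`.
#' @return An `abundance_table` restricted to the retained species. Rows are
#'   not re-closed, so they no longer sum to 1; the result carries class
#'   `filtered_abundance` in addition.
#' @export
filter_species <- function(table, min_abund = 1e-4, min_prev = 0.30) {
  if (min_abund <= 0 || min_abund >= 1 || min_prev <= 0 || min_prev >= 1) {
    stop_config("filter thresholds must lie in (0, 1)")
  }
  prev <- colMeans(table > min_abund)
  keep <- prev > min_prev
  if (!any(keep)) warning("no species pass the abundance/prevalence filter")
  out <- unclass(table)[, keep, drop = FALSE]
  structure(out, genus = attr(table, "genus")[keep],
            class = c("filtered_abundance", "matrix", "array"))
}

#' Centred log-ratio transform with pseudo-count and zero replacement
#'
#' Three-step policy: (1) a universal pseudo-value delta equal to the smallest
#' non-zero entry of the whole matrix is added to every cell; (2) each sample
#' is CLR-transformed, `log(x + delta)` minus the sample mean of
#' `log(x + delta)` over the included species; (3) for each species, cells
#' whose original abundance was exactly zero are replaced by the minimum CLR
#' value that species attains among samples where it was originally non-zero,
#' so all original zeros of a species share one equally-low value.
#'
#' Step (3) intentionally breaks the row-sum-zero identity of the CLR; the
#' pre-replacement matrix satisfies it and is retained in the result.
#'
#' @param table A (possibly filtered) abundance matrix, samples x species.
#' @return An object of class `clr_table`: list with `values` (post-replacement
#'   CLR matrix), `pre_replacement` (pure CLR matrix), `pseudo_value` (delta),
#'   and `replaced_mask` (logical matrix of originally-zero cells).
#' @export
clr_transform <- function(table) {
  x <- unclass(as.matrix(table))
  if (nrow(x) == 0L || ncol(x) == 0L) stop_input("abundance table is empty")
  zero_species <- colSums(x > 0) == 0L
  if (any(zero_species)) {
    stop("policy error: species with zero abundance in every sample (",
         paste(colnames(x)[zero_species], collapse = ", "),
         "); filter before CLR", call. = FALSE)
  }
  delta <- min(x[x > 0])
  lx <- log(x + delta)
  clr <- lx - rowMeans(lx)
  replaced <- x == 0
  values <- clr
  for (j in which(colSums(replaced) > 0L)) {
    values[replaced[, j], j] <- min(clr[!replaced[, j], j])
  }
  structure(list(values = values, pre_replacement = clr,
                 pseudo_value = delta, replaced_mask = replaced),
            class = "clr_table")
}

#' @export
print.clr_table <- function(x, ...) {
  cat(sprintf("clr_table: %d samples x %d species; pseudo-value %.3g; %d zero cells replaced\n",
              nrow(x$values), ncol(x$values), x$pseudo_value, sum(x$replaced_mask)))
  invisible(x)
}

#' Rarefy a count table to fixed depth
#'
#' Subsamples each sample's counts without replacement to a common depth
#' (default 190,977), via [vegan::rrarefy] under a local seed.
#'
#' @param counts Integer matrix of counts, samples in rows.
#' @param depth Target depth per sample.
#' @param seed Integer seed.
#' @return Integer matrix with every row summing exactly to `depth`.
#' @export
rarefy_counts <- function(counts, depth = 190977L, seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("counts must be non-negative integers")
  }
  totals <- rowSums(counts)
  short <- totals < depth
  if (any(short)) {
    stop_input("samples below rarefaction depth %d: %s", depth,
               paste(sprintf("%s (%d)", rownames(counts)[short] %||% which(short),
                             totals[short]), collapse = ", "))
  }
  # counts are validated as integers above; silence vegan's count heuristic
  out <- with_local_seed(seed, withCallingHandlers(
    vegan::rrarefy(counts, depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(out) <- "integer"
  out
}

#' Alpha diversity of a count or proportion table
#'
#' @param table Matrix with samples in rows (typically the rarefied counts).
#' @param metric One of `"shannon"` (natural log), `"richness"` (count of
#'   non-zero species), `"inv_simpson"`.
#' @return Numeric vector, one value per sample.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "richness", "inv_simpson")) {
  metric <- match.arg(metric)
  x <- as.matrix(table)
  if (any(rowSums(x) <= 0)) stop_domain("alpha diversity undefined for empty samples")
  switch(metric,
         shannon     = vegan::diversity(x, index = "shannon"),
         richness    = rowSums(x > 0),
         inv_simpson = vegan::diversity(x, index = "invsimpson"))
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum|a_i - b_i| / sum(a_i + b_i)`, computed with
#' [vegan::vegdist] and returned as a dense symmetric matrix with zero
#' diagonal.
#'
#' @param table Non-negative matrix, samples in rows.
#' @return Square symmetric numeric matrix in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  x <- unclass(as.matrix(table))
  if (any(x < 0)) stop_input("Bray-Curtis requires non-negative data")
  if (any(rowSums(x) == 0)) {
    stop_domain("Bray-Curtis undefined for all-zero samples: %s",
                paste(rownames(x)[rowSums(x) == 0] %||% which(rowSums(x) == 0),
                      collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(x, method = "bray"))
  diag(d) <- 0
  d
}
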