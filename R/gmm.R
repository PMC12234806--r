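# Gut metabolic module (GMM) carriage from KEGG-ortholog presence, and
# species-set catalogues (genus sets, GMM carrier sets) for enrichment.

#' Construct a GMM definition
#'
#' A module consists of one or more alternative paths; each path is an ordered
#' list of steps and each step is a non-empty set of alternative KEGG Orthology
#' (KO) identifiers that can perform it.
#'
#' @param module_id Module identifier.
#' @param paths List of paths; each path a list of character vectors (KO
#'   alternatives per step).
#' @return Object of class `gmm_definition`.
#' @export
gmm_definition <- function(module_id, paths) {
  if (!length(paths)) stop_input("module '%s' needs at least one path", module_id)
  for (p in paths) {
    if (!length(p)) stop_input("module '%s' has an empty path", module_id)
    if (any(!lengths(p))) stop_input("module '%s' has a step with no KO alternatives", module_id)
  }
  structure(list(module_id = module_id, paths = paths), class = "gmm_definition")
}

#' Decide whether a KO repertoire carries a metabolic module
#'
#' A step is covered when at least one of its alternative KOs is present. A
#' path qualifies when the fraction of covered steps is at least two-thirds;
#' for paths of three or fewer steps every step must be covered. The module is
#' carried when any path qualifies.
#'
#' @param ko_presence Character vector of KO identifiers present in a species.
#' @param module A [gmm_definition].
#' @return Logical scalar.
#' @export
carries_module <- function(ko_presence, module) {
  stopifnot(inherits(module, "gmm_definition"))
  for (path in module$paths) {
    covered <- vapply(path, function(step) any(step %in% ko_presence), logical(1))
    L <- length(covered)
    ok <- if (L <= 3L) all(covered) else mean(covered) >= 2 / 3
    if (ok) return(TRUE)
  }
  FALSE
}

#' Build species sets for enrichment (genus sets and GMM carrier sets)
#'
#' Genus sets come from the abundance table's species-to-genus map; each GMM
#' set contains the species whose KO repertoire carries the module. Sets
#' smaller than `min_set_size` are pruned (and reported).
#'
#' @param abundance An [abundance_table] (or filtered table) whose columns are
#'   the analysis species.
#' @param gmms List of [gmm_definition]s.
#' @param ko_profiles Named list: species id -> character vector of KOs.
#' @param min_set_size Minimum retained set size (default 5, for enrichment
#'   stability).
#' @return Object of class `species_set_catalog`: list with `sets` (named list
#'   of species-id vectors), `kind` (named `"genus"`/`"gmm"`), `pruned`
#'   (names of sets dropped for size).
#' @export
build_species_sets <- function(abundance, gmms, ko_profiles, min_set_size = 5L) {
  species <- colnames(abundance)
  missing_ko <- setdiff(species, names(ko_profiles))
  if (length(missing_ko)) {
    stop_input("ko_profiles missing species: %s",
               paste(utils::head(missing_ko, 5L), collapse = ", "))
  }
  genus <- attr(abundance, "genus")
  sets <- split(species, genus[species])
  kind <- stats::setNames(rep("genus", length(sets)), names(sets))
  for (m in gmms) {
    carriers <- species[vapply(species, function(s) carries_module(ko_profiles[[s]], m), logical(1))]
    sets[[m$module_id]] <- carriers
    kind[m$module_id] <- "gmm"
  }
  small <- lengths(sets) < min_set_size
  pruned <- names(sets)[small]
  sets <- sets[!small]
  kind <- kind[!small]
  if (!length(sets)) stop_input("species-set catalog is empty after pruning")
  structure(list(sets = sets, kind = kind, pruned = pruned),
            class = "species_set_catalog")
}

#' @export
print.species_set_catalog <- function(x, ...) {
  cat(sprintf("species_set_catalog: %d sets (%d genus, %d gmm); %d pruned for size\n",
              length(x$sets), sum(x$kind == "genus"), sum(x$kind == "gmm"),
              length(x$pruned)))
  invisible(x)
}

#' Write GMM definitions to a structured text file
#'
#' Tab-separated with columns `module_id`, `path_id`, `step_index`, `kos`
#' (comma-separated alternatives).
#'
#' @param gmms List of [gmm_definition]s.
#' @param path Output file path.
#' @export
write_gmm_definitions <- function(gmms, path) {
  rows <- do.call(rbind, lapply(gmms, function(m) {
    do.call(rbind, lapply(seq_along(m$paths), function(pi) {
      data.frame(module_id = m$module_id, path_id = pi,
                 step_index = seq_along(m$paths[[pi]]),
                 kos = vapply(m$paths[[pi]], paste, "", collapse = ","))
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GMM definitions written by [write_gmm_definitions]
#'
#' @param path File path.
#' @return List of [gmm_definition]s.
#' @export
read_gmm_definitions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$module_id), function(mt) {
    paths <- lapply(split(mt, mt$path_id), function(pt) {
      pt <- pt[order(pt$step_index), ]
      strsplit(pt$kos, ",")
    })
    gmm_definition(mt$module_id[1L], unname(paths))
  })
}

#' Write a species-set catalog as GMT-style text
#'
#' One line per set: set id, description (set kind), then member species ids,
#' tab-separated.
#'
#' @param catalog A [build_species_sets] result.
#' @param path Output file path.
#' @export
write_gmt <- function(catalog, path) {
  lines <- vapply(names(catalog$sets), function(id) {
    paste(c(id, catalog$kind[[id]], catalog$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
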