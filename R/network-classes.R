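#' Construct a metabolic reaction
#'
#' A reaction is the atomic unit of a genome-scale metabolic network: a set of
#' substrates and products with positive stoichiometric coefficients, a
#' reversibility flag, and the gene and pathway annotations that link it to the
#' expression data. Reaction identifiers are MetaCyc-style strings shared
#' across bins, which is what makes cross-bin aggregation by reaction possible.
#'
#' @param id Unique reaction identifier (non-empty string).
#' @param substrates Named numeric vector: metabolite id -> coefficient (> 0).
#' @param products Named numeric vector: metabolite id -> coefficient (> 0).
#' @param reversible Logical; may the reaction also fire backwards?
#' @param genes Character vector of gene ids catalysing the reaction.
#' @param pathways Character vector of pathway ids the reaction belongs to.
#' @param exchange Logical; exchange/boundary reactions may have an empty
#'   substrate or product side.
#' @return An object of class `"Reaction"`.
#' @export
#' @examples
#' reaction("R1", c(A = 1), c(B = 1), genes = "g1", pathways = "PWY1")
reaction <- function(id, substrates = numeric(), products = numeric(),
                     reversible = FALSE, genes = character(),
                     pathways = character(), exchange = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    validation_error("reaction id must be a non-empty string")
  }
  substrates <- as_stoich(substrates, id, "substrate")
  products <- as_stoich(products, id, "product")
  if (!exchange && (length(substrates) == 0L || length(products) == 0L)) {
    validation_error(sprintf(
      "reaction '%s': substrates and products must be non-empty unless exchange = TRUE", id))
  }
  shared <- intersect(names(substrates), names(products))
  if (length(shared)) {
    validation_error(sprintf("reaction '%s': metabolite(s) on both sides: %s",
                             id, paste(shared, collapse = ", ")))
  }
  structure(
    list(id = id, substrates = substrates, products = products,
         reversible = isTRUE(reversible),
         genes = unique(as.character(genes)),
         pathways = unique(as.character(pathways)),
         exchange = isTRUE(exchange)),
    class = "Reaction"
  )
}

as_stoich <- function(x, rid, side) {
  if (length(x) == 0L) return(setNames(numeric(0), character(0)))
  x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    validation_error(sprintf("reaction '%s': unnamed %s coefficients", rid, side))
  }
  x <- vapply(split(as.numeric(x), names(x)), sum, numeric(1))
  if (any(!is.finite(x)) || any(x <= 0)) {
    validation_error(sprintf("reaction '%s': %s coefficients must be positive", rid, side))
  }
  x
}

#' Construct a genome-scale metabolic network
#'
#' @param organism_id Bin or host label.
#' @param reactions List of [reaction()] objects.
#' @param metabolites Optional data.frame with columns `id` and optionally
#'   `name`, `compartment`. Metabolites referenced by reactions but not listed
#'   are added automatically; declaring them explicitly only attaches metadata.
#' @param completeness Optional completeness percentage (metadata only).
#' @return Object of class `"MetabolicNetwork"` with unique reaction ids and a
#'   resolved metabolite table.
#' @export
metabolic_network <- function(organism_id, reactions = list(),
                              metabolites = NULL, completeness = NA_real_) {
  if (!is.character(organism_id) || length(organism_id) != 1L || !nzchar(organism_id)) {
    validation_error("organism_id must be a non-empty string")
  }
  if (length(reactions) && !all(vapply(reactions, inherits, logical(1), "Reaction"))) {
    validation_error("reactions must be a list of Reaction objects")
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    validation_error(sprintf("duplicate reaction id(s): %s",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(reactions) <- ids
  referenced <- unique(unlist(lapply(reactions, function(r) {
    c(names(r$substrates), names(r$products))
  })))
  referenced <- referenced %||% character(0)
  if (is.null(metabolites)) {
    metabolites <- data.frame(id = character(0), name = character(0),
                              compartment = character(0), stringsAsFactors = FALSE)
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- NA_character_
  if (anyDuplicated(metabolites$id)) {
    validation_error("duplicate metabolite ids in metabolite table")
  }
  extra <- setdiff(referenced, metabolites$id)
  if (length(extra)) {
    metabolites <- rbind(metabolites[, c("id", "name", "compartment")],
                         data.frame(id = extra, name = extra,
                                    compartment = NA_character_,
                                    stringsAsFactors = FALSE))
  }
  rownames(metabolites) <- NULL
  structure(
    list(organism_id = organism_id, metabolites = metabolites,
         reactions = reactions, completeness = completeness),
    class = "MetabolicNetwork"
  )
}

#' @export
print.MetabolicNetwork <- function(x, ...) {
  cat(sprintf("MetabolicNetwork '%s': %d reactions, %d metabolites\n",
              x$organism_id, length(x$reactions), nrow(x$metabolites)))
  n_rev <- sum(vapply(x$reactions, `[[`, logical(1), "reversible"))
  n_gene <- length(network_genes(x))
  cat(sprintf("  %d reversible; %d distinct genes\n", n_rev, n_gene))
  invisible(x)
}

#' Genes annotated anywhere in a network
#' @param network A `MetabolicNetwork`.
#' @return Character vector of distinct gene ids.
#' @export
network_genes <- function(network) {
  unique(unlist(lapply(network$reactions, `[[`, "genes"))) %||% character(0)
}

#' Reaction-to-pathway map of a network (or several)
#'
#' @param ... One or more `MetabolicNetwork` objects.
#' @return Named list: reaction id -> character vector of pathway ids (union
#'   across the supplied networks).
#' @export
pathway_map <- function(...) {
  nets <- list(...)
  if (length(nets) == 1L && is.list(nets[[1]]) && !inherits(nets[[1]], "MetabolicNetwork")) {
    nets <- nets[[1]]
  }
  out <- list()
  for (net in nets) {
    for (r in net$reactions) {
      out[[r$id]] <- unique(c(out[[r$id]], r$pathways))
    }
  }
  out
}

#' Validate a metabolic network
#'
#' Produces a report of structural problems: dangling metabolite references,
#' duplicate reaction ids, and non-exchange reactions with an empty side. A
#' network is valid iff the report has zero rows. The constructors enforce most
#' of these invariants already; `validate_network()` exists to vet objects
#' assembled by hand or deserialised from files.
#'
#' @param network A `MetabolicNetwork` (or a bare list shaped like one).
#' @return A data.frame with columns `type`, `id`, `message`; zero rows when
#'   the network is valid.
#' @export
validate_network <- function(network) {
  issues <- list()
  add <- function(type, id, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, id = id, message = message, stringsAsFactors = FALSE)
  }
  ids <- vapply(network$reactions, function(r) r$id %||% NA_character_, character(1))
  dup <- unique(ids[duplicated(ids)])
  for (d in dup) add("duplicate_reaction", d, "reaction id occurs more than once")
  declared <- network$metabolites$id
  for (r in network$reactions) {
    refs <- c(names(r$substrates), names(r$products))
    dangling <- setdiff(refs, declared)
    for (m in dangling) {
      add("dangling_reference", m,
          sprintf("reaction '%s' references undeclared metabolite '%s'", r$id, m))
    }
    if (!isTRUE(r$exchange) &&
        (length(r$substrates) == 0L || length(r$products) == 0L)) {
      add("empty_reaction", r$id, "non-exchange reaction with an empty side")
    }
  }
  if (length(issues) == 0L) {
    return(data.frame(type = character(0), id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, issues)
}

#' Merge metabolic networks into a meta-organism
#'
#' Community-level ("mixed bag") analyses work on the union of the member
#' networks: metabolites and reactions are merged by id, and reactions present
#' in several members keep a single definition with the union of their gene and
#' pathway annotations. Two members defining the same reaction id with
#' different stoichiometry or reversibility is treated as a data error rather
#' than silently resolved.
#'
#' @param networks Non-empty list of `MetabolicNetwork` objects.
#' @param label Organism label for the merged network.
#' @return A `MetabolicNetwork`.
#' @export
merge_networks <- function(networks, label = "merged") {
  if (inherits(networks, "MetabolicNetwork")) networks <- list(networks)
  if (length(networks) == 0L) validation_error("merge_networks: empty network list")
  merged <- list()
  origin <- list()
  for (net in networks) {
    for (r in net$reactions) {
      if (is.null(merged[[r$id]])) {
        merged[[r$id]] <- r
        origin[[r$id]] <- net$organism_id
      } else {
        prev <- merged[[r$id]]
        if (!identical(prev$substrates[order(names(prev$substrates))],
                       r$substrates[order(names(r$substrates))]) ||
            !identical(prev$products[order(names(prev$products))],
                       r$products[order(names(r$products))]) ||
            !identical(prev$reversible, r$reversible)) {
          hs_error(sprintf(
            paste0("conflicting definitions for reaction '%s' between '%s' and '%s':\n",
                   "  first:  %s\n  second: %s"),
            r$id, origin[[r$id]], net$organism_id,
            format_reaction(prev), format_reaction(r)),
            "holoscope_conflict_error")
        }
        prev$genes <- unique(c(prev$genes, r$genes))
        prev$pathways <- unique(c(prev$pathways, r$pathways))
        merged[[r$id]] <- prev
      }
    }
  }
  met <- unique(do.call(rbind, lapply(networks, function(n) {
    n$metabolites[, c("id", "name", "compartment")]
  })))
  met <- met[!duplicated(met$id), , drop = FALSE]
  metabolic_network(label, unname(merged), metabolites = met)
}

format_reaction <- function(r) {
  side <- function(v) paste(sprintf("%g %s", unname(v), names(v)), collapse = " + ")
  sprintf("%s %s %s", side(r$substrates),
          if (r$reversible) "<=>" else "-->", side(r$products))
}

#' Build a bin catalog
#'
#' Bundles the per-bin metabolic networks with the gene-to-bin map the
#' aggregation stage needs. Gene ids must be unique across the catalog (in
#' practice they are bin-prefixed), and every mapped bin must have a network.
#'
#' @param networks Named list: bin id -> `MetabolicNetwork`.
#' @param gene_to_bin Named character vector: gene id -> bin id. Defaults to
#'   the map implied by the networks' own gene annotations.
#' @return Object of class `"BinCatalog"`.
#' @export
bin_catalog <- function(networks, gene_to_bin = NULL) {
  if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
    validation_error("networks must be a named list (bin id -> network)")
  }
  if (is.null(gene_to_bin)) {
    gene_to_bin <- unlist(lapply(names(networks), function(b) {
      setNames(rep(b, length(network_genes(networks[[b]]))),
               network_genes(networks[[b]]))
    })) %||% setNames(character(0), character(0))
  }
  if (anyDuplicated(names(gene_to_bin))) {
    dup <- unique(names(gene_to_bin)[duplicated(names(gene_to_bin))])
    validation_error(sprintf("gene id(s) mapped to more than one bin: %s",
                             paste(head(dup, 5), collapse = ", ")))
  }
  unknown <- setdiff(unique(gene_to_bin), names(networks))
  if (length(unknown)) {
    validation_error(sprintf("gene map references unknown bin(s): %s",
                             paste(unknown, collapse = ", ")))
  }
  structure(list(networks = networks, gene_to_bin = gene_to_bin),
            class = "BinCatalog")
}

#' @export
print.BinCatalog <- function(x, ...) {
  cat(sprintf("BinCatalog: %d bins, %d mapped genes\n",
              length(x$networks), length(x$gene_to_bin)))
  invisible(x)
}
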