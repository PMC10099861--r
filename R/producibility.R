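# Network-expansion producibility ("scope"). A reaction fires forward once
# every substrate is available and, if reversible, backward once every product
# is; fired reactions add their outputs to the available pool; iteration
# continues to a fixed point. Stoichiometric coefficients are ignored (boolean
# availability) and compartments play no role — the standard network-expansion
# convention for qualitative producibility.

#' Metabolites producible from a seed set (network expansion)
#'
#' @param network A `MetabolicNetwork`.
#' @param seeds A `SeedSet` (or character vector of metabolite ids).
#' @return Object of class `"ScopeResult"`: list with elements
#'   `network_label`, `seeds`, `producible` (character vector, includes the
#'   seeds), `first_iteration` (named integer vector; 0 for seeds),
#'   `fired_reactions` (data.frame `iteration`, `reaction_id`, `direction`)
#'   and `iterations`.
#' @details The result is a monotone closure: it contains the seeds, adding
#'   seeds or reactions can only enlarge it, and it is independent of the
#'   order in which reactions are examined. Each direction of a reversible
#'   reaction is tested independently and may fire at most once.
#' @export
#' @examples
#' net <- metabolic_network("toy", list(
#'   reaction("R1", c(A = 1), c(B = 1)),
#'   reaction("R2", c(B = 1), c(C = 1))))
#' scope(net, seed_set("A"))$producible
scope <- function(network, seeds) {
  if (!inherits(seeds, "SeedSet")) seeds <- seed_set(seeds)
  issues <- validate_network(network)
  if (nrow(issues)) {
    validation_error(sprintf("scope: network '%s' is invalid (%d issue(s)); run validate_network()",
                             network$organism_id, nrow(issues)))
  }
  # Flatten to parallel lists of directions for speed and order-independence.
  dirs <- list()
  for (r in network$reactions) {
    dirs[[length(dirs) + 1L]] <- list(id = r$id, dir = "forward",
                                      need = names(r$substrates),
                                      gain = names(r$products))
    if (r$reversible) {
      dirs[[length(dirs) + 1L]] <- list(id = r$id, dir = "backward",
                                        need = names(r$products),
                                        gain = names(r$substrates))
    }
  }
  producible <- unique(as.character(seeds))
  first_iteration <- setNames(rep(0L, length(producible)), producible)
  unfired <- seq_along(dirs)
  fired <- list()
  iter <- 0L
  repeat {
    can_fire <- unfired[vapply(dirs[unfired], function(d) {
      all(d$need %in% producible)
    }, logical(1))]
    if (length(can_fire) == 0L) break
    iter <- iter + 1L
    gains <- setdiff(unique(unlist(lapply(dirs[can_fire], `[[`, "gain"))),
                     producible)
    fired[[iter]] <- data.frame(
      iteration = iter,
      reaction_id = vapply(dirs[can_fire], `[[`, character(1), "id"),
      direction = vapply(dirs[can_fire], `[[`, character(1), "dir"),
      stringsAsFactors = FALSE)
    if (length(gains)) {
      first_iteration[gains] <- iter
      producible <- c(producible, gains)
    }
    unfired <- setdiff(unfired, can_fire)
  }
  fired_df <- do.call(rbind, fired) %||%
    data.frame(iteration = integer(0), reaction_id = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  rownames(fired_df) <- NULL
  structure(list(network_label = network$organism_id, seeds = seeds,
                 producible = sort(producible),
                 first_iteration = first_iteration[sort(producible)],
                 fired_reactions = fired_df,
                 iterations = iter),
            class = "ScopeResult")
}

#' @export
print.ScopeResult <- function(x, ...) {
  cat(sprintf("ScopeResult '%s': %d producible metabolites (%d seeds, %d iterations, %d firings)\n",
              x$network_label, length(x$producible), length(x$seeds),
              x$iterations, nrow(x$fired_reactions)))
  invisible(x)
}

#' Community producibility under mixed-bag semantics
#'
#' The community scope is the scope of the union of the member networks, i.e.
#' members exchange metabolites freely. A metabolite can therefore be
#' community-producible even when no single member produces it alone (one
#' member's product feeds another member's reaction).
#'
#' @param networks Non-empty list of `MetabolicNetwork` objects.
#' @param seeds A `SeedSet`.
#' @param label Label for the merged community network.
#' @return A `ScopeResult` for the merged network.
#' @export
community_scope <- function(networks, seeds, label = "community") {
  scope(merge_networks(networks, label = label), seeds)
}

#' In-silico added value of a community for its host
#'
#' Computes which metabolites become newly producible by the host when it is
#' given access to everything the community can make from the medium: the
#' community scope is added to the host's seed set and the host scope is
#' recomputed. `added_value` is the difference to the host-alone scope —
#' metabolites the host can only make in the presence of community-supplied
#' precursors.
#'
#' @param host Host `MetabolicNetwork`.
#' @param community List of community member networks (may be empty).
#' @param seeds A `SeedSet`.
#' @return Object of class `"AddedValueResult"`: list with `host_alone`,
#'   `community_producible`, `host_with_community` (all character vectors) and
#'   `added_value = host_with_community \ host_alone`.
#' @export
added_value <- function(host, community, seeds) {
  if (!inherits(seeds, "SeedSet")) seeds <- seed_set(seeds)
  host_alone <- scope(host, seeds)$producible
  community_producible <- if (length(community) == 0L) {
    character(0)
  } else {
    community_scope(community, seeds)$producible
  }
  augmented <- seed_set(unique(c(as.character(seeds), community_producible)),
                        label = paste0(attr(seeds, "label"), "+community"))
  host_with <- scope(host, augmented)$producible
  structure(list(host_alone = host_alone,
                 community_producible = community_producible,
                 host_with_community = host_with,
                 added_value = sort(setdiff(host_with, host_alone))),
            class = "AddedValueResult")
}

#' @export
print.AddedValueResult <- function(x, ...) {
  cat(sprintf("AddedValueResult: host alone %d, community %d, host+community %d, added value %d\n",
              length(x$host_alone), length(x$community_producible),
              length(x$host_with_community), length(x$added_value)))
  invisible(x)
}

#' Upset-style intersection table of producible sets
#'
#' Partitions the union of the supplied sets by exact membership pattern
#' (which conditions contain the element), the computation behind an upset
#' plot. Pattern counts sum to the size of the union.
#'
#' @param results Named list (>= 2 entries): condition -> character vector.
#' @return A data.frame with one logical column per condition, the `count`
#'   of elements showing exactly that pattern, and a `members` column with the
#'   comma-separated element ids; per-condition totals are attached as the
#'   `"totals"` attribute.
#' @export
compare_producibility <- function(results) {
  if (length(results) < 2L || is.null(names(results))) {
    validation_error("compare_producibility: need a named list of >= 2 sets")
  }
  conds <- names(results)
  universe <- sort(unique(unlist(results)))
  membership <- vapply(conds, function(cn) universe %in% results[[cn]],
                       logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, conds))
  key <- apply(membership, 1L, paste, collapse = "|")
  patterns <- unique(key)
  out <- do.call(rbind, lapply(patterns, function(k) {
    rows <- key == k
    flags <- membership[which(rows)[1], , drop = TRUE]
    df <- as.data.frame(as.list(flags), check.names = FALSE)
    df$count <- sum(rows)
    df$members <- paste(universe[rows], collapse = ",")
    df
  }))
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "totals") <- vapply(results, function(x) length(unique(x)), integer(1))
  out
}
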