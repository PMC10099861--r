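# Network serialisation. Two dialects are supported: SBML level 2/3 (the
# format genome-scale networks are archived in) and a compact two-file TSV
# dialect used for fixtures and human-readable exports. Both round-trip
# through the corresponding writer.

#' Read a metabolic network from SBML
#'
#' Parses SBML level 2 or level 3 documents. Gene associations are taken from
#' `fbc:geneProductAssociation` elements when present, otherwise from
#' `GENE_ASSOCIATION:` lines in reaction notes; pathway annotations from
#' `SUBSYSTEM:` note lines. Reversibility is the `reversible` attribute
#' (default `TRUE` in SBML L2, required in L3). Boolean gene logic is
#' flattened to the set of genes mentioned, which is all downstream stages
#' use.
#'
#' @param path Path to an SBML file.
#' @param organism_id Optional label overriding the model id.
#' @return A `MetabolicNetwork`.
#' @export
read_sbml <- function(path, organism_id = NULL) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    format_error(sprintf("SBML parse failure in %s: %s", path, conditionMessage(e)))
  })
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) {
    format_error(sprintf("%s: no <model> element (line %d)", path, 1L))
  }
  label <- organism_id %||% xml2::xml_attr(model, "id") %||% "model"
  if (is.na(label)) label <- "model"

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")),
                  xml2::xml_attr(sp_nodes, "id"), xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(mets$id)) {
    validation_error(sprintf("%s: duplicate species id(s): %s", path,
                             paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    rev_attr <- xml2::xml_attr(node, "reversible")
    reversible <- if (is.na(rev_attr)) TRUE else tolower(rev_attr) == "true"
    subs <- sbml_side(node, "listOfReactants")
    prods <- sbml_side(node, "listOfProducts")
    notes <- paste(xml2::xml_text(xml2::xml_find_all(node, ".//notes//p")),
                   collapse = "\n")
    gp_refs <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
    genes <- vapply(gp_refs, function(ref) {
      at <- xml2::xml_attrs(ref)
      hit <- grep("(^|:)geneProduct$", names(at))
      if (length(hit)) unname(at[[hit[1]]]) else NA_character_
    }, character(1))
    genes <- genes[!is.na(genes)]
    if (length(genes) == 0L) genes <- parse_note_field(notes, "GENE_ASSOCIATION")
    pwys <- parse_note_field(notes, "SUBSYSTEM")
    reaction(rid, subs, prods, reversible = reversible, genes = genes,
             pathways = pwys,
             exchange = length(subs) == 0L || length(prods) == 0L)
  })

  referenced <- unique(unlist(lapply(reactions, function(r) {
    c(names(r$substrates), names(r$products))
  })))
  dangling <- setdiff(referenced, mets$id)
  if (length(dangling)) {
    validation_error(sprintf("%s: dangling species reference(s): %s", path,
                             paste(dangling, collapse = ", ")))
  }
  metabolic_network(label, reactions, metabolites = mets)
}

sbml_side <- function(node, list_name) {
  refs <- xml2::xml_find_all(node, sprintf(".//%s/speciesReference", list_name))
  if (length(refs) == 0L) return(numeric(0))
  coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
  coef[is.na(coef)] <- 1
  setNames(coef, xml2::xml_attr(refs, "species"))
}

parse_note_field <- function(notes, field) {
  lines <- strsplit(notes, "\n", fixed = TRUE)[[1]]
  hits <- grep(paste0("^\\s*", field, ":"), lines, value = TRUE)
  if (length(hits) == 0L) return(character(0))
  val <- sub(paste0("^\\s*", field, ":\\s*"), "", hits[[1]])
  toks <- unlist(strsplit(val, "\\s+(or|and)\\s+|[,;]\\s*"))
  toks <- gsub("[()]", "", toks)
  toks <- trimws(toks)
  toks[nzchar(toks)]
}

#' Write a metabolic network to SBML
#'
#' Emits SBML level 3 version 1 core with gene associations and pathway
#' annotations encoded as `GENE_ASSOCIATION:` / `SUBSYSTEM:` note lines, the
#' convention [read_sbml()] parses back, making write/read a lossless
#' round-trip for the fields this package uses.
#'
#' @param network A `MetabolicNetwork`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">')
  w('  <model id="%s">', esc(network$organism_id))
  comps <- unique(network$metabolites$compartment)
  comps <- comps[!is.na(comps)]
  if (length(comps) == 0L) comps <- "c"
  w('    <listOfCompartments>')
  for (cm in comps) w('      <compartment id="%s" constant="true"/>', esc(cm))
  w('    </listOfCompartments>')
  w('    <listOfSpecies>')
  for (i in seq_len(nrow(network$metabolites))) {
    m <- network$metabolites[i, ]
    w('      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
      esc(m$id), esc(m$name), esc(if (is.na(m$compartment)) comps[[1]] else m$compartment))
  }
  w('    </listOfSpecies>')
  w('    <listOfReactions>')
  for (r in network$reactions) {
    w('      <reaction id="%s" reversible="%s" fast="false">',
      esc(r$id), if (r$reversible) "true" else "false")
    if (length(r$genes) || length(r$pathways)) {
      w('        <notes><body xmlns="http://www.w3.org/1999/xhtml">')
      if (length(r$genes)) {
        w('          <p>GENE_ASSOCIATION: %s</p>', esc(paste(r$genes, collapse = " or ")))
      }
      if (length(r$pathways)) {
        w('          <p>SUBSYSTEM: %s</p>', esc(paste(r$pathways, collapse = ", ")))
      }
      w('        </body></notes>')
    }
    for (side in c("Reactants", "Products")) {
      v <- if (side == "Reactants") r$substrates else r$products
      if (length(v)) {
        w('        <listOf%s>', side)
        for (j in seq_along(v)) {
          w('          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
            esc(names(v)[j]), unname(v[j]))
        }
        w('        </listOf%s>', side)
      }
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  w('  </model>')
  w('</sbml>')
  invisible(path)
}

#' Read a metabolic network from the TSV dialect
#'
#' The reactions file has columns `reaction_id`, `substrates`, `products`,
#' `reversible` (0/1) and `pathways`; stoichiometries are written as
#' `"A:1,B:2"` tokens and pathways comma-separated. The optional gene map file
#' has columns `gene_id`, `reaction_id`. An empty substrate or product field
#' marks an exchange reaction.
#'
#' @param reactions_path Reactions TSV path.
#' @param gene_map_path Optional gene map TSV path.
#' @param organism_id Network label (defaults to the reactions file stem).
#' @return A `MetabolicNetwork`.
#' @export
read_network_tsv <- function(reactions_path, gene_map_path = NULL,
                             organism_id = NULL) {
  rx <- read_tsv_checked(reactions_path,
                         c("reaction_id", "substrates", "products",
                           "reversible", "pathways"))
  label <- organism_id %||%
    sub("\\.[^.]*$", "", basename(reactions_path))
  gene_map <- NULL
  if (!is.null(gene_map_path)) {
    gene_map <- read_tsv_checked(gene_map_path, c("gene_id", "reaction_id"))
    unknown <- setdiff(unique(gene_map$reaction_id), rx$reaction_id)
    if (length(unknown)) {
      validation_error(sprintf("%s: gene map references unknown reaction(s): %s",
                               gene_map_path, paste(unknown, collapse = ", ")))
    }
  }
  reactions <- lapply(seq_len(nrow(rx)), function(i) {
    row <- rx[i, ]
    subs <- parse_stoich_tokens(row$substrates, reactions_path, row$reaction_id)
    prods <- parse_stoich_tokens(row$products, reactions_path, row$reaction_id)
    genes <- if (is.null(gene_map)) character(0) else
      gene_map$gene_id[gene_map$reaction_id == row$reaction_id]
    pwys <- split_list_field(row$pathways)
    reaction(row$reaction_id, subs, prods,
             reversible = as.integer(row$reversible) == 1L,
             genes = genes, pathways = pwys,
             exchange = length(subs) == 0L || length(prods) == 0L)
  })
  metabolic_network(label, reactions)
}

parse_stoich_tokens <- function(field, path, rid) {
  field <- trimws(field %||% "")
  if (is.na(field) || !nzchar(field)) return(numeric(0))
  toks <- trimws(strsplit(field, ",", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (tok in toks) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    coef <- if (length(parts) == 2L) {
      suppressWarnings(as.numeric(parts[[2]]))
    } else NA_real_
    if (length(parts) != 2L || !nzchar(parts[[1]]) || is.na(coef)) {
      format_error(sprintf("%s: malformed stoichiometry token '%s' in reaction '%s'",
                           path, tok, rid))
    }
    out[parts[[1]]] <- coef
  }
  out
}

split_list_field <- function(field) {
  field <- trimws(field %||% "")
  if (is.na(field) || !nzchar(field)) return(character(0))
  toks <- trimws(strsplit(field, ",", fixed = TRUE)[[1]])
  toks[nzchar(toks)]
}

#' Write a network in the TSV dialect
#'
#' @param network A `MetabolicNetwork`.
#' @param reactions_path Output path for the reactions table.
#' @param gene_map_path Optional output path for the gene map.
#' @return `reactions_path`, invisibly.
#' @export
write_network_tsv <- function(network, reactions_path, gene_map_path = NULL) {
  fmt_side <- function(v) paste(sprintf("%s:%g", names(v), unname(v)), collapse = ",")
  df <- do.call(rbind, lapply(network$reactions, function(r) {
    data.frame(reaction_id = r$id,
               substrates = fmt_side(r$substrates),
               products = fmt_side(r$products),
               reversible = as.integer(r$reversible),
               pathways = paste(r$pathways, collapse = ","),
               stringsAsFactors = FALSE)
  })) %||% data.frame(reaction_id = character(0), substrates = character(0),
                      products = character(0), reversible = integer(0),
                      pathways = character(0))
  write_tsv(df, reactions_path)
  if (!is.null(gene_map_path)) {
    gm <- do.call(rbind, lapply(network$reactions, function(r) {
      if (length(r$genes) == 0L) return(NULL)
      data.frame(gene_id = r$genes, reaction_id = r$id, stringsAsFactors = FALSE)
    })) %||% data.frame(gene_id = character(0), reaction_id = character(0))
    write_tsv(gm, gene_map_path)
  }
  invisible(reactions_path)
}

#' Read a seed-metabolite set
#'
#' Seeds abstract the growth medium for producibility analyses. TSV files need
#' a `metabolite_id` column; JSON files either a bare array of ids or an
#' object with fields `label` and `metabolites`.
#'
#' @param path Path to a `.tsv`/`.txt` or `.json` seed file.
#' @param label Seed-set label (defaults to the file stem / JSON label).
#' @return Object of class `"SeedSet"`: a character vector of metabolite ids
#'   with a `label` attribute.
#' @export
read_seeds <- function(path, label = NULL) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.list(obj) && !is.null(obj$metabolites)) {
      ids <- as.character(obj$metabolites)
      label <- label %||% obj$label
    } else {
      ids <- as.character(obj)
    }
  } else {
    ids <- read_tsv_checked(path, "metabolite_id")$metabolite_id
  }
  seed_set(ids, label %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct a seed set
#' @param metabolites Non-empty character vector of metabolite ids.
#' @param label Label for the medium (e.g. `"glucose-minimal"`).
#' @export
seed_set <- function(metabolites, label = "seeds") {
  metabolites <- unique(as.character(metabolites))
  if (length(metabolites) == 0L || any(!nzchar(metabolites))) {
    validation_error("seed set must contain at least one non-empty metabolite id")
  }
  structure(metabolites, label = label, class = "SeedSet")
}

#' Default glucose-centred seed medium
#'
#' Glucose as the sole carbon source plus a small inorganic complement
#' (water, phosphate, ammonium, sulfate, oxygen, carbon dioxide) — a minimal
#' abstraction of a glucose growth medium for scope analyses.
#' @return A `SeedSet`.
#' @export
default_seeds <- function() {
  seed_set(c("GLC", "WATER", "Pi", "AMMONIUM", "SULFATE",
             "OXYGEN-MOLECULE", "CARBON-DIOXIDE"),
           label = "glucose-minimal")
}
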