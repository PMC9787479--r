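# File formats: comma-delimited tables, run manifests (JSON) and bipartite
# graph exports (GraphML via igraph, GEXF via xml2) with iron-involving
# reaction nodes flagged so visualization tools can color them.

#' Write a network as comma-delimited tables
#'
#' Writes `nodes.csv` (one row per species, with degrees) and `edges.csv`
#' (one row per reaction event, reactant/product multisets `;`-joined).
#' Together the two files reconstruct the network losslessly (see
#' [read_network_csv()]).
#'
#' @param net a `crn_network`
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
write_network_csv <- function(net, dir) {
  stopifnot(inherits(net, "crn_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  deg <- degree_metrics(net)
  nodes <- merge(net$species, deg, by = "id", sort = FALSE)
  nodes <- nodes[order(match(nodes$id, net$species$id)), ]
  np <- file.path(dir, "nodes.csv")
  ep <- file.path(dir, "edges.csv")
  utils::write.csv(nodes, np, row.names = FALSE)
  utils::write.csv(events_df(net), ep, row.names = FALSE)
  invisible(c(nodes = np, edges = ep))
}

#' Rebuild a network from its CSV export
#'
#' @param dir directory holding `nodes.csv` and `edges.csv`
#' @return list with `species` (data.frame) and `events` (list), comparable
#'   with the originating network's fields
#' @export
read_network_csv <- function(dir) {
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"),
                           stringsAsFactors = FALSE)
  edges <- utils::read.csv(file.path(dir, "edges.csv"),
                           stringsAsFactors = FALSE)
  events <- lapply(seq_len(nrow(edges)), function(i) {
    list(rule = edges$rule[i], iron = edges$iron[i],
         reactants = sort(strsplit(edges$reactants[i], ";", fixed = TRUE)[[1]]),
         products = sort(strsplit(edges$products[i], ";", fixed = TRUE)[[1]]),
         generation = edges$generation[i])
  })
  list(species = nodes[, c("id", "formula", "mass", "charge", "ubiquitous",
                           "first_generation")],
       events = events)
}

# bipartite igraph: species vertices + one vertex per reaction event
network_igraph <- function(net) {
  sp_ids <- net$species$id
  ev_ids <- if (length(net$events))
    sprintf("event_%d", seq_along(net$events)) else character(0)
  el <- list()
  for (k in seq_along(net$events)) {
    ev <- net$events[[k]]
    for (r in ev$reactants) el[[length(el) + 1L]] <- c(r, ev_ids[k])
    for (p in ev$products) el[[length(el) + 1L]] <- c(ev_ids[k], p)
  }
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(sp_ids) + length(ev_ids),
                            name = c(sp_ids, ev_ids))
  if (length(el)) {
    em <- do.call(rbind, el)
    g <- igraph::add_edges(g, t(cbind(match(em[, 1], c(sp_ids, ev_ids)),
                                      match(em[, 2], c(sp_ids, ev_ids)))))
  }
  nsp <- length(sp_ids)
  deg <- degree_metrics(net)
  dm <- match(sp_ids, deg$id)
  igraph::V(g)$kind <- c(rep("species", nsp),
                         rep("reaction", length(ev_ids)))
  igraph::V(g)$formula <- c(net$species$formula, rep(NA, length(ev_ids)))
  igraph::V(g)$mass <- c(net$species$mass, rep(NA, length(ev_ids)))
  igraph::V(g)$first_generation <- c(net$species$first_generation,
                                     vapply(net$events, `[[`, 0L, "generation"))
  igraph::V(g)$in_degree <- c(deg$in_degree[dm], rep(NA, length(ev_ids)))
  igraph::V(g)$out_degree <- c(deg$out_degree[dm], rep(NA, length(ev_ids)))
  igraph::V(g)$total_degree <- c(deg$total_degree[dm], rep(NA, length(ev_ids)))
  igraph::V(g)$rule <- c(rep(NA, nsp),
                         vapply(net$events, `[[`, "", "rule"))
  igraph::V(g)$iron_flag <- c(rep(FALSE, nsp),
                              vapply(net$events, `[[`, TRUE, "iron"))
  g
}

#' Export a network as a bipartite directed graph
#'
#' Species nodes carry canonical id, formula, mass, first generation and
#' degrees; reaction nodes carry rule name, generation and an `iron_flag`
#' attribute (so iron-involving reactions can be colored in a viewer); edges
#' run reactant -> event -> product with multiplicity.
#'
#' @param net a `crn_network`
#' @param path output file
#' @param format `"graphml"` or `"gexf"`
#' @return invisibly, `path`
#' @export
export_network <- function(net, path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  g <- network_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    write_gexf(g, path)
  }
  invisible(path)
}

# minimal GEXF 1.2 writer over an attributed igraph
write_gexf <- function(g, path) {
  doc <- xml2::xml_new_root("gexf",
    xmlns = "http://www.gexf.net/1.2draft", version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "directed")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  fields <- c("kind", "formula", "mass", "first_generation", "in_degree",
              "out_degree", "total_degree", "rule", "iron_flag")
  types <- c("string", "string", "integer", "integer", "integer",
             "integer", "integer", "string", "boolean")
  for (i in seq_along(fields))
    xml2::xml_add_child(attrs, "attribute", id = as.character(i - 1L),
                        title = fields[i], type = types[i])
  nodes <- xml2::xml_add_child(graph, "nodes")
  vnames <- igraph::V(g)$name
  for (v in seq_along(vnames)) {
    nd <- xml2::xml_add_child(nodes, "node", id = vnames[v],
                              label = vnames[v])
    av <- xml2::xml_add_child(nd, "attvalues")
    for (i in seq_along(fields)) {
      val <- igraph::vertex_attr(g, fields[i])[v]
      if (!is.na(val))
        xml2::xml_add_child(av, "attvalue", `for` = as.character(i - 1L),
                            value = as.character(val))
    }
  }
  edges <- xml2::xml_add_child(graph, "edges")
  el <- igraph::as_edgelist(g, names = TRUE)
  for (k in seq_len(nrow(el)))
    xml2::xml_add_child(edges, "edge", id = as.character(k - 1L),
                        source = el[k, 1], target = el[k, 2])
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Node and edge counts of an exported graph file
#'
#' Reads a GraphML file back through igraph or a GEXF file through xml2 and
#' returns its node/edge counts, for round-trip verification.
#' @param path exported file
#' @param format `"graphml"` or `"gexf"`
#' @export
exported_graph_counts <- function(path, format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    c(nodes = as.integer(igraph::vcount(g)),
      edges = as.integer(igraph::ecount(g)))
  } else {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns(doc)
    c(nodes = length(xml2::xml_find_all(doc, "//d1:node", ns)),
      edges = length(xml2::xml_find_all(doc, "//d1:edge", ns)))
  }
}

#' Write a run manifest (JSON)
#'
#' Configuration echo, per-generation novelty counts and totals; suitable as
#' a compact regression record of a run.
#' @param net a `crn_network`
#' @param path output file
#' @export
write_manifest <- function(net, path) {
  stopifnot(inherits(net, "crn_network"))
  manifest <- list(
    config = list(
      seeds = vapply(net$config$seeds, function(s) s$canonical_id, ""),
      rules = names(net$config$rules),
      max_generations = net$config$max_generations,
      mass_cap = net$config$mass_cap
    ),
    per_generation = net$per_generation,
    totals = list(
      species = nrow(net$species),
      molecular_species = sum(!net$species$ubiquitous),
      events = length(net$events),
      saturated_at = net$saturated_at
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a comparison report to disk
#'
#' Emits `catalysis.csv`, `degrees.csv`, `rule_frequencies.csv` and
#' `report.json` under `dir`.
#' @param cmp a `crn_comparison` from [compare_networks()]
#' @param dir output directory
#' @export
write_comparison_report <- function(cmp, dir) {
  stopifnot(inherits(cmp, "crn_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cmp$catalyzed, file.path(dir, "catalysis.csv"),
                   row.names = FALSE)
  degs <- rbind(cbind(network = "iron_free", cmp$degrees_free),
                cbind(network = "iron_containing", cmp$degrees_iron))
  utils::write.csv(degs, file.path(dir, "degrees.csv"), row.names = FALSE)
  utils::write.csv(cmp$rule_frequencies,
                   file.path(dir, "rule_frequencies.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    totals = cmp$totals,
    percent_catalysis = cmp$percent_catalysis,
    percent_catalysis_printed = cmp$percent_catalysis_printed,
    n_catalyzed = nrow(cmp$catalyzed),
    growth = list(
      free = if (!is.null(cmp$growth_free))
        cmp$growth_free[c("slope", "intercept", "fold_per_generation")],
      iron = if (!is.null(cmp$growth_iron))
        cmp$growth_iron[c("slope", "intercept", "fold_per_generation")]
    )
  ), file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE, na = "null")
  invisible(dir)
}
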