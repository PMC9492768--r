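#' Signed directed gene networks
#'
#' A `signed_network` is the package's container for a prior-knowledge
#' network (PKN): a directed graph whose nodes are gene symbols and whose
#' edges carry an activation (+1) or inhibition (-1) sign. Gene symbols are
#' uppercased and deduplicated on ingest; at most one edge is kept per
#' ordered node pair (conflicting duplicate signs resolve to inhibition).
#'
#' @param edges A data frame with columns `from`, `to`, `sign` (+1/-1).
#' @param nodes Optional character vector of node symbols; defaults to the
#'   union of edge endpoints. Isolated nodes may be added here.
#' @param name Pathway identifier.
#'
#' @return A `signed_network`: list with `name`, `nodes` (sorted unique
#'   uppercase symbols) and `edges` (a tibble `from`, `to`, `sign`).
#' @export
#'
#' @examples
#' net <- signed_network(data.frame(from = "A", to = "B", sign = -1))
#' net$edges
signed_network <- function(edges, nodes = NULL, name = "network") {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to", "sign") %in% names(edges)))
  edges$from <- toupper(as.character(edges$from))
  edges$to <- toupper(as.character(edges$to))
  edges$sign <- as.integer(edges$sign)
  if (nrow(edges) && !all(edges$sign %in% c(-1L, 1L))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  # merge duplicates per ordered pair; inhibition dominates on conflict
  if (nrow(edges)) {
    merged <- edges |>
      dplyr::group_by(.data$from, .data$to) |>
      dplyr::summarise(
        n_signs = dplyr::n_distinct(.data$sign),
        sign = min(.data$sign),
        .groups = "drop"
      )
    if (any(merged$n_signs > 1L)) {
      warning("conflicting duplicate edge signs merged to inhibition (-1)",
              call. = FALSE)
    }
    edges <- merged |> dplyr::select("from", "to", "sign")
  }
  nodes <- sort(unique(c(toupper(as.character(nodes)), edges$from, edges$to)))
  if (!length(nodes)) stop("network has no nodes", call. = FALSE)
  structure(
    list(name = name, nodes = nodes,
         edges = dplyr::arrange(edges, .data$from, .data$to)),
    class = "signed_network"
  )
}

#' @export
print.signed_network <- function(x, ...) {
  cat("<signed_network> ", x$name, ": ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", sum(x$edges$sign < 0), " inhibitory)\n",
      sep = "")
  invisible(x)
}

#' Parse a KEGG KGML pathway file into a signed network
#'
#' KEGG `entry` elements of type gene (or group) frequently bundle several
#' gene symbols; each member gene inherits every relation of its entry, so a
#' relation between two multi-gene entries expands to the full bipartite set
#' of signed edges. Relation subtypes `activation`/`expression` map to +1 and
#' `inhibition`/`repression` to -1. Subtypes with no sign semantics (binding,
#' indirect effect, ...) default to +1 with a warning unless `strict = TRUE`,
#' in which case they are dropped.
#'
#' @param path Path to a KGML file, or a KGML string.
#' @param strict Drop sign-less relation subtypes instead of defaulting to +1.
#' @param name Network name; defaults to the KGML `title`/`name` attribute.
#'
#' @return A [signed_network()].
#' @export
parse_kgml <- function(path, strict = FALSE, name = NULL) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (is.na(root)) stop("not a KGML document: no <pathway> root", call. = FALSE)
  if (is.null(name)) {
    name <- xml2::xml_attr(root, "title")
    if (is.na(name)) name <- xml2::xml_attr(root, "name")
    if (is.na(name)) name <- "kegg_pathway"
  }

  entries <- xml2::xml_find_all(doc, "//entry")
  entry_genes <- list() # entry id -> character vector of member symbols
  for (e in entries) {
    id <- xml2::xml_attr(e, "id")
    type <- xml2::xml_attr(e, "type")
    if (identical(type, "group")) {
      comp <- xml2::xml_find_all(e, "component")
      entry_genes[[id]] <- list(members = xml2::xml_attr(comp, "id"),
                                kind = "group")
      next
    }
    gname <- xml2::xml_attr(e, "name")
    gfx <- xml2::xml_find_first(e, "graphics")
    label <- if (!is.na(gfx)) xml2::xml_attr(gfx, "name") else NA_character_
    # prefer graphics labels ("AKT1, AKT..."), fall back to the name field
    # stripped of the "hsa:"/"ko:" prefixes
    syms <- character(0)
    if (!is.na(label) && nzchar(label)) {
      syms <- strsplit(label, ",")[[1]]
      syms <- sub("\\.\\.\\.$", "", trimws(syms))
    } else if (!is.na(gname)) {
      syms <- sub("^[a-z]+:", "", strsplit(gname, "\\s+")[[1]])
    }
    syms <- toupper(syms[nzchar(syms)])
    if (identical(type, "gene") && length(syms)) {
      entry_genes[[id]] <- list(members = unique(syms), kind = "gene")
    }
  }

  resolve <- function(id) {
    info <- entry_genes[[id]]
    if (is.null(info)) return(character(0))
    if (info$kind == "group") {
      unique(unlist(lapply(info$members, resolve)))
    } else {
      info$members
    }
  }

  plus <- c("activation", "expression")
  minus <- c("inhibition", "repression")
  rel_nodes <- xml2::xml_find_all(doc, "//relation")
  from <- character(0); to <- character(0); sgn <- integer(0)
  for (rel in rel_nodes) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    src <- resolve(e1); dst <- resolve(e2)
    if (!length(src) || !length(dst)) {
      warning("relation ", e1, "->", e2,
              " references a non-gene or unknown entry; skipped",
              call. = FALSE)
      next
    }
    subtypes <- xml2::xml_attr(xml2::xml_find_all(rel, "subtype"), "name")
    s <- NA_integer_
    if (any(subtypes %in% minus)) {
      s <- -1L
    } else if (any(subtypes %in% plus)) {
      s <- 1L
    } else if (strict) {
      next
    } else {
      warning("relation ", e1, "->", e2, " has no signed subtype (",
              paste(subtypes, collapse = ","), "); defaulting to activation",
              call. = FALSE)
      s <- 1L
    }
    grid <- expand.grid(src = src, dst = dst, stringsAsFactors = FALSE)
    from <- c(from, grid$src); to <- c(to, grid$dst)
    sgn <- c(sgn, rep(s, nrow(grid)))
  }

  all_genes <- unique(unlist(lapply(
    names(entry_genes)[vapply(entry_genes, function(i) i$kind == "gene",
                              logical(1))],
    resolve
  )))
  signed_network(
    tibble::tibble(from = from, to = to, sign = sgn),
    nodes = all_genes, name = name
  )
}

.parse_sign <- function(x) {
  x <- trimws(tolower(as.character(x)))
  dplyr::case_when(
    x %in% c("a", "activation", "+", "1", "+1", "activates") ~ 1L,
    x %in% c("i", "inhibition", "-", "-1", "−", "−1", "inhibits",
             "repression") ~ -1L,
    TRUE ~ NA_integer_
  )
}

#' Parse a GraphML network with signed edges
#'
#' @param path Path to a GraphML file (or GraphML string).
#' @param sign_key Name of the edge attribute carrying the sign. Accepted
#'   values: "a"/"i", "activation"/"inhibition", "+"/"-", 1/-1.
#' @param strict If `TRUE`, error on undirected graphs or edges with a
#'   missing/unrecognized sign; otherwise missing signs default to +1 with a
#'   warning.
#' @param name Network name; defaults to the file stem.
#'
#' @return A [signed_network()].
#' @export
parse_graphml <- function(path, sign_key = "signal", strict = FALSE,
                          name = NULL) {
  if (!file.exists(path) && grepl("<graphml", path, fixed = TRUE)) {
    tf <- tempfile(fileext = ".graphml")
    writeLines(path, tf)
    path <- tf
  }
  g <- igraph::read_graph(path, format = "graphml")
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  if (!igraph::is_directed(g)) {
    if (strict) stop("GraphML graph is undirected (strict mode)", call. = FALSE)
    g <- igraph::as_directed(g, mode = "mutual")
    warning("undirected GraphML converted to mutual directed edges",
            call. = FALSE)
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  eattr <- igraph::edge_attr(g)
  if (sign_key %in% names(eattr)) {
    sgn <- .parse_sign(eattr[[sign_key]])
  } else {
    sgn <- rep(NA_integer_, nrow(el))
  }
  if (anyNA(sgn)) {
    if (strict) {
      stop("edge sign attribute '", sign_key,
           "' missing or unrecognized (strict mode)", call. = FALSE)
    }
    warning(sum(is.na(sgn)), " edge(s) without a recognized '", sign_key,
            "' attribute; defaulting to activation", call. = FALSE)
    sgn[is.na(sgn)] <- 1L
  }
  nodes <- igraph::vertex_attr(g, "name")
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(g)))
  signed_network(
    tibble::tibble(from = el[, 1], to = el[, 2], sign = sgn),
    nodes = nodes, name = name
  )
}

#' Write a signed network to GraphML or an edge-list TSV
#'
#' @param net A [signed_network()].
#' @param path Output file path.
#' @param sign_key Edge attribute name used for the sign in GraphML.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, sign_key = "signal") {
  g <- igraph::graph_from_data_frame(
    net$edges, directed = TRUE,
    vertices = data.frame(name = net$nodes)
  )
  names(igraph::edge_attr(g)) # force attr list init
  g <- igraph::set_edge_attr(g, sign_key,
                             value = ifelse(net$edges$sign > 0, "a", "i"))
  g <- igraph::delete_edge_attr(g, "sign")
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edge_tsv <- function(net, path) {
  readr::write_tsv(net$edges, path)
  invisible(path)
}

#' Restrict a network to the genes measured in a dataset
#'
#' Nodes absent from `genes` are dropped with their incident edges. If fewer
#' than `min_nodes` nodes survive, the pathway is too small for meaningful
#' rule inference and `NULL` is returned so callers can skip it.
#'
#' @param net A [signed_network()].
#' @param genes Character vector of measured gene symbols.
#' @param min_nodes Minimum surviving node count (default 15).
#' @return A pruned [signed_network()], or `NULL` (skip signal).
#' @export
prune_to_dataset <- function(net, genes, min_nodes = 15) {
  stopifnot(length(genes) > 0)
  genes <- toupper(genes)
  keep <- intersect(net$nodes, genes)
  if (length(keep) < min_nodes) {
    message("pathway '", net$name, "': ", length(keep), " of ",
            length(net$nodes), " nodes measured (< ", min_nodes, "); skipped")
    return(NULL)
  }
  edges <- dplyr::filter(net$edges, .data$from %in% keep, .data$to %in% keep)
  signed_network(edges, nodes = keep, name = net$name)
}

#' Cap node in-degree and fix the canonical regulator order
#'
#' Rule inference considers at most `k_max` regulators per node. Nodes with
#' more incoming edges keep the `k_max` parents whose binarized expression has
#' the largest absolute Spearman correlation with the target's (ties broken
#' alphabetically by parent symbol); zero-variance columns count as
#' correlation 0. Surviving regulators are ordered alphabetically — this
#' order defines the truth-table bit positions used everywhere downstream.
#'
#' @param net A [signed_network()].
#' @param binary A [binarize()]d expression matrix covering all net nodes.
#' @param k_max Maximum in-degree (default 3).
#' @return A tibble with one row per node: `target`, and list-columns
#'   `regulators` (character) and `signs` (integer), in canonical order.
#' @export
cap_indegree <- function(net, binary, k_max = 3) {
  states <- binary$states
  missing <- setdiff(net$nodes, colnames(states))
  if (length(missing)) {
    stop("binary data lacks network genes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  spear <- function(a, b) {
    r <- suppressWarnings(cor(a, b, method = "spearman"))
    if (is.na(r)) 0 else abs(r)
  }
  purrr::map_dfr(net$nodes, function(node) {
    parents <- dplyr::filter(net$edges, .data$to == node)
    if (nrow(parents) > k_max) {
      y <- states[, node]
      parents$score <- vapply(parents$from, function(p) spear(states[, p], y),
                              numeric(1))
      parents <- parents |>
        dplyr::arrange(dplyr::desc(.data$score), .data$from) |>
        head(k_max)
    }
    parents <- dplyr::arrange(parents, .data$from)
    tibble::tibble(target = node,
                   regulators = list(parents$from),
                   signs = list(as.integer(parents$sign)))
  })
}
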